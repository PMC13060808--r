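# Synthetic fixture generation with machine-readable ground truth.
#
# Every generator emits, alongside its files, a manifest recording the
# planted truth: pairwise leaf distances (computed by a Dijkstra oracle
# that is coded independently of the tree-walking implementation in the
# taxonomy module), which BLAST rows must survive filtering together with
# their exact expected scores under a straight-line transcription of the
# scoring formulas, and the six-column rows planted in each generated
# article. Identical seed and spec yield byte-identical files.

#' Specification of a synthetic fixture bundle
#'
#' Defaults describe a two-domain taxonomy of depth 3 with binary
#' branching, a 35-row hit table (20 passing all filters, 5 failing each
#' of the identity/e-value/coverage thresholds), one paralog and one
#' lineage-fallback hit among the passing rows, and three well-formed
#' articles each planting a five-step His-tag purification. The failed
#' protocol is derived from the first article with two planted
#' differences: the elution imidazole concentration halved and the
#' lysozyme supplement dropped from lysis.
#'
#' @param seed Integer seed; identical seed and spec give byte-identical
#'   fixtures.
#' @param n_domains,depth,branching Tree shape: domains under the root,
#'   ranked levels below each domain, children per internal node.
#' @param n_pass Hits passing every filter threshold.
#' @param n_fail_pident,n_fail_evalue,n_fail_qcov Hits violating exactly
#'   one threshold each.
#' @param n_paralog Passing hits drawn from the query organism itself.
#' @param n_fallback Passing hits whose taxon is absent from the tree but
#'   resolvable one lineage step up.
#' @param n_articles Articles generated (each mapped to a top-ranked hit).
#' @param malformed_rate Fraction of articles written as irrecoverably
#'   malformed files.
#' @param n_inaccessible Extra citation records planted as inaccessible.
#' @param annotations Named character vector written to the annotation
#'   file.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_domains = 2L, depth = 3L,
                         branching = 2L, n_pass = 20L, n_fail_pident = 5L,
                         n_fail_evalue = 5L, n_fail_qcov = 5L,
                         n_paralog = 1L, n_fallback = 1L, n_articles = 3L,
                         malformed_rate = 0, n_inaccessible = 1L,
                         annotations = c(transmembrane = "62-84")) {
  if (n_domains < 1L || depth < 1L || branching < 1L) {
    rr_error("degenerate tree shape", "rescuerank_config_error")
  }
  if (n_paralog + n_fallback > n_pass) {
    rr_error("paralog + fallback rows cannot exceed passing rows",
             "rescuerank_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_domains = as.integer(n_domains),
         depth = as.integer(depth), branching = as.integer(branching),
         n_pass = as.integer(n_pass),
         n_fail_pident = as.integer(n_fail_pident),
         n_fail_evalue = as.integer(n_fail_evalue),
         n_fail_qcov = as.integer(n_fail_qcov),
         n_paralog = as.integer(n_paralog),
         n_fallback = as.integer(n_fallback),
         n_articles = as.integer(n_articles),
         malformed_rate = malformed_rate,
         n_inaccessible = as.integer(n_inaccessible),
         annotations = annotations),
    class = "fixture_spec"
  )
}

# ---- independent distance oracle ------------------------------------------
# Dijkstra over the tree adjacency; each edge charges the rank penalty of
# its deeper (child-side) endpoint. Deliberately a different algorithm
# from the ancestor-walk in penalized_distance().

#' Dijkstra oracle for rank-penalized tree distances
#'
#' Graph-search reference used to cross-check [penalized_distance()] and
#' to compute manifest ground truth. Runs Dijkstra over the adjacency of
#' the node table, charging each parent-child edge the rank penalty of
#' the child, then adds the domain-crossing surcharge when the endpoints'
#' domain ancestors differ.
#'
#' @param nodes Node data.frame (`taxon_id`, `parent_id`, `rank`).
#' @param a,b Taxon ids.
#' @param schedule A [penalty_schedule()].
#' @return Numeric penalized distance.
#' @export
oracle_distance <- function(nodes, a, b, schedule = penalty_schedule()) {
  ids <- nodes$taxon_id
  n <- length(ids)
  ia <- match(as.integer(a), ids)
  ib <- match(as.integer(b), ids)
  parent <- match(nodes$parent_id, ids)
  pen <- unname(schedule$per_rank_penalty[nodes$rank])
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) {
      adj[[i]] <- c(adj[[i]], parent[i])
      wts[[i]] <- c(wts[[i]], pen[i])          # up: the child pays
      adj[[parent[i]]] <- c(adj[[parent[i]]], i)
      wts[[parent[i]]] <- c(wts[[parent[i]]], pen[i])  # down: ditto
    }
  }
  dist <- rep(Inf, n)
  dist[ia] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    if (u == ib) break
    done[u] <- TRUE
    for (k in seq_along(adj[[u]])) {
      v <- adj[[u]][k]
      cand <- dist[u] + wts[[u]][k]
      if (cand < dist[v]) dist[v] <- cand
    }
  }
  d <- dist[ib]
  # domain crossing: walk each endpoint's parent chain for its domain node
  dom <- function(i) {
    while (!is.na(i)) {
      if (nodes$rank[i] == "domain") return(ids[i])
      i <- parent[i]
    }
    NA_integer_
  }
  da <- dom(ia)
  db <- dom(ib)
  if (!is.na(da) && !is.na(db) && da != db) {
    d <- d + schedule$domain_crossing_penalty
  }
  d
}

# Straight-line transcription of the three scoring formulas, kept separate
# from the score_hits() code path on purpose.
transcribe_scores <- function(pident, distance, fallback_steps, paralog,
                              maxdist, decrement = 0.05,
                              w_seq = 0.5, w_taxa = 0.5) {
  s_seq <- pident / 100
  s_taxa_raw <- if (distance == 0) 0.5 else 1 - distance / maxdist
  s_taxa <- min(max(s_taxa_raw - decrement * fallback_steps, 0), 1)
  if (paralog) s_taxa <- s_taxa / 2
  list(s_seq = s_seq, s_taxa_raw = s_taxa_raw, s_taxa = s_taxa,
       s_overall = w_seq * s_seq + w_taxa * s_taxa)
}

# ---- taxonomy fixture ------------------------------------------------------

fixture_rank_levels <- function(depth) {
  utils::tail(c("kingdom", "phylum", "class", "order", "family", "genus",
                "species"), depth)
}

#' Generate a synthetic taxonomy tree with distance ground truth
#'
#' Builds a balanced tree (one unranked root, `n_domains` domains, `depth`
#' ranked levels of `branching` children each), writes it as a 4-column
#' TSV, and returns a manifest listing every pairwise leaf distance under
#' unit penalties and under the default schedule, both computed by the
#' Dijkstra oracle.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `path`, `nodes`, `leaves`,
#'   `unit_distances`, `default_distances`, `maxdistance`.
#' @export
make_taxonomy <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  levels <- fixture_rank_levels(spec$depth)
  rows <- list(data.frame(taxon_id = 1L, parent_id = NA_integer_,
                          rank = "no_rank", name = "root",
                          stringsAsFactors = FALSE))
  next_id <- 2L
  frontier <- integer(0)
  for (d in seq_len(spec$n_domains)) {
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = next_id, parent_id = 1L, rank = "domain",
      name = paste0("domain_", d), stringsAsFactors = FALSE
    )
    frontier <- c(frontier, next_id)
    next_id <- next_id + 1L
  }
  for (lev in seq_along(levels)) {
    new_frontier <- integer(0)
    for (p in frontier) {
      for (k in seq_len(spec$branching)) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = next_id, parent_id = p, rank = levels[lev],
          name = paste0(levels[lev], "_", next_id), stringsAsFactors = FALSE
        )
        new_frontier <- c(new_frontier, next_id)
        next_id <- next_id + 1L
      }
    }
    frontier <- new_frontier
  }
  nodes <- do.call(rbind, rows)
  path <- file.path(dir, "taxonomy.tsv")
  utils::write.table(nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  leaves <- nodes$taxon_id[!(nodes$taxon_id %in% nodes$parent_id)]
  unit <- penalty_schedule(
    per_rank_penalty = stats::setNames(rep(1, length(taxonomy_ranks)),
                                       taxonomy_ranks),
    domain_crossing_penalty = 1
  )
  default <- penalty_schedule()
  pairs <- utils::combn(leaves, 2L)
  unit_d <- numeric(ncol(pairs))
  default_d <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    unit_d[j] <- oracle_distance(nodes, pairs[1L, j], pairs[2L, j], unit)
    default_d[j] <- oracle_distance(nodes, pairs[1L, j], pairs[2L, j],
                                    default)
  }
  invisible(list(
    path = path, nodes = nodes, leaves = leaves,
    unit_distances = data.frame(a = pairs[1L, ], b = pairs[2L, ],
                                distance = unit_d),
    default_distances = data.frame(a = pairs[1L, ], b = pairs[2L, ],
                                   distance = default_d),
    maxdistance = max(default_d)
  ))
}

lookup_default_distance <- function(tax, a, b) {
  if (a == b) return(0)
  dd <- tax$default_distances
  hit <- (dd$a == a & dd$b == b) | (dd$a == b & dd$b == a)
  dd$distance[hit][1L]
}

# ---- hits fixture ----------------------------------------------------------

#' Generate a synthetic BLAST hit table with expected scores
#'
#' Writes a tabular hit file in which a spec-controlled number of rows
#' violates each filter threshold, plants paralog and lineage-fallback
#' rows among the passing hits, and returns a manifest recording which
#' rows must survive filtering and their exact expected score components
#' under the default schedule and weights (computed by an independent
#' straight-line transcription of the scoring formulas, using the
#' oracle-derived distances).
#'
#' @param spec A [fixture_spec()].
#' @param tax The manifest returned by [make_taxonomy()].
#' @param dir Output directory.
#' @return Invisibly, a list with `path`, `query_taxon`, `expected`
#'   (data.frame of surviving rows and scores), `n_rows`.
#' @export
make_hits <- function(spec, tax, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed + 1L, {
    leaves <- tax$leaves
    query_taxon <- leaves[1L]
    n_total <- spec$n_pass + spec$n_fail_pident + spec$n_fail_evalue +
      spec$n_fail_qcov
    kind <- c(rep("pass", spec$n_pass),
              rep("fail_pident", spec$n_fail_pident),
              rep("fail_evalue", spec$n_fail_evalue),
              rep("fail_qcov", spec$n_fail_qcov))
    # special passing rows: paralogs first, then fallback rows
    special <- rep("none", n_total)
    if (spec$n_paralog > 0L) special[seq_len(spec$n_paralog)] <- "paralog"
    if (spec$n_fallback > 0L) {
      special[spec$n_paralog + seq_len(spec$n_fallback)] <- "fallback"
    }
    max_id <- max(tax$nodes$taxon_id)
    rows <- vector("list", n_total)
    exp_rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      pident <- round(stats::runif(1, 40, 95), 1)
      evalue <- signif(10^stats::runif(1, -30, -6), 3)
      qcov <- round(stats::runif(1, 80, 100), 1)
      if (kind[i] == "fail_pident") pident <- round(stats::runif(1, 5, 18), 1)
      if (kind[i] == "fail_evalue") evalue <- signif(10^stats::runif(1, -2.5, -1), 3)
      if (kind[i] == "fail_qcov") qcov <- round(stats::runif(1, 40, 70), 1)
      bitscore <- round(600 - i * 3.5, 1)
      subj_leaf <- sample(leaves[-1L], 1L)  # the query leaf is reserved
                                            # for explicit paralog rows
      staxid <- subj_leaf
      slineage <- ""
      fallback_steps <- 0L
      paralog <- FALSE
      if (special[i] == "paralog") {
        subj_leaf <- query_taxon
        staxid <- query_taxon
        paralog <- TRUE
      } else if (special[i] == "fallback") {
        subj_leaf <- sample(leaves[-1L], 1L)
        staxid <- max_id + i  # strain absent from the tree
        chain <- subj_leaf
        p <- tax$nodes$parent_id[match(subj_leaf, tax$nodes$taxon_id)]
        while (!is.na(p)) {
          chain <- c(chain, p)
          p <- tax$nodes$parent_id[match(p, tax$nodes$taxon_id)]
        }
        slineage <- paste(chain, collapse = "|")
        fallback_steps <- 1L
      }
      sseqid <- sprintf("SUBJ%03d", i)
      rows[[i]] <- data.frame(
        qseqid = "query", sseqid = sseqid, pident = pident,
        length = 230L, mismatch = 10L, gapopen = 1L, qstart = 1L,
        qend = 230L, sstart = 1L, send = 230L, evalue = evalue,
        bitscore = bitscore, qcovs = qcov, staxid = staxid,
        slineage = slineage, stringsAsFactors = FALSE
      )
      if (kind[i] == "pass") {
        d <- lookup_default_distance(tax, query_taxon, subj_leaf)
        sc <- transcribe_scores(pident, d, fallback_steps, paralog,
                                tax$maxdistance)
        exp_rows[[i]] <- data.frame(
          sseqid = sseqid, pident = pident, distance = d,
          fallback_steps = fallback_steps, is_paralog = paralog,
          s_seq = sc$s_seq, s_taxa_raw = sc$s_taxa_raw,
          s_taxa = sc$s_taxa, s_overall = sc$s_overall,
          stringsAsFactors = FALSE
        )
      }
    }
    tab <- do.call(rbind, rows)
    path <- file.path(dir, "hits.tsv")
    con <- file(path, "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(tab))) {
      writeLines(paste(
        tab$qseqid[i], tab$sseqid[i], format(tab$pident[i], trim = TRUE),
        tab$length[i], tab$mismatch[i], tab$gapopen[i], tab$qstart[i],
        tab$qend[i], tab$sstart[i], tab$send[i],
        format(tab$evalue[i], trim = TRUE, scientific = TRUE),
        format(tab$bitscore[i], trim = TRUE),
        format(tab$qcovs[i], trim = TRUE), tab$staxid[i], tab$slineage[i],
        sep = "\t"
      ), con)
    }
    expected <- do.call(rbind, exp_rows[!vapply(exp_rows, is.null, TRUE)])
    # manifest ranking mirrors the rank_hits tie-break rules
    expected <- expected[order(-expected$s_overall, -expected$s_seq,
                               expected$sseqid), ]
    rownames(expected) <- NULL
    invisible(list(path = path, query_taxon = query_taxon,
                   expected = expected, n_rows = n_total))
  })
}

# ---- article fixtures ------------------------------------------------------

fixture_step_sentence <- function(category, variant, comp, ph, supp_phrase) {
  tpl <- switch(category,
    lysis = c(
      "Cells were resuspended in lysis buffer (%s, pH %s)%s and lysed by sonication.",
      "Pellets were lysed in lysis buffer containing %s, pH %s%s."
    ),
    capture = c(
      "The clarified lysate was loaded onto a HisTrap column equilibrated with binding buffer (%s, pH %s)%s.",
      "The supernatant was applied to Ni Sepharose resin equilibrated in binding buffer containing %s, pH %s%s."
    ),
    wash = c(
      "The column was washed with wash buffer (%s, pH %s)%s.",
      "The resin was washed extensively with wash buffer containing %s, pH %s%s."
    ),
    elution = c(
      "Bound protein was eluted with elution buffer (%s, pH %s)%s.",
      "The protein was eluted using elution buffer containing %s, pH %s%s."
    ),
    polish = c(
      "The pooled fractions were polished by size-exclusion chromatography on a Superdex 75 column in SEC buffer (%s, pH %s)%s.",
      "Final polishing used gel filtration on a Superdex 200 column equilibrated with SEC buffer containing %s, pH %s%s."
    )
  )
  sprintf(tpl[variant], comp, ph, supp_phrase)
}

# Plant the parameters of one five-step protocol. All randomness is drawn
# from the caller's seeded RNG stream.
plant_protocol <- function(fixed_elution_imidazole = 500) {
  buffer <- sample(c("HEPES", "Tris", "MOPS"), 1L)
  buffer_mM <- sample(c(20, 25, 50), 1L)
  salt <- sample(c("NaCl", "KCl"), 1L)
  salt_mM <- sample(c(150, 300, 500), 1L)
  reductant <- sample(c("DTT", "TCEP"), 1L)
  glycerol <- sample(c(TRUE, FALSE), 1L)
  ph <- sample(c(6.8, 7.0, 7.4, 7.5, 8.0), 1L)
  base <- function(extra = NULL) {
    parts <- c(sprintf("%g mM %s", buffer_mM, buffer),
               sprintf("%g mM %s", salt_mM, salt), extra)
    if (glycerol) parts <- c(parts, "5% glycerol")
    paste(c(parts, sprintf("1 mM %s", reductant)), collapse = ", ")
  }
  steps <- list(
    lysis = list(comp = base("30 mM Imidazole"), ph = ph,
                 supplements = c("lysozyme", "protease inhibitor cocktail")),
    capture = list(comp = base("30 mM Imidazole"), ph = ph,
                   supplements = character(0)),
    wash = list(comp = base("40 mM Imidazole"), ph = ph,
                supplements = character(0)),
    elution = list(comp = base(sprintf("%g mM Imidazole",
                                       fixed_elution_imidazole)),
                   ph = ph, supplements = character(0)),
    polish = list(comp = base(), ph = ph, supplements = character(0))
  )
  list(buffer = buffer, salt = salt, reductant = reductant,
       glycerol = glycerol, ph = ph, steps = steps)
}

protocol_sentences <- function(plan, variant) {
  out <- character(0)
  for (cat in names(plan$steps)) {
    st <- plan$steps[[cat]]
    supp_phrase <- if (cat == "lysis" && length(st$supplements)) {
      " supplemented with lysozyme and protease inhibitor cocktail"
    } else ""
    out <- c(out, fixture_step_sentence(cat, variant, st$comp,
                                        format(st$ph), supp_phrase))
  }
  out
}

# Ground-truth six-column expectations for one planted protocol, mirroring
# what a faithful summarizer must recover from the sentences.
plan_expected_rows <- function(plan) {
  rows <- list()
  for (cat in names(plan$steps)) {
    st <- plan$steps[[cat]]
    supp <- character(0)
    if (length(st$supplements)) supp <- st$supplements
    if (plan$glycerol) supp <- c(supp, "glycerol")
    supp <- c(supp, plan$reductant)
    rows[[cat]] <- list(
      category = cat, ph = st$ph, salt = plan$salt,
      supplements = sort(tolower(supp)),
      composition = st$comp
    )
  }
  rows
}

jats_article <- function(article_id, title, protocol_sentences) {
  intro <- paste(
    "The target gene was studied in a structural genomics context.",
    "Its open reading frame was amplified and ligated into an expression vector.")
  assay <- "Protein concentration was determined by absorbance at 280 nm."
  expression_p <- paste(
    "The construct was transformed into a standard host strain and grown",
    "in rich medium before induction.")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<article xmlns:xlink="http://www.w3.org/1999/xlink">\n',
    "  <front><article-meta><title-group><article-title>", title,
    "</article-title></title-group></article-meta></front>\n",
    "  <body>\n",
    "    <sec><title>Introduction</title><p>", intro, "</p></sec>\n",
    "    <sec><title>Materials and Methods</title>\n",
    "      <sec><title>Cloning and expression</title><p>", expression_p,
    "</p></sec>\n",
    "      <sec><title>Protein purification</title><p>",
    paste(protocol_sentences, collapse = " "), " ", assay, "</p></sec>\n",
    "    </sec>\n",
    "    <sec><title>Results</title><p>The purified protein crystallized",
    " readily.</p></sec>\n",
    "  </body>\n",
    "</article>\n"
  )
}

#' Generate synthetic JATS articles with planted purification protocols
#'
#' Each well-formed article embeds a methods section whose purification
#' subsection is rendered from planted step parameters using sentence
#' templates rotated per article; a spec-controlled number of files is
#' written as irrecoverably malformed text instead. The manifest records
#' the planted six-column rows, the exact protocol sentences, and which
#' files are malformed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory; articles land in `dir/articles/`.
#' @return Invisibly, a list with `dir`, `articles` (per-article manifest),
#'   `n_malformed`.
#' @export
make_articles <- function(spec, dir) {
  adir <- file.path(dir, "articles")
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed + 2L, {
    n <- spec$n_articles
    n_malformed <- round(spec$malformed_rate * n)
    malformed_idx <- if (n_malformed > 0L) {
      sort(sample(seq_len(n), n_malformed))
    } else integer(0)
    articles <- vector("list", n)
    for (i in seq_len(n)) {
      article_id <- sprintf("PMC%07d", i)
      path <- file.path(adir, paste0(article_id, ".xml"))
      if (i %in% malformed_idx) {
        writeLines(c("corrupted download: this payload is not XML",
                     paste0("fragment ", i, " @@@@ truncated")), path)
        articles[[i]] <- list(article_id = article_id, malformed = TRUE)
        next
      }
      plan <- plant_protocol()
      variant <- sample(1:2, 1L)
      sentences <- protocol_sentences(plan, variant)
      title <- sprintf(
        "Structure and purification of synthetic target homolog %d", i
      )
      writeLines(jats_article(article_id, title, sentences), path,
                 useBytes = TRUE)
      articles[[i]] <- list(
        article_id = article_id, malformed = FALSE, title = title,
        variant = variant, plan = plan,
        protocol_text = paste(sentences, collapse = " "),
        expected_rows = plan_expected_rows(plan)
      )
    }
    invisible(list(dir = adir, articles = articles,
                   n_malformed = n_malformed))
  })
}

#' Generate the failed-baseline protocol with planted differences
#'
#' The failed protocol reuses the first well-formed article's planted
#' parameters with two deliberate deviations: the elution imidazole
#' concentration is halved (250 mM instead of 500 mM) and the lysozyme /
#' protease-inhibitor supplementation is dropped from lysis. Both are
#' recorded in the returned manifest so diff and optimizer outputs can be
#' checked against known truth.
#'
#' @param spec A [fixture_spec()].
#' @param articles Manifest from [make_articles()].
#' @param dir Output directory.
#' @return Invisibly, a list with `path`, `planted_differences`.
#' @export
make_failed_protocol <- function(spec, articles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- Filter(function(a) !isTRUE(a$malformed), articles$articles)
  if (!length(ok)) {
    rr_error("no well-formed article to derive the failed protocol from",
             "rescuerank_config_error")
  }
  with_seed(spec$seed + 3L, {
    plan <- ok[[1L]]$plan
    plan$steps$elution$comp <- sub("500 mM Imidazole", "250 mM Imidazole",
                                   plan$steps$elution$comp, fixed = TRUE)
    plan$steps$lysis$supplements <- character(0)
    sentences <- character(0)
    for (cat in names(plan$steps)) {
      st <- plan$steps[[cat]]
      sentences <- c(sentences, fixture_step_sentence(
        cat, 1L, st$comp, format(st$ph), ""
      ))
    }
    path <- file.path(dir, "failed_protocol.txt")
    writeLines(paste(sentences, collapse = " "), path, useBytes = TRUE)
    invisible(list(
      path = path,
      planted_differences = list(
        list(parameter = "imidazole (mM)", step_category = "elution",
             failed_value = 250, successful_value = 500),
        list(parameter = "supplement: lysozyme", step_category = "lysis")
      )
    ))
  })
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes the taxonomy TSV, query FASTA, hit table, citation map, JATS
#' article directory, failed protocol, annotation file, and a
#' `manifest.json` consolidating every piece of planted ground truth.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Invisibly, the consolidated manifest list (also written as
#'   `manifest.json`).
#' @export
make_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- make_taxonomy(spec, dir)
  hits <- make_hits(spec, tax, dir)
  articles <- make_articles(spec, dir)
  failed <- make_failed_protocol(spec, articles, dir)
  with_seed(spec$seed + 4L, {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    seq <- paste(sample(aa, 240, replace = TRUE), collapse = "")
    writeLines(c(">query synthetic purification target", seq),
               file.path(dir, "query.fasta"))
  })
  # citation map: the top-ranked surviving hits get the well-formed
  # articles, in order; extra planted inaccessible records follow
  ok_articles <- Filter(function(a) !isTRUE(a$malformed),
                        articles$articles)
  bad_articles <- Filter(function(a) isTRUE(a$malformed),
                         articles$articles)
  ranked_ids <- hits$expected$sseqid
  cit <- list()
  k <- 1L
  for (a in c(ok_articles, bad_articles)) {
    if (k > length(ranked_ids)) break
    cit[[length(cit) + 1L]] <- data.frame(
      structure_id = ranked_ids[k], article_id = a$article_id,
      has_primary_citation = TRUE, in_pmc = TRUE, open_license = TRUE,
      stringsAsFactors = FALSE
    )
    k <- k + 1L
  }
  for (j in seq_len(spec$n_inaccessible)) {
    if (k > length(ranked_ids)) break
    cit[[length(cit) + 1L]] <- data.frame(
      structure_id = ranked_ids[k], article_id = NA_character_,
      has_primary_citation = (j %% 3L != 1L),
      in_pmc = (j %% 3L == 0L), open_license = FALSE,
      stringsAsFactors = FALSE
    )
    k <- k + 1L
  }
  citations <- do.call(rbind, cit)
  utils::write.table(citations, file.path(dir, "citations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann_path <- file.path(dir, "annotations.txt")
  writeLines(paste(names(spec$annotations), "=",
                   unname(spec$annotations)), ann_path)
  # manifest paths are relative to the bundle dir so that two bundles
  # generated from the same seed are byte-identical wherever they land
  manifest <- list(
    spec = unclass(spec),
    taxonomy = list(
      path = basename(tax$path), n_nodes = nrow(tax$nodes),
      leaves = tax$leaves,
      query_taxon = hits$query_taxon,
      unit_distances = tax$unit_distances,
      default_distances = tax$default_distances,
      maxdistance = tax$maxdistance
    ),
    hits = list(path = basename(hits$path), n_rows = hits$n_rows,
                n_surviving = nrow(hits$expected),
                expected = hits$expected),
    articles = lapply(articles$articles, function(a) {
      a$plan <- NULL  # plans are re-expanded in expected_rows
      a
    }),
    n_malformed = articles$n_malformed,
    failed = list(path = basename(failed$path),
                  planted_differences = failed$planted_differences),
    citations = citations
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
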
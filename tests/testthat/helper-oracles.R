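# Shared test fixtures and independent oracles.
#
# oracle_igraph() is the reference for rank-penalized distances: it builds
# a weighted graph in which each parent-child edge costs the child's rank
# penalty and asks igraph for the shortest path, so it shares no code
# with the ancestor-walk in penalized_distance() nor with the Dijkstra
# oracle shipped in the fixtures module.

oracle_igraph <- function(nodes, a, b, schedule = penalty_schedule()) {
  ids <- nodes$taxon_id
  pen <- unname(schedule$per_rank_penalty[nodes$rank])
  pidx <- match(nodes$parent_id, ids)
  edges <- integer(0)
  weights <- numeric(0)
  for (i in seq_along(ids)) {
    if (!is.na(pidx[i])) {
      edges <- c(edges, pidx[i], i)
      weights <- c(weights, pen[i])
    }
  }
  g <- igraph::make_graph(edges, n = length(ids), directed = FALSE)
  d <- igraph::distances(g, v = match(a, ids), to = match(b, ids),
                         weights = weights)[1L, 1L]
  dom <- function(i) {
    while (!is.na(i)) {
      if (nodes$rank[i] == "domain") return(i)
      i <- pidx[i]
    }
    NA_integer_
  }
  da <- dom(match(a, ids))
  db <- dom(match(b, ids))
  if (!is.na(da) && !is.na(db) && da != db) {
    d <- d + schedule$domain_crossing_penalty
  }
  d
}

# Full pairwise oracle distance matrix for a node table, via one igraph
# shortest-path computation plus the domain-crossing surcharge.
oracle_igraph_matrix <- function(nodes, schedule = penalty_schedule()) {
  ids <- nodes$taxon_id
  pen <- unname(schedule$per_rank_penalty[nodes$rank])
  pidx <- match(nodes$parent_id, ids)
  edges <- integer(0)
  weights <- numeric(0)
  for (i in seq_along(ids)) {
    if (!is.na(pidx[i])) {
      edges <- c(edges, pidx[i], i)
      weights <- c(weights, pen[i])
    }
  }
  g <- igraph::make_graph(edges, n = length(ids), directed = FALSE)
  d <- igraph::distances(g, weights = weights)
  dom <- rep(NA_integer_, length(ids))
  for (i in seq_along(ids)) {
    j <- i
    while (!is.na(j)) {
      if (nodes$rank[j] == "domain") {
        dom[i] <- j
        break
      }
      j <- pidx[j]
    }
  }
  cross <- outer(dom, dom, function(a, b) {
    !is.na(a) & !is.na(b) & a != b
  })
  d + cross * schedule$domain_crossing_penalty
}

# Random rooted tree: unranked root, a few domain children, remaining
# nodes attached to a uniformly random earlier node with a random rank.
random_tree_nodes <- function(n, n_domains = 2L) {
  stopifnot(n >= 1L + n_domains)
  ranks <- setdiff(taxonomy_ranks, "domain")
  taxon_id <- seq_len(n)
  parent_id <- c(NA_integer_, rep(1L, n_domains),
                 if (n > 1L + n_domains) {
                   vapply((n_domains + 2L):n,
                          function(i) sample.int(i - 1L, 1L), 1L)
                 })
  rank <- c("no_rank", rep("domain", n_domains),
            sample(ranks, max(n - 1L - n_domains, 0L), replace = TRUE))
  data.frame(taxon_id = taxon_id, parent_id = parent_id, rank = rank,
             name = paste0("n", taxon_id), stringsAsFactors = FALSE)
}

# Small fixed tree used across taxonomy tests:
# root(1,no_rank) -> domains 2,3; under 2: genus 4 -> species 6,7;
# under 3: genus 5 -> species 8.
small_two_domain_nodes <- function() {
  data.frame(
    taxon_id = 1:8,
    parent_id = c(NA, 1, 1, 2, 3, 4, 4, 5),
    rank = c("no_rank", "domain", "domain", "genus", "genus",
             "species", "species", "species"),
    name = paste0("n", 1:8),
    stringsAsFactors = FALSE
  )
}

unit_schedule <- function(crossing = 1) {
  penalty_schedule(
    per_rank_penalty = stats::setNames(rep(1, length(taxonomy_ranks)),
                                       taxonomy_ranks),
    domain_crossing_penalty = crossing
  )
}

# Straight-line transcription of the three scoring formulas, written here
# independently of both the package implementation and the fixtures
# module's copy.
transcription_oracle <- function(pident, distance, fallback_steps,
                                 paralog, maxdist, decrement = 0.05,
                                 w_seq = 0.5, w_taxa = 0.5) {
  s_seq <- pident / 100
  s_taxa <- if (distance == 0) 0.5 else 1 - distance / maxdist
  s_taxa <- s_taxa - decrement * fallback_steps
  s_taxa <- max(0, min(1, s_taxa))
  if (paralog) s_taxa <- s_taxa / 2
  w_seq * s_seq + w_taxa * s_taxa
}

# Minimal hit table builder for filter/rank tests.
make_hit_rows <- function(n, pident = 80, evalue = 1e-10, qcov = 90,
                          bitscore = NULL, staxid = 1L) {
  data.frame(
    qseqid = "q", sseqid = sprintf("S%03d", seq_len(n)),
    pident = rep_len(pident, n), length = 100L, mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = rep_len(evalue, n),
    bitscore = if (is.null(bitscore)) seq(500, by = -1, length.out = n)
    else rep_len(bitscore, n),
    qcovs = rep_len(qcov, n), staxid = rep_len(staxid, n),
    slineage = "", stringsAsFactors = FALSE
  )
}

hits_to_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Minimal JATS builder for litmine tests.
jats_doc <- function(sections, title = "A test article") {
  body <- paste(vapply(sections, function(s) {
    inner <- if (!is.null(s$subsections)) {
      paste(vapply(s$subsections, function(ss) {
        paste0("<sec><title>", ss$title, "</title><p>", ss$text,
               "</p></sec>")
      }, ""), collapse = "")
    } else ""
    paste0("<sec><title>", s$title, "</title>",
           if (!is.null(s$text)) paste0("<p>", s$text, "</p>") else "",
           inner, "</sec>")
  }, ""), collapse = "")
  paste0('<article><front><article-meta><title-group><article-title>',
         title, '</article-title></title-group></article-meta></front>',
         '<body>', body, '</body></article>')
}
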
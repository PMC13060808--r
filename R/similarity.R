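# Composite similarity scoring of BLAST hits.
#
# S_seq    = pident / 100
# S_taxa   = 0.5 if distance == 0, else 1 - distance / maxdistance
#            (minus a per-fallback-step decrement, clamped to [0, 1];
#             halved when the hit is a paralog of the query)
# S_overall = w_seq * S_seq + w_taxa * S_taxa    (defaults 0.5 / 0.5)

#' Default column order for tabular BLAST output
#'
#' The standard 12 tabular columns followed by the per-subject query
#' coverage, the subject taxon id, and an optional pipe-separated subject
#' lineage used for fallback when the taxon is absent from the tree.
#'
#' @format Character vector.
#' @export
blast_columns <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore",
  "qcovs", "staxid", "slineage"
)

#' Parse tabular BLAST output
#'
#' Reads outfmt-6-style tab-separated hit tables. Malformed rows (wrong
#' field count, non-numeric numeric fields, out-of-range percentages) are
#' skipped with a warning reporting the count; an empty input yields an
#' empty table.
#'
#' @param path Path to the tabular file (or a character vector of lines via
#'   `text`).
#' @param col_names Column names in file order; must include `sseqid`,
#'   `pident`, `evalue`, `bitscore` and `qcovs`. Trailing columns missing
#'   from a row are filled with `NA` only for the optional `slineage`.
#' @param text Optional character scalar/vector of raw lines, used instead
#'   of `path`.
#' @return A `data.frame` of class `blast_hits`, one row per well-formed hit.
#' @export
parse_blast_table <- function(path = NULL, col_names = blast_columns,
                              text = NULL) {
  need <- c("sseqid", "pident", "evalue", "bitscore", "qcovs")
  if (!all(need %in% col_names)) {
    rr_error(paste0("column map must include: ", paste(need, collapse = ", ")),
             "rescuerank_config_error")
  }
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
  else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  ncore <- length(col_names) - ("slineage" %in% col_names)
  out <- vector("list", length(lines))
  skipped <- 0L
  numeric_cols <- intersect(
    c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
      "sstart", "send", "evalue", "bitscore", "qcovs"),
    col_names
  )
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < ncore || length(f) > length(col_names)) {
      skipped <- skipped + 1L
      next
    }
    f <- c(f, rep(NA_character_, length(col_names) - length(f)))
    row <- as.list(f)
    names(row) <- col_names
    nums <- suppressWarnings(as.numeric(unlist(row[numeric_cols])))
    if (anyNA(nums)) {
      skipped <- skipped + 1L
      next
    }
    row[numeric_cols] <- as.list(nums)
    if (row$pident < 0 || row$pident > 100 || row$qcovs < 0 ||
        row$qcovs > 100 || row$evalue < 0) {
      skipped <- skipped + 1L
      next
    }
    out[[i]] <- row
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (skipped > 0L) {
    rr_warn(paste0(skipped, " malformed BLAST row(s) skipped; ",
                   length(out), " retained"))
  }
  if (!length(out)) {
    hits <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(col_names)), col_names),
      stringsAsFactors = FALSE
    )
    for (cc in numeric_cols) hits[[cc]] <- numeric(0)
  } else {
    hits <- do.call(rbind, lapply(out, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  rownames(hits) <- NULL
  class(hits) <- c("blast_hits", "data.frame")
  hits
}

#' Retrieval criteria for BLAST hits
#'
#' Defaults: percent identity above 20, e-value below 1e-3, query coverage
#' above 75, and at most 50 hits retained. Comparisons are strict
#' inequalities; set `strict = FALSE` to include boundary values.
#'
#' @param min_pident,max_evalue,min_qcov,max_hits Thresholds.
#' @param strict Use strict inequalities at the thresholds (default TRUE).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_pident = 20, max_evalue = 1e-3,
                            min_qcov = 75, max_hits = 50L, strict = TRUE) {
  if (min_pident < 0 || min_pident > 100 || min_qcov < 0 || min_qcov > 100 ||
      max_evalue < 0 || max_hits < 1L) {
    rr_error("filter criteria out of range", "rescuerank_config_error")
  }
  structure(
    list(min_pident = min_pident, max_evalue = max_evalue,
         min_qcov = min_qcov, max_hits = as.integer(max_hits),
         strict = isTRUE(strict)),
    class = "filter_criteria"
  )
}

#' Filter BLAST hits by identity, e-value and coverage, then cap the count
#'
#' Hits must have `pident > min_pident`, `evalue < max_evalue` and
#' `qcovs > min_qcov` (strict by default). When more than `max_hits`
#' survive, the best `max_hits` by bitscore are kept (ties broken by
#' smaller e-value, then lexicographic subject id).
#'
#' @param hits A `blast_hits` data.frame.
#' @param criteria A [filter_criteria()].
#' @return The retained subset, same class, deterministic order
#'   (bitscore-descending within the cap path, input order otherwise).
#' @export
filter_hits <- function(hits, criteria = filter_criteria()) {
  if (!nrow(hits)) return(hits)
  keep <- if (criteria$strict) {
    hits$pident > criteria$min_pident &
      hits$evalue < criteria$max_evalue &
      hits$qcovs > criteria$min_qcov
  } else {
    hits$pident >= criteria$min_pident &
      hits$evalue <= criteria$max_evalue &
      hits$qcovs >= criteria$min_qcov
  }
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) > criteria$max_hits) {
    ord <- order(-out$bitscore, out$evalue, out$sseqid)
    out <- out[ord[seq_len(criteria$max_hits)], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Normalized sequence similarity from percent identity
#'
#' @param pident Percent identity in \[0, 100\].
#' @return `pident / 100`, in \[0, 1\].
#' @export
sequence_similarity <- function(pident) {
  if (any(!is.finite(pident)) || any(pident < 0) || any(pident > 100)) {
    rr_error("pident must lie in [0, 100]", "rescuerank_domain_error")
  }
  pident / 100
}

#' Taxonomic similarity from a penalized distance
#'
#' Returns 0.5 when the penalized distance is zero (same organism; the
#' paralog halving is applied separately), otherwise
#' `1 - raw_distance / maxdistance`. A decrement of
#' `missing_lineage_decrement` per lineage-fallback step is then subtracted
#' and the result clamped to \[0, 1\].
#'
#' @param distance A `taxonomic_distance`, or a non-negative numeric raw
#'   distance.
#' @param maxdistance Positive normalizer, typically [max_distance()].
#' @param fallback_steps Fallback hops consumed resolving the organisms;
#'   defaults to the value carried by `distance`.
#' @param schedule A [penalty_schedule()] supplying the decrement.
#' @return Scalar similarity in \[0, 1\].
#' @export
taxonomic_similarity <- function(distance, maxdistance,
                                 fallback_steps = NULL,
                                 schedule = penalty_schedule()) {
  if (!is.finite(maxdistance) || maxdistance <= 0) {
    rr_error("maxdistance must be > 0", "rescuerank_domain_error")
  }
  if (inherits(distance, "taxonomic_distance")) {
    if (is.null(fallback_steps)) fallback_steps <- distance$fallback_steps
    distance <- distance$raw_distance
  }
  if (is.null(fallback_steps)) fallback_steps <- 0L
  s <- if (distance == 0) 0.5 else 1 - distance / maxdistance
  s <- s - schedule$missing_lineage_decrement * fallback_steps
  min(max(s, 0), 1)
}

#' Halve the taxonomic similarity of same-organism (paralog) hits
#'
#' @param s_taxa Taxonomic similarity in \[0, 1\].
#' @param same_organism Is the hit from the query's own organism?
#' @return `s_taxa / 2` for paralogs, else `s_taxa` unchanged.
#' @export
paralog_penalty <- function(s_taxa, same_organism) {
  if (any(s_taxa < 0) || any(s_taxa > 1)) {
    rr_error("s_taxa must lie in [0, 1]", "rescuerank_domain_error")
  }
  ifelse(same_organism, s_taxa / 2, s_taxa)
}

#' Weights of the two similarity components
#'
#' @param w_seq,w_taxa Non-negative weights summing to 1 (defaults 0.5 each).
#' @return An object of class `similarity_weights`.
#' @export
similarity_weights <- function(w_seq = 0.5, w_taxa = 1 - w_seq) {
  if (w_seq < 0 || w_taxa < 0 || abs(w_seq + w_taxa - 1) > 1e-9) {
    rr_error("weights must be non-negative and sum to 1",
             "rescuerank_config_error")
  }
  structure(list(w_seq = w_seq, w_taxa = w_taxa),
            class = "similarity_weights")
}

#' Composite overall similarity score
#'
#' @param s_seq,s_taxa Component scores in \[0, 1\].
#' @param weights A [similarity_weights()].
#' @return `w_seq * s_seq + w_taxa * s_taxa`, in \[0, 1\].
#' @export
overall_score <- function(s_seq, s_taxa, weights = similarity_weights()) {
  if (any(s_seq < 0 | s_seq > 1) || any(s_taxa < 0 | s_taxa > 1)) {
    rr_error("component scores must lie in [0, 1]", "rescuerank_domain_error")
  }
  weights$w_seq * s_seq + weights$w_taxa * s_taxa
}

#' Score filtered BLAST hits against a taxonomy tree
#'
#' For each hit the subject taxon is resolved in the tree (walking up the
#' optional `slineage` column when absent), the rank-penalized distance to
#' the query organism is computed, and the component and composite scores
#' are attached. Hits whose taxon cannot be resolved even via lineage are
#' excluded and reported in the `excluded` attribute.
#'
#' @param hits A `blast_hits` data.frame (typically after [filter_hits()]).
#' @param tree A `taxonomy_tree`.
#' @param query_taxon Taxon id of the query organism.
#' @param query_lineage Optional lineage for the query organism, used when
#'   it is itself absent from the tree.
#' @param schedule A [penalty_schedule()].
#' @param weights A [similarity_weights()].
#' @param maxdist Normalizer; computed by [max_distance()] when `NULL`.
#' @return A `data.frame` of class `scored_hits` with columns `s_seq`,
#'   `s_taxa_raw`, `s_taxa`, `s_overall`, `is_paralog`, `fallback_steps`
#'   appended; attribute `excluded` holds subject ids dropped as
#'   unresolvable, attribute `maxdistance` the normalizer used.
#' @export
score_hits <- function(hits, tree, query_taxon, query_lineage = integer(0),
                       schedule = penalty_schedule(),
                       weights = similarity_weights(), maxdist = NULL) {
  if (is.null(maxdist)) maxdist <- max_distance(tree, schedule)
  qres <- resolve_with_fallback(tree, query_taxon, query_lineage)
  qid <- qres$node$taxon_id
  n <- nrow(hits)
  s_seq <- s_taxa_raw <- s_taxa <- s_overall <- rep(NA_real_, n)
  is_paralog <- rep(FALSE, n)
  fb <- rep(0L, n)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    lineage <- integer(0)
    if ("slineage" %in% names(hits) && !is.na(hits$slineage[i]) &&
        nzchar(hits$slineage[i])) {
      lineage <- as.integer(strsplit(hits$slineage[i], "|", fixed = TRUE)[[1L]])
    }
    sres <- tryCatch(
      resolve_with_fallback(tree, hits$staxid[i], lineage),
      rescuerank_unresolvable_taxon = function(e) NULL
    )
    if (is.null(sres)) {
      drop[i] <- TRUE
      next
    }
    d <- penalized_distance(tree, qid, sres$node$taxon_id, schedule)
    steps <- qres$fallback_steps + sres$fallback_steps
    same <- as.integer(hits$staxid[i]) == as.integer(query_taxon)
    s_seq[i] <- sequence_similarity(hits$pident[i])
    s_taxa_raw[i] <- if (d$raw_distance == 0) 0.5
    else 1 - d$raw_distance / maxdist
    st <- taxonomic_similarity(d, maxdist, fallback_steps = steps,
                               schedule = schedule)
    s_taxa[i] <- paralog_penalty(st, same)
    s_overall[i] <- overall_score(s_seq[i], s_taxa[i], weights)
    is_paralog[i] <- same
    fb[i] <- steps
  }
  excluded <- hits$sseqid[drop]
  if (length(excluded)) {
    rr_warn(paste0(length(excluded), " hit(s) excluded as unresolvable: ",
                   paste(excluded, collapse = ", ")))
  }
  out <- hits[!drop, , drop = FALSE]
  out$s_seq <- s_seq[!drop]
  out$s_taxa_raw <- s_taxa_raw[!drop]
  out$s_taxa <- s_taxa[!drop]
  out$s_overall <- s_overall[!drop]
  out$is_paralog <- is_paralog[!drop]
  out$fallback_steps <- fb[!drop]
  rownames(out) <- NULL
  class(out) <- c("scored_hits", "data.frame")
  attr(out, "excluded") <- excluded
  attr(out, "maxdistance") <- maxdist
  out
}

#' Rank scored hits, apply the similarity threshold and the result limit
#'
#' Hits with `s_overall >= min_score` are sorted from most to least similar
#' (ties: higher `s_seq`, then lexicographic subject id) and truncated to
#' `limit`.
#'
#' @param scored A `scored_hits` data.frame.
#' @param min_score Minimum overall similarity retained (default 0).
#' @param limit Maximum number of hits returned (default all).
#' @return The ranked subset, same class.
#' @export
rank_hits <- function(scored, min_score = 0, limit = Inf) {
  out <- scored[scored$s_overall >= min_score, , drop = FALSE]
  ord <- order(-out$s_overall, -out$s_seq, out$sseqid)
  out <- out[ord, , drop = FALSE]
  if (is.finite(limit) && nrow(out) > limit) {
    out <- out[seq_len(limit), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write ranked hits with all score components
#'
#' @param scored A `scored_hits` data.frame.
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_ranked_hits <- function(scored, tsv = NULL, json = NULL) {
  paths <- character(0)
  if (!is.null(tsv)) {
    utils::write.table(scored, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(scored), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, json)
  }
  invisible(paths)
}
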
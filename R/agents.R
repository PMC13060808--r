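# The three agent roles — extraction, summarization, optimization — with a
# deterministic rule-based backend as the tested default and a pluggable
# callable backend for remote models. Whatever the backend, outputs are
# schema-validated before they propagate: the extractor may only return a
# subset of its input sentences, the summarizer a validated six-column
# table whose values appear verbatim in the input, the optimizer a
# structured report. Nonconforming output from a pluggable backend is
# retried a bounded number of times, then surfaced as an agent failure.

default_purification_lexicon <- c(
  "column", "resin", "buffer", "elut", "imidazole", "dialys", "his-tag",
  "his tag", "size-exclusion", "size exclusion", "lysis", "lysed",
  "chromatograph", "superdex", "sepharose", "histrap", "sonicat", "wash",
  "equilibrat", "purif", "eluate", "flow-through", "gel filtration",
  "centrifug", "clarif", "imac", "affinity", "supernatant"
)

default_salt_lexicon <- c(
  "NaCl", "NaCI", "KCl", "KCI", "LiCl", "MgCl2", "CaCl2", "(NH4)2SO4",
  "ammonium sulfate", "sodium chloride", "potassium chloride"
)

default_supplement_lexicon <- c(
  "protease inhibitor cocktail", "protease inhibitor", "lysozyme",
  "glycerol", "DTT", "TCEP", "β-mercaptoethanol", "2-mercaptoethanol",
  "beta-mercaptoethanol", "BME", "CHAPS", "Triton X-100", "Tween-20",
  "Tween 20", "NP-40", "DNase", "benzonase", "EDTA", "PMSF", "DDM"
)

# Keywords that open a new protocol step, tried in sentence-position order.
step_keyword_categories <- c(
  "lysis" = "lysis", "lysed" = "lysis", "resuspend" = "lysis",
  "sonicat" = "lysis", "homogeniz" = "lysis",
  "equilibrat" = "capture", "binding buffer" = "capture",
  "loaded" = "capture", "histrap" = "capture", "ni sepharose" = "capture",
  "ni-nta" = "capture", "talon" = "capture", "affinity" = "capture",
  "washed" = "wash", "wash buffer" = "wash", "washing" = "wash",
  "elut" = "elution",
  "dialyz" = "cleavage", "dialys" = "cleavage", "cleav" = "cleavage",
  "tev" = "cleavage",
  "size-exclusion" = "polish", "size exclusion" = "polish",
  "superdex" = "polish", "gel filtration" = "polish", "superose" = "polish"
)

#' Agent backends
#'
#' `rules_backend()` is the deterministic, offline rule-based backend used
#' throughout testing: a pure function of its inputs, so repeated runs are
#' identical. `callable_backend()` wraps any function (e.g. an adapter for
#' a remote model endpoint) behind the same contract; its raw output is
#' schema-validated and retried up to `retries` times before an
#' `rescuerank_agent_failure` is raised. Remote endpoints and credentials
#' are adapter concerns of the supplied function.
#'
#' @param fn For `callable_backend`, a `function(role, payload, ...)`
#'   returning the role's output type (extractor: character; summarizer:
#'   `protocol_table`; optimizer: `optimization_report`).
#' @param name Backend identifier.
#' @param retries Validation-failure retries before giving up (default 2).
#' @return An object of class `agent_backend`.
#' @export
rules_backend <- function() {
  structure(list(name = "rules", deterministic = TRUE, fn = NULL,
                 retries = 0L),
            class = "agent_backend")
}

#' @rdname rules_backend
#' @export
callable_backend <- function(fn, name = "remote", retries = 2L) {
  if (!is.function(fn)) {
    rr_error("callable_backend requires a function", "rescuerank_config_error")
  }
  structure(list(name = name, deterministic = FALSE, fn = fn,
                 retries = as.integer(retries)),
            class = "agent_backend")
}

# Run a pluggable backend with bounded retries and a validator; the rules
# backend never passes through here.
call_backend <- function(backend, role, payload, validator) {
  last <- NULL
  for (attempt in seq_len(backend$retries + 1L)) {
    out <- tryCatch(backend$fn(role, payload, attempt = attempt),
                    error = function(e) e)
    if (!inherits(out, "error")) {
      ok <- tryCatch({
        validator(out)
        TRUE
      }, error = function(e) {
        last <<- e
        FALSE
      })
      if (ok) return(out)
    } else {
      last <- out
    }
  }
  rr_error(paste0("backend '", backend$name, "' failed ", role,
                  " validation after ", backend$retries + 1L, " attempt(s): ",
                  conditionMessage(last)),
           "rescuerank_agent_failure")
}

#' Extract purification-protocol text from a methods section
#'
#' The rules backend splits the methods text into sentences, scores each by
#' the number of purification-lexicon terms it contains, and returns the
#' sentences scoring at least `min_terms`, concatenated in order. The
#' output is always a subset of the input sentences — nothing is
#' synthesized. Raises `rescuerank_empty_protocol` (carrying nothing
#' extractable) when no sentence qualifies.
#'
#' @param methods A `methods_text` from [find_methods_section()], or a
#'   character scalar.
#' @param backend An `agent_backend`.
#' @param min_terms Minimum lexicon terms per retained sentence (default 1).
#' @return Character scalar of extracted protocol text.
#' @export
extract_purification_text <- function(methods, backend = rules_backend(),
                                      min_terms = 1L) {
  text <- if (inherits(methods, "methods_text")) methods$text else methods
  if (!nzchar(trimws(text))) {
    rr_error("empty methods text", "rescuerank_empty_protocol")
  }
  sentences <- split_sentences(text)
  validator <- function(out) {
    stopifnot(is.character(out), length(out) == 1L)
    out_s <- squish(out)
    in_s <- squish(text)
    for (s in split_sentences(out)) {
      if (!grepl(squish(s), in_s, fixed = TRUE)) {
        stop("extractor output is not a subset of its input")
      }
    }
    invisible(out_s)
  }
  if (backend$name != "rules" && !is.null(backend$fn)) {
    return(call_backend(backend, "extractor", text, validator))
  }
  lex <- tolower(read_lexicon("purification.txt",
                              default_purification_lexicon))
  scores <- vapply(sentences, function(s) {
    sl <- tolower(s)
    sum(vapply(lex, function(term) grepl(term, sl, fixed = TRUE), TRUE))
  }, numeric(1))
  keep <- sentences[scores >= min_terms]
  if (!length(keep)) {
    rr_error("no purification-related sentences found",
             "rescuerank_empty_protocol")
  }
  paste(keep, collapse = " ")
}

# Extract the verbatim matched substring for a set of lexicon terms.
match_verbatim <- function(text, terms) {
  found <- character(0)
  for (term in terms) {
    m <- regexpr(term, text, ignore.case = TRUE, fixed = FALSE)
    if (m[1L] != -1L) found <- c(found, regmatches(text, m))
  }
  unique(found)
}

#' Summarize protocol text into the standardized six-column table
#'
#' The rules backend segments the text into steps on chromatography/step
#' keywords (a sentence containing a step keyword opens a new step;
#' keyword-free sentences extend the current one), then extracts per step:
#' the step label (the verbatim keyword occurrence), the buffer name
#' (`"... buffer"` phrases), the composition (the verbatim span covering
#' all recognized concentration mentions), the pH (`pH <number>`), the
#' salt type (salt lexicon) and supplements (additive lexicon, joined with
#' `"; "`). Every emitted value appears verbatim (whitespace-normalized)
#' in the input. Text with no step keyword yields a single-step table with
#' a warning.
#'
#' @param protocol_text Non-empty protocol text.
#' @param backend An `agent_backend`.
#' @param provenance Optional provenance attached to the table.
#' @return A validated `protocol_table`.
#' @export
summarize_protocol <- function(protocol_text, backend = rules_backend(),
                               provenance = NULL) {
  if (!nzchar(trimws(protocol_text))) {
    rr_error("empty protocol text", "rescuerank_validation_error")
  }
  validator <- function(out) {
    stopifnot(inherits(out, "protocol_table"))
    validate_table(out)
  }
  if (backend$name != "rules" && !is.null(backend$fn)) {
    return(call_backend(backend, "summarizer", protocol_text, validator))
  }
  salts <- read_lexicon("salts.txt", default_salt_lexicon)
  supps <- read_lexicon("supplements.txt", default_supplement_lexicon)
  sentences <- split_sentences(protocol_text)
  warnings <- character(0)

  # segment: first step keyword (by position in the sentence) labels it
  seg_label <- character(0)
  seg_text <- character(0)
  for (s in sentences) {
    sl <- tolower(s)
    pos <- vapply(names(step_keyword_categories), function(kw) {
      p <- regexpr(kw, sl, fixed = TRUE)
      if (p[1L] == -1L) NA_integer_ else as.integer(p[1L])
    }, integer(1))
    if (all(is.na(pos))) {
      if (length(seg_text)) {
        seg_text[length(seg_text)] <- paste(seg_text[length(seg_text)], s)
      } else {
        seg_label <- c(seg_label, NA_character_)
        seg_text <- c(seg_text, s)
      }
    } else {
      kw <- names(step_keyword_categories)[which.min(pos)]
      # verbatim occurrence of the keyword (word-extended to the right)
      m <- regexpr(paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", kw),
                          "[A-Za-z-]*"), s, ignore.case = TRUE)
      seg_label <- c(seg_label, regmatches(s, m))
      seg_text <- c(seg_text, s)
    }
  }
  if (all(is.na(seg_label))) {
    warnings <- c(warnings, "unsegmentable text: emitted a single step")
    seg_text <- paste(seg_text, collapse = " ")
    first <- squish(seg_text)
    seg_label <- substr(first, 1L, min(nchar(first), 60L))
  }
  steps <- vector("list", length(seg_text))
  conc_pat <- paste0("[0-9]+(?:\\.[0-9]+)?\\s*",
                     "(?:mM|M|%|mg/m[lL]|[uµ]g/m[lL])\\s+",
                     "[A-Za-z][A-Za-z0-9βα\\-()/]*")
  for (i in seq_along(seg_text)) {
    s <- seg_text[i]
    label <- seg_label[i]
    if (is.na(label)) label <- substr(squish(s), 1L, 60L)
    bn <- regmatches(s, regexpr("\\b[A-Za-z][A-Za-z-]*[ ]buffer\\b", s,
                                ignore.case = TRUE))
    phm <- regmatches(s, regexec("pH\\s*([0-9]+(?:\\.[0-9]+)?)", s))[[1L]]
    ph <- if (length(phm)) as.numeric(phm[2L]) else NA_real_
    if (!is.na(ph) && (ph < 0 || ph > 14)) {
      warnings <- c(warnings,
                    paste0("implausible pH ", ph, " in step ", i,
                           " set to NA"))
      ph <- NA_real_
    }
    salt <- match_verbatim(s, salts)
    supp <- match_verbatim(s, supps)
    # keep the most specific supplement matches (drop terms that are
    # substrings of another match, e.g. "protease inhibitor" within
    # "protease inhibitor cocktail")
    if (length(supp) > 1L) {
      supp <- supp[!vapply(seq_along(supp), function(k) {
        any(grepl(tolower(supp[k]), tolower(supp[-k]), fixed = TRUE))
      }, TRUE)]
    }
    cm <- gregexpr(conc_pat, s, perl = TRUE)[[1L]]
    comp <- NA_character_
    if (cm[1L] != -1L) {
      start <- cm[1L]
      end <- cm[length(cm)] + attr(cm, "match.length")[length(cm)] - 1L
      comp <- substr(s, start, end)
    }
    steps[[i]] <- protocol_step(
      purification_step = label,
      buffer_name = if (length(bn)) bn[1L] else NA_character_,
      buffer_composition = comp,
      ph = ph,
      salt_type = if (length(salt)) salt[1L] else NA_character_,
      buffer_supplement = if (length(supp)) paste(supp, collapse = "; ")
      else NA_character_
    )
  }
  if (length(warnings)) {
    rr_warn(paste(warnings, collapse = "; "))
  }
  validate_table(
    protocol_table(do.call(rbind, steps), provenance = provenance,
                   warnings = warnings)
  )
}

#' Generate an optimization report from protocol differences
#'
#' The rules backend wraps [diff_protocols()] and applies rule templates:
#' each observed difference becomes a recommendation to move the failed
#' parameter toward the successful range, with confidence `high` when at
#' least three successes exhibit the difference, `medium` for two and
#' `low` for one. Target annotations add annotation-driven
#' recommendations regardless of the diffs (a transmembrane span suggests
#' a mild detergent; a signal peptide suggests construct truncation), at
#' low confidence. The revised protocol is the failed protocol with
#' numeric parameters moved to the successful median and missing
#' supplements appended. With no successes the report carries
#' annotations-only recommendations.
#'
#' @param failed The failed-baseline `protocol_table`.
#' @param successes List of successful `protocol_table`s (may be empty).
#' @param annotations Named character vector or list of target annotations
#'   (e.g. `c(transmembrane = "62-84")`).
#' @param backend An `agent_backend`.
#' @return An object of class `optimization_report`: `differences` (with
#'   `recommendation`, `confidence`, `source` columns), `revised_protocol`
#'   (a `protocol_table`), `annotations_considered`.
#' @export
optimize_protocol <- function(failed, successes, annotations = NULL,
                              backend = rules_backend()) {
  validator <- function(out) {
    stopifnot(inherits(out, "optimization_report"))
    stopifnot(all(c("recommendation", "confidence") %in%
                    names(out$differences)))
    validate_table(out$revised_protocol)
  }
  if (backend$name != "rules" && !is.null(backend$fn)) {
    return(call_backend(
      backend, "optimizer",
      list(failed = failed, successes = successes,
           annotations = annotations),
      validator
    ))
  }
  diffs <- if (length(successes)) diff_protocols(failed, successes)
  else data.frame(parameter = character(0), step_category = character(0),
                  failed_value = character(0),
                  successful_values = character(0), delta = numeric(0),
                  n_support = integer(0), stringsAsFactors = FALSE)
  confidence_of <- function(n) {
    if (n >= 3L) "high" else if (n == 2L) "medium" else "low"
  }
  rec <- character(nrow(diffs))
  conf <- character(nrow(diffs))
  for (i in seq_len(nrow(diffs))) {
    d <- diffs[i, ]
    rec[i] <- if (startsWith(d$parameter, "supplement: ")) {
      paste0("Add ", sub("^supplement: ", "", d$parameter), " to the ",
             d$step_category, " buffer, as used in successful protocols.")
    } else if (!is.na(d$delta)) {
      paste0("Adjust ", d$parameter, " in the ", d$step_category,
             " step from ", d$failed_value, " toward the successful range (",
             d$successful_values, ").")
    } else {
      paste0("Consider replacing ", d$parameter, " ", d$failed_value,
             " in the ", d$step_category, " step with ",
             d$successful_values, ".")
    }
    conf[i] <- confidence_of(d$n_support)
  }
  diffs$recommendation <- rec
  diffs$confidence <- conf
  diffs$source <- rep("literature", nrow(diffs))

  ann_labels <- character(0)
  if (!is.null(annotations) && length(annotations)) {
    ann_labels <- names(annotations)
    for (k in seq_along(annotations)) {
      label <- names(annotations)[k]
      value <- as.character(annotations[[k]])
      arow <- NULL
      if (grepl("transmembrane", label, ignore.case = TRUE)) {
        arow <- data.frame(
          parameter = paste0("annotation: ", label),
          step_category = "lysis", failed_value = NA_character_,
          successful_values = NA_character_,
          delta = NA_real_, n_support = 0L,
          recommendation = paste0(
            "Target carries a transmembrane span (", value,
            "): include a mild detergent (e.g. DDM or CHAPS) in lysis and ",
            "purification buffers to keep it soluble."),
          confidence = "low", source = "annotation",
          stringsAsFactors = FALSE
        )
      } else if (grepl("signal[ _-]?peptide", label, ignore.case = TRUE)) {
        arow <- data.frame(
          parameter = paste0("annotation: ", label),
          step_category = NA_character_, failed_value = NA_character_,
          successful_values = NA_character_,
          delta = NA_real_, n_support = 0L,
          recommendation = paste0(
            "Target carries a signal peptide (", value,
            "): consider truncating it from the construct or harvesting ",
            "from the secreted/periplasmic fraction."),
          confidence = "low", source = "annotation",
          stringsAsFactors = FALSE
        )
      }
      if (!is.null(arow)) diffs <- rbind(diffs, arow)
    }
  }
  rownames(diffs) <- NULL

  # revised protocol: failed steps with numeric parameters moved to the
  # successful median and missing supplements appended
  revised <- as.data.frame(failed, stringsAsFactors = FALSE)
  rcat <- step_category(revised$purification_step, revised$buffer_name)
  lit <- diffs[diffs$source == "literature", , drop = FALSE]
  for (i in seq_len(nrow(lit))) {
    d <- lit[i, ]
    j <- which(rcat == d$step_category)[1L]
    if (is.na(j)) next
    if (d$parameter == "ph" && !is.na(d$delta)) {
      revised$ph[j] <- as.numeric(d$failed_value) + d$delta
    } else if (startsWith(d$parameter, "supplement: ")) {
      supp <- sub("^supplement: ", "", d$parameter)
      cur <- revised$buffer_supplement[j]
      revised$buffer_supplement[j] <- if (is.na(cur) || !nzchar(cur)) supp
      else paste(cur, supp, sep = "; ")
    } else if (!is.na(d$delta)) {
      comp <- sub("\\s*\\(.*\\)$", "", d$parameter)
      target <- as.numeric(d$failed_value) + d$delta
      unit <- sub("^.*\\(([^)]*)\\)$", "\\1", d$parameter)
      esc <- function(x) gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", x)
      # replace only the number so the verbatim component casing survives
      revised$buffer_composition[j] <- sub(
        paste0("[0-9]+(?:\\.[0-9]+)?(?=\\s*", esc(unit), "\\s+",
               esc(comp), ")"),
        format(target, trim = TRUE),
        revised$buffer_composition[j], perl = TRUE, ignore.case = TRUE
      )
    }
  }
  structure(
    list(differences = diffs,
         revised_protocol = protocol_table(revised),
         annotations_considered = ann_labels),
    class = "optimization_report"
  )
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("Optimization report:", nrow(x$differences), "difference(s)/",
      "recommendation(s);", length(x$annotations_considered),
      "annotation(s) considered\n")
  if (nrow(x$differences)) {
    print.data.frame(x$differences[, c("parameter", "failed_value",
                                       "successful_values", "confidence")])
  }
  invisible(x)
}

#' Read a target annotation key-value file
#'
#' Simple `key = value` (or `key\tvalue`) lines, e.g.
#' `transmembrane = 62-84`, `signal_peptide = 1-22`.
#'
#' @param path Path to the annotation file.
#' @return Named character vector (possibly empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    rr_error(paste0("annotation file not found: ", path),
             "rescuerank_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  kv <- strsplit(lines, "\\s*=\\s*|\t")
  stats::setNames(
    vapply(kv, function(x) trimws(paste(x[-1L], collapse = " ")), ""),
    vapply(kv, function(x) trimws(x[1L]), "")
  )
}
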
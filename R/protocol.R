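# The standardized six-column purification protocol table and the
# comparative machinery built on it: step-category alignment, buffer
# component parsing, protocol diffing, and report rendering.

#' The six standardized protocol columns, in canonical order
#' @format Character vector of length 6.
#' @export
protocol_columns <- c(
  "purification_step", "buffer_name", "buffer_composition",
  "ph", "salt_type", "buffer_supplement"
)

# Step-category lexicon used to align steps across protocols. Patterns are
# matched case-insensitively against the step label and, failing that, the
# buffer name. Categories are tried in order, stage words (elution, wash,
# polish) before resin/column words, so a label like "HisTrap column -
# Elution" lands on elution rather than capture.
step_category_lexicon <- list(
  elution  = c("elut"),
  wash     = c("wash"),
  polish   = c("size[- ]exclusion", "superdex", "gel filtration",
               "sec\\b", "polish", "superose"),
  cleavage = c("cleav", "dialys", "tev", "3c protease"),
  lysis    = c("lysis", "lyse", "sonicat", "homogeniz", "resuspend"),
  capture  = c("bind", "equilibrat", "equihbrat", "load", "histrap",
               "ni[ -]?sepharose", "imac", "capture", "affinity", "talon")
)

#' Construct one purification protocol step
#'
#' @param purification_step Non-empty free-text step label.
#' @param buffer_name,buffer_composition,salt_type,buffer_supplement
#'   Optional strings (`NA` when absent).
#' @param ph Optional pH in \[0, 14\].
#' @return A one-row data.frame with the six standardized columns.
#' @export
protocol_step <- function(purification_step, buffer_name = NA_character_,
                          buffer_composition = NA_character_,
                          ph = NA_real_, salt_type = NA_character_,
                          buffer_supplement = NA_character_) {
  data.frame(
    purification_step = as.character(purification_step),
    buffer_name = as.character(buffer_name),
    buffer_composition = as.character(buffer_composition),
    ph = as.numeric(ph),
    salt_type = as.character(salt_type),
    buffer_supplement = as.character(buffer_supplement),
    stringsAsFactors = FALSE
  )
}

#' Assemble a protocol table with provenance
#'
#' @param steps A data.frame of rows built with [protocol_step()] (or with
#'   the same six columns), in protocol order.
#' @param provenance Either the string `"failed baseline"` or a list with
#'   `article_title`, `url`, `organism`, `similarity_score`; `NULL` for
#'   tables of unknown origin.
#' @param warnings Character vector of extraction warnings.
#' @return A data.frame of class `protocol_table`; provenance and warnings
#'   are carried as attributes.
#' @export
protocol_table <- function(steps, provenance = NULL, warnings = character(0)) {
  missing_cols <- setdiff(protocol_columns, names(steps))
  if (length(missing_cols)) {
    rr_error(paste0("protocol table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "rescuerank_validation_error")
  }
  steps <- as.data.frame(steps, stringsAsFactors = FALSE)[protocol_columns]
  rownames(steps) <- NULL
  structure(steps, provenance = provenance, warnings = warnings,
            class = c("protocol_table", "data.frame"))
}

#' Validate a protocol table
#'
#' Checks that the six standardized columns are present in order, that
#' every step label is non-empty, and that any pH present lies in
#' \[0, 14\]. Returns the table unchanged when valid; otherwise raises a
#' `rescuerank_validation_error` naming the offending step and field.
#'
#' @param table A `protocol_table`.
#' @return The validated table, invisibly identical to the input.
#' @export
validate_table <- function(table) {
  if (!identical(names(table)[seq_along(protocol_columns)],
                 protocol_columns)) {
    rr_error("columns must be the six standardized fields in order",
             "rescuerank_validation_error")
  }
  bad_label <- which(is.na(table$purification_step) |
                       !nzchar(trimws(table$purification_step)))
  if (length(bad_label)) {
    rr_error(paste0("step ", bad_label[1L],
                    ": purification_step must be non-empty"),
             "rescuerank_validation_error")
  }
  bad_ph <- which(!is.na(table$ph) & (table$ph < 0 | table$ph > 14))
  if (length(bad_ph)) {
    rr_error(paste0("step ", bad_ph[1L], ": ph ", table$ph[bad_ph[1L]],
                    " outside [0, 14]"),
             "rescuerank_validation_error")
  }
  table
}

#' @export
print.protocol_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  if (identical(prov, "failed baseline")) {
    cat("Protocol table (failed baseline),", nrow(x), "step(s)\n")
  } else if (is.list(prov)) {
    cat("Protocol table from \"", prov$article_title, "\", ",
        nrow(x), " step(s)\n", sep = "")
  } else {
    cat("Protocol table,", nrow(x), "step(s)\n")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read a protocol table as CSV with the six fixed headers
#'
#' Absent cells are written as `None`, mirroring the tabular summary
#' convention; `None` and empty cells read back as `NA`. pH values using a
#' decimal comma are repaired with a warning; unparseable or out-of-range
#' pH values are kept as `NA` with a warning rather than silently
#' corrected.
#'
#' @param table A `protocol_table`.
#' @param path CSV path.
#' @return `write_protocol_csv`: invisibly, `path`. `read_protocol_csv`:
#'   a `protocol_table`.
#' @export
write_protocol_csv <- function(table, path) {
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (cc in protocol_columns) {
    v <- as.character(out[[cc]])
    v[is.na(v)] <- "None"
    out[[cc]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(protocol_columns, names(raw))
  if (length(missing_cols)) {
    rr_error(paste0("CSV lacks column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "rescuerank_validation_error")
  }
  warnings <- character(0)
  for (cc in protocol_columns) {
    raw[[cc]][raw[[cc]] %in% c("", "None", "NA")] <- NA_character_
  }
  ph_chr <- raw$ph
  comma <- !is.na(ph_chr) & grepl("^[0-9]+,[0-9]+$", ph_chr)
  if (any(comma)) {
    warnings <- c(warnings, paste0("decimal-comma pH repaired in step(s) ",
                                   paste(which(comma), collapse = ", ")))
    ph_chr[comma] <- sub(",", ".", ph_chr[comma], fixed = TRUE)
  }
  ph <- suppressWarnings(as.numeric(ph_chr))
  out_of_range <- !is.na(ph) & (ph < 0 | ph > 14)
  if (any(out_of_range)) {
    warnings <- c(warnings,
                  paste0("implausible pH ", ph_chr[out_of_range][1L],
                         " in step ", which(out_of_range)[1L],
                         " set to NA"))
    ph[out_of_range] <- NA_real_
  }
  raw$ph <- ph
  protocol_table(raw, warnings = warnings)
}

#' Infer the step category of protocol step labels
#'
#' Categories (`lysis`, `capture`, `wash`, `elution`, `cleavage`,
#' `polish`) are assigned from a keyword lexicon matched against the step
#' label and, when that fails, the buffer name.
#'
#' @param labels Character vector of step labels.
#' @param buffer_names Optional character vector of buffer names used as a
#'   fallback cue.
#' @return Character vector of categories; `NA` when no pattern matches.
#' @export
step_category <- function(labels, buffer_names = NULL) {
  out <- rep(NA_character_, length(labels))
  for (cat in names(step_category_lexicon)) {
    pat <- paste(step_category_lexicon[[cat]], collapse = "|")
    m <- is.na(out) & grepl(pat, labels, ignore.case = TRUE)
    if (!is.null(buffer_names)) {
      m <- m | (is.na(out) & !is.na(buffer_names) &
                  grepl(pat, buffer_names, ignore.case = TRUE))
    }
    out[m] <- cat
  }
  out
}

#' Parse named component concentrations from buffer composition text
#'
#' Recognizes `number unit component` triples with units `mM`, `M`, `%`,
#' `mg/ml` and `ug/ml`/`µg/ml`, tolerant of punctuation between
#' components. Component names are lowercased for comparison; molar units
#' are normalized to mM and mass units to mg/ml.
#'
#' @param text Composition free text (vectorized).
#' @return A data.frame with `component`, `value`, `unit` (normalized),
#'   one row per recognized mention.
#' @export
parse_concentrations <- function(text) {
  pat <- paste0(
    "([0-9]+(?:\\.[0-9]+)?)\\s*",
    "(mM|M|%|mg/m[lL]|[uµ]g/m[lL])\\s+",
    "([A-Za-z][A-Za-z0-9βα\\-()/]*(?:\\s+inhibitor(?:\\s+cocktail)?)?)"
  )
  rows <- list()
  for (txt in text) {
    if (is.na(txt)) next
    m <- gregexpr(pat, txt, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (piece in regmatches(txt, list(m))[[1L]]) {
      g <- regmatches(piece, regexec(pat, piece, perl = TRUE))[[1L]]
      value <- as.numeric(g[2L])
      unit <- g[3L]
      if (unit == "M") {
        value <- value * 1000
        unit <- "mM"
      } else if (grepl("^[uµ]g", unit)) {
        value <- value / 1000
        unit <- "mg/ml"
      } else if (grepl("^mg", unit)) {
        unit <- "mg/ml"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = tolower(trimws(g[4L])), value = value, unit = unit,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(component = character(0), value = numeric(0),
                      unit = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Split a multi-valued supplement cell on the "; " convention.
split_supplements <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Parameter-level differences between a failed protocol and successes
#'
#' Steps are aligned across protocols by inferred step category, then
#' compared per parameter: pH, salt type, named component concentrations
#' parsed from the composition text, and supplements present in successes
#' but absent from the failed protocol. For numeric parameters `delta` is
#' the median successful value minus the failed value, so swapping the
#' roles of failed and successful protocols flips its sign.
#'
#' @param failed The failed-baseline `protocol_table`.
#' @param successes A list of successful `protocol_table`s.
#' @return A data.frame of class `protocol_diff`: `parameter`,
#'   `step_category`, `failed_value`, `successful_values` (collapsed,
#'   `" | "`-separated), `delta` (`NA` for categorical parameters),
#'   `n_support` (successes exhibiting the difference). Empty (with a
#'   message) when no steps align.
#' @export
diff_protocols <- function(failed, successes) {
  if (!nrow(failed)) {
    rr_error("failed protocol has no steps", "rescuerank_validation_error")
  }
  if (!length(successes)) {
    rr_error("at least one successful protocol is required",
             "rescuerank_validation_error")
  }
  empty <- data.frame(
    parameter = character(0), step_category = character(0),
    failed_value = character(0), successful_values = character(0),
    delta = numeric(0), n_support = integer(0), stringsAsFactors = FALSE
  )
  fcat <- step_category(failed$purification_step, failed$buffer_name)
  rows <- list()
  cats <- unique(fcat[!is.na(fcat)])
  aligned_any <- FALSE
  for (cat in cats) {
    frow <- failed[which(fcat == cat)[1L], ]
    srows <- list()
    for (s in successes) {
      scat <- step_category(s$purification_step, s$buffer_name)
      k <- which(scat == cat)
      if (length(k)) srows[[length(srows) + 1L]] <- s[k[1L], ]
    }
    if (!length(srows)) next
    aligned_any <- TRUE
    # pH
    sph <- vapply(srows, function(r) r$ph, numeric(1))
    sph_known <- sph[!is.na(sph)]
    if (!is.na(frow$ph) && length(sph_known) &&
        any(abs(sph_known - frow$ph) > 1e-9)) {
      differing <- sph_known[abs(sph_known - frow$ph) > 1e-9]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = "ph", step_category = cat,
        failed_value = format(frow$ph),
        successful_values = paste(format(sph_known), collapse = " | "),
        delta = stats::median(sph_known) - frow$ph,
        n_support = length(differing), stringsAsFactors = FALSE
      )
    }
    # salt type
    ssalt <- vapply(srows, function(r) as.character(r$salt_type),
                    character(1))
    ssalt_known <- ssalt[!is.na(ssalt)]
    if (!is.na(frow$salt_type) && length(ssalt_known)) {
      differing <- ssalt_known[tolower(ssalt_known) !=
                                 tolower(frow$salt_type)]
      if (length(differing)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = "salt_type", step_category = cat,
          failed_value = frow$salt_type,
          successful_values = paste(unique(ssalt_known), collapse = " | "),
          delta = NA_real_, n_support = length(differing),
          stringsAsFactors = FALSE
        )
      }
    }
    # named component concentrations
    fconc <- parse_concentrations(frow$buffer_composition)
    sconc <- lapply(srows, function(r) {
      parse_concentrations(r$buffer_composition)
    })
    for (comp in unique(fconc$component)) {
      fv <- fconc$value[fconc$component == comp][1L]
      funit <- fconc$unit[fconc$component == comp][1L]
      sv <- unlist(lapply(sconc, function(d) {
        d$value[d$component == comp & d$unit == funit]
      }))
      if (length(sv) && any(abs(sv - fv) > 1e-9)) {
        differing <- sv[abs(sv - fv) > 1e-9]
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = paste0(comp, " (", funit, ")"), step_category = cat,
          failed_value = format(fv),
          successful_values = paste(format(sv), collapse = " | "),
          delta = stats::median(sv) - fv, n_support = length(differing),
          stringsAsFactors = FALSE
        )
      }
    }
    # supplements present in successes, absent from failed
    fsupp <- tolower(c(split_supplements(frow$buffer_supplement),
                       fconc$component))
    for (supp in unique(tolower(unlist(lapply(srows, function(r) {
      split_supplements(r$buffer_supplement)
    }))))) {
      supp_core <- tolower(sub("^[0-9.]+\\s*\\S+\\s+", "", supp))
      present <- any(vapply(fsupp, function(f) {
        grepl(supp_core, f, fixed = TRUE) || grepl(f, supp_core, fixed = TRUE)
      }, TRUE))
      if (!present) {
        n_sup <- sum(vapply(srows, function(r) {
          any(grepl(supp_core, tolower(split_supplements(r$buffer_supplement)),
                    fixed = TRUE))
        }, TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = paste0("supplement: ", supp_core), step_category = cat,
          failed_value = "absent",
          successful_values = supp,
          delta = NA_real_, n_support = n_sup, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!aligned_any) {
    message("diff_protocols: no alignable steps between failed and successes")
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("protocol_diff", "data.frame")
  out
}

protocol_table_to_list <- function(table) {
  steps <- as.data.frame(table, stringsAsFactors = FALSE)[protocol_columns]
  list(steps = steps, provenance = attr(table, "provenance"))
}

list_to_protocol_table <- function(x) {
  steps <- as.data.frame(x$steps, stringsAsFactors = FALSE)
  steps$ph <- as.numeric(steps$ph)
  prov <- x$provenance
  if (is.data.frame(prov)) prov <- as.list(prov[1L, , drop = FALSE])
  if (is.list(prov)) {
    prov <- lapply(prov, function(v) if (is.null(v)) NA else v)
    if (!is.null(prov$similarity_score)) {
      prov$similarity_score <- as.numeric(prov$similarity_score)
    }
  }
  protocol_table(steps, provenance = prov)
}

#' Render the consolidated rescue report
#'
#' Emits both a Markdown and a JSON variant containing, in order: the
#' ranked homolog list with all score components, one six-column table per
#' mined protocol with its provenance, the failed baseline table (when
#' given), and the optimization section with differences and the revised
#' protocol. With zero mined protocols the report states that no
#' accessible literature was found and omits the optimization section.
#'
#' @param ranked A `scored_hits` data.frame (possibly empty).
#' @param tables List of mined `protocol_table`s.
#' @param optimization An `optimization_report` from [optimize_protocol()],
#'   or `NULL`.
#' @param failed The failed-baseline `protocol_table`, or `NULL`.
#' @return A list of class `rescue_report` with elements `markdown`
#'   (character scalar) and `json` (character scalar).
#' @export
render_report <- function(ranked, tables, optimization = NULL,
                          failed = NULL) {
  md <- c("# Protein purification rescue report", "")
  md <- c(md, "## Ranked homologs", "")
  if (!is.null(ranked) && nrow(ranked)) {
    md <- c(md,
            "| rank | subject | pident | S_seq | S_taxa | S_overall |",
            "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(ranked))) {
      md <- c(md, sprintf("| %d | %s | %.1f | %.4f | %.4f | %.4f |",
                          i, ranked$sseqid[i], ranked$pident[i],
                          ranked$s_seq[i], ranked$s_taxa[i],
                          ranked$s_overall[i]))
    }
  } else {
    md <- c(md, "No candidate homologs passed the filters.")
  }
  md <- c(md, "", "## Mined purification protocols", "")
  if (!length(tables)) {
    md <- c(md, "No accessible literature yielded a purification protocol.")
  }
  fmt_cell <- function(v) {
    v <- as.character(v)
    ifelse(is.na(v) | !nzchar(v), "None", v)
  }
  render_table_md <- function(tb) {
    out <- c(
      paste("| Purification step | Buffer name | Buffer composition |",
            "pH | Salt type | Buffer supplement |"),
      "|---|---|---|---|---|---|"
    )
    for (i in seq_len(nrow(tb))) {
      out <- c(out, paste0(
        "| ", paste(vapply(protocol_columns, function(cc) {
          fmt_cell(tb[[cc]][i])
        }, ""), collapse = " | "), " |"
      ))
    }
    out
  }
  for (tb in tables) {
    prov <- attr(tb, "provenance")
    if (is.list(prov)) {
      md <- c(md, paste0("### ", prov$article_title), "",
              paste0("Source: ", prov$url, " | organism: ", prov$organism,
                     " | similarity: ",
                     format(prov$similarity_score, digits = 4)), "")
    } else {
      md <- c(md, "### Mined protocol", "")
    }
    md <- c(md, render_table_md(tb), "")
  }
  if (!is.null(failed)) {
    md <- c(md, "## Failed protocol (baseline)", "",
            render_table_md(failed), "")
  }
  if (!is.null(optimization) && length(tables)) {
    md <- c(md, "## Optimization", "")
    if (nrow(optimization$differences)) {
      md <- c(md,
              paste("| parameter | step | failed | successful |",
                    "recommendation | confidence |"),
              "|---|---|---|---|---|---|")
      d <- optimization$differences
      for (i in seq_len(nrow(d))) {
        md <- c(md, sprintf("| %s | %s | %s | %s | %s | %s |",
                            d$parameter[i], fmt_cell(d$step_category[i]),
                            fmt_cell(d$failed_value[i]),
                            fmt_cell(d$successful_values[i]),
                            d$recommendation[i], d$confidence[i]))
      }
      md <- c(md, "", "### Revised protocol", "",
              render_table_md(optimization$revised_protocol))
    } else {
      md <- c(md, "No differences between the failed and mined protocols.")
    }
  }
  json_obj <- list(
    ranked_hits = if (!is.null(ranked)) {
      as.data.frame(ranked, stringsAsFactors = FALSE)
    } else data.frame(),
    protocols = lapply(tables, protocol_table_to_list),
    failed_baseline = if (!is.null(failed)) {
      protocol_table_to_list(failed)
    } else NULL,
    optimization = if (!is.null(optimization) && length(tables)) {
      list(
        differences = as.data.frame(optimization$differences,
                                    stringsAsFactors = FALSE),
        revised_protocol = as.data.frame(optimization$revised_protocol,
                                         stringsAsFactors = FALSE),
        annotations_considered = optimization$annotations_considered
      )
    } else NULL
  )
  json <- jsonlite::toJSON(json_obj, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  structure(
    list(markdown = paste(md, collapse = "\n"),
         json = as.character(json)),
    class = "rescue_report"
  )
}

#' Re-parse the JSON variant of a rescue report
#'
#' Inverse of the JSON emitted by [render_report()]: protocol tables come
#' back as `protocol_table` objects structurally equal to the inputs.
#'
#' @param json JSON string (or path to a `.json` file).
#' @return A list with `ranked_hits`, `protocols`, `failed_baseline`,
#'   `optimization`.
#' @export
parse_report <- function(json) {
  if (length(json) == 1L && !grepl("[{\\[]", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                          simplifyVector = TRUE)
  protocols <- lapply(
    if (is.data.frame(x$protocols)) split(x$protocols,
                                          seq_len(nrow(x$protocols)))
    else x$protocols,
    list_to_protocol_table
  )
  names(protocols) <- NULL
  list(
    ranked_hits = x$ranked_hits,
    protocols = protocols,
    failed_baseline = if (!is.null(x$failed_baseline)) {
      list_to_protocol_table(x$failed_baseline)
    } else NULL,
    optimization = x$optimization
  )
}
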
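table1_lysis_sentence <- paste(
  "Cells were lysed in lysis buffer containing 20 mM HEPES, 300 mM NaCl,",
  "5% glycerol, 30 mM Imidazole, 0.5% CHAPS, 10 mM MgCl2,",
  "3 mM β-mercaptoethanol, pH 7.4."
)

test_that("the extractor keeps only purification sentences, verbatim", {
  methods <- paste(
    "The gene was amplified by PCR and ligated into a vector.",
    "Cultures were grown at 37 degrees in rich medium.",
    "Cells were lysed by sonication in lysis buffer with 300 mM NaCl.",
    "The lysate was loaded onto a HisTrap column and eluted with 500 mM Imidazole.",
    "Crystals grew in two weeks."
  )
  out <- extract_purification_text(methods)
  expect_match(out, "lysed by sonication", fixed = TRUE)
  expect_match(out, "HisTrap column", fixed = TRUE)
  expect_false(grepl("amplified by PCR", out, fixed = TRUE))
  expect_false(grepl("Crystals", out, fixed = TRUE))
})

test_that("methods with no purification vocabulary raise an empty-protocol error", {
  expect_error(
    extract_purification_text(
      "The gene was sequenced. Data were analyzed with custom scripts."
    ),
    class = "rescuerank_empty_protocol"
  )
})

test_that("extractor output is always a sentence subset of its input", {
  dir <- withr::local_tempdir()
  arts <- make_articles(fixture_spec(seed = 11, n_articles = 8), dir)
  for (a in arts$articles) {
    doc <- parse_jats(file.path(dir, "articles",
                                paste0(a$article_id, ".xml")),
                      a$article_id)
    methods <- find_methods_section(doc)
    out <- extract_purification_text(methods)
    in_norm <- gsub("\\s+", " ", methods$text)
    for (s in strsplit(out, "(?<=[.!?])\\s+", perl = TRUE)[[1]]) {
      expect_true(grepl(gsub("\\s+", " ", s), in_norm, fixed = TRUE))
    }
  }
})

test_that("a lysis-row sentence summarizes to pH 7.4 with NaCl", {
  tab <- summarize_protocol(table1_lysis_sentence)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$ph, 7.4)
  expect_equal(tab$salt_type, "NaCl")
  expect_equal(step_category(tab$purification_step), "lysis")
  expect_match(tab$buffer_supplement, "glycerol")
  expect_match(tab$buffer_supplement, "CHAPS")
})

test_that("an elution sentence summarizes to an elution step at pH 7.0", {
  tab <- summarize_protocol(
    "The protein was eluted with 25 mM HEPES, 300 mM NaCl, 500 mM Imidazole, pH 7.0."
  )
  expect_equal(step_category(tab$purification_step), "elution")
  expect_equal(tab$ph, 7.0)
  expect_equal(tab$salt_type, "NaCl")
  expect_match(tab$buffer_composition, "500 mM Imidazole", fixed = TRUE)
})

test_that("text with no recognizable entities yields one warned step", {
  expect_warning(
    tab <- summarize_protocol("The sample was processed as described."),
    "single step"
  )
  expect_equal(nrow(tab), 1L)
  expect_true(is.na(tab$ph))
  expect_true(is.na(tab$salt_type))
  expect_true(is.na(tab$buffer_supplement))
})

test_that("summarizer output is grounded verbatim in its input", {
  dir <- withr::local_tempdir()
  arts <- make_articles(fixture_spec(seed = 13, n_articles = 6), dir)
  for (a in arts$articles) {
    text <- a$protocol_text
    tab <- summarize_protocol(text)
    in_norm <- gsub("\\s+", " ", text)
    for (col in c("purification_step", "buffer_name",
                  "buffer_composition", "salt_type")) {
      for (v in tab[[col]]) {
        if (is.na(v)) next
        expect_true(grepl(gsub("\\s+", " ", v), in_norm, fixed = TRUE),
                    label = paste(col, v))
      }
    }
    for (cell in tab$buffer_supplement) {
      if (is.na(cell)) next
      for (piece in trimws(strsplit(cell, ";")[[1]])) {
        expect_true(grepl(piece, in_norm, fixed = TRUE), label = piece)
      }
    }
    for (p in tab$ph) {
      if (is.na(p)) next
      expect_true(grepl(paste0("pH ", format(p)), in_norm, fixed = TRUE))
    }
  }
})

test_that("the rules backend is deterministic", {
  text <- paste(
    "Cells were lysed in lysis buffer with 300 mM NaCl and lysozyme.",
    "Protein was eluted with elution buffer containing 500 mM Imidazole, pH 7.0."
  )
  expect_identical(summarize_protocol(text), summarize_protocol(text))
  expect_identical(extract_purification_text(text),
                   extract_purification_text(text))
})

test_that("planted protocols summarize back to their manifest rows", {
  dir <- withr::local_tempdir()
  arts <- make_articles(fixture_spec(seed = 17, n_articles = 4), dir)
  for (a in arts$articles) {
    tab <- summarize_protocol(a$protocol_text)
    expect_equal(nrow(tab), length(a$expected_rows))
    cats <- step_category(tab$purification_step, tab$buffer_name)
    for (i in seq_along(a$expected_rows)) {
      exp_row <- a$expected_rows[[i]]
      expect_equal(cats[i], exp_row$category)
      expect_equal(tab$ph[i], exp_row$ph)
      expect_equal(tab$salt_type[i], exp_row$salt)
      expect_equal(tab$buffer_composition[i], exp_row$composition)
      got_supp <- sort(tolower(trimws(
        strsplit(tab$buffer_supplement[i], ";")[[1]]
      )))
      expect_equal(got_supp, exp_row$supplements)
    }
  }
})

test_that("identical failed and success protocols optimize to no recommendations", {
  tab <- protocol_table(protocol_step(
    "Lysis", "lysis buffer", "20 mM HEPES, 300 mM NaCl", 7.4, "NaCl", NA
  ))
  rep <- optimize_protocol(tab, list(tab))
  expect_equal(nrow(rep$differences), 0L)
  expect_length(rep$annotations_considered, 0L)
})

test_that("a planted imidazole difference drives a confident recommendation", {
  failed <- protocol_table(protocol_step(
    "Elution", "elution buffer", "300 mM NaCl, 250 mM Imidazole",
    7.0, "NaCl", NA
  ))
  success <- protocol_table(protocol_step(
    "Elution", "elution buffer", "300 mM NaCl, 500 mM Imidazole",
    7.0, "NaCl", NA
  ))
  one <- optimize_protocol(failed, list(success))
  expect_equal(nrow(one$differences), 1L)
  expect_match(one$differences$recommendation, "imidazole")
  expect_equal(one$differences$confidence, "low")

  two <- optimize_protocol(failed, list(success, success))
  expect_equal(two$differences$confidence, "medium")
  three <- optimize_protocol(failed, list(success, success, success))
  expect_equal(three$differences$confidence, "high")

  # revised protocol moves the concentration toward the successful median
  expect_match(three$revised_protocol$buffer_composition,
               "500 mM Imidazole", fixed = TRUE)
})

test_that("annotations drive recommendations even with no diffs", {
  tab <- protocol_table(protocol_step(
    "Lysis", "lysis buffer", "20 mM HEPES, 300 mM NaCl", 7.4, "NaCl", NA
  ))
  rep <- optimize_protocol(tab, list(tab),
                           annotations = c(transmembrane = "62-84",
                                           signal_peptide = "1-22"))
  ann <- rep$differences[rep$differences$source == "annotation", ]
  expect_equal(nrow(ann), 2L)
  expect_match(ann$recommendation[1], "detergent")
  expect_match(ann$recommendation[2], "signal peptide")
  expect_true(all(ann$confidence == "low"))
  expect_setequal(rep$annotations_considered,
                  c("transmembrane", "signal_peptide"))

  # with no successes at all, annotation-only recommendations survive
  none <- optimize_protocol(tab, list(),
                            annotations = c(transmembrane = "10-30"))
  expect_equal(nrow(none$differences), 1L)
  expect_equal(none$differences$source, "annotation")
})

test_that("nonconforming pluggable-backend output is retried then rejected", {
  calls <- 0L
  flaky <- callable_backend(function(role, payload, attempt) {
    calls <<- calls + 1L
    if (calls < 3L) return("not a protocol table")
    summarize_protocol(payload)
  }, retries = 2L)
  tab <- summarize_protocol(
    "Protein was eluted with elution buffer, 500 mM Imidazole, pH 7.0.",
    backend = flaky
  )
  expect_s3_class(tab, "protocol_table")
  expect_equal(calls, 3L)

  always_bad <- callable_backend(function(role, payload, attempt) {
    "still not a table"
  }, retries = 2L)
  expect_error(
    summarize_protocol("Protein was eluted with 500 mM Imidazole.",
                       backend = always_bad),
    class = "rescuerank_agent_failure"
  )
})

test_that("a grounded pluggable extractor passes validation, an inventing one fails", {
  text <- "Protein was purified on a column with elution buffer."
  echo <- callable_backend(function(role, payload, attempt) payload,
                           name = "echo")
  expect_equal(extract_purification_text(text, backend = echo), text)
  liar <- callable_backend(function(role, payload, attempt) {
    "A fabricated step never present in the input."
  }, retries = 0L)
  expect_error(extract_purification_text(text, backend = liar),
               class = "rescuerank_agent_failure")
})
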
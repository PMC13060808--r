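# A constructed six-step His-tag purification summary in the standardized
# table layout (lysis through size exclusion), used across these tests.
example_summary_table <- function() {
  protocol_table(rbind(
    protocol_step("Lysis", "lysis buffer",
                  paste("20 mM HEPES, 300 mM NaCl, 5% glycerol,",
                        "30 mM Imidazole, 0.5% CHAPS, 10 mM MgCl2,",
                        "3 mM β-mercaptoethanol"),
                  7.4, "NaCl",
                  "protease inhibitor cocktail; lysozyme"),
    protocol_step("HisTrap FF 5 ml column - Equilibration/Binding",
                  "binding buffer",
                  "25 mM HEPES, 300 mM NaCl, 5% Glycerol, 30 mM Imidazole, 1 mM DTT",
                  7.0, "NaCl", NA),
    protocol_step("HisTrap FF 5 ml column - Elution", NA,
                  "25 mM HEPES, 300 mM NaCl, 5% Glycerol, 500 mM Imidazole, 1 mM DTT",
                  7.0, "NaCl", NA),
    protocol_step("Cleavage - Dialysis", "cleavage buffer",
                  "20 mM HEPES, 500 mM NaCl, 5% Glycerol, 1 mM TCEP",
                  7.6, "NaCl", NA),
    protocol_step("Ni Sepharose 6 Fast Flow resin - Wash", "wash buffer",
                  "20 mM HEPES, 300 mM NaCl, 40 mM imidazole, 1 mM TCEP 5% glycerol",
                  7.0, "NaCl", NA),
    protocol_step("Superdex 75 26/60 column - Equilibration", "SEC buffer",
                  "20 mM HEPES, 300 mM NaCl, 5% glycerol and 1 mM TCEP",
                  7.0, "NaCl", NA)
  ))
}

test_that("a realistic six-step summary table passes validation", {
  tab <- example_summary_table()
  expect_identical(validate_table(tab), tab)
  expect_equal(names(tab), protocol_columns)
})

test_that("validation names the offending step and field", {
  bad_ph <- protocol_table(protocol_step("Lysis", ph = 15))
  expect_error(validate_table(bad_ph), "ph 15",
               class = "rescuerank_validation_error")
  bad_label <- protocol_table(protocol_step("x"))
  bad_label$purification_step <- ""
  expect_error(validate_table(bad_label), "purification_step",
               class = "rescuerank_validation_error")
  expect_error(protocol_table(data.frame(purification_step = "x")),
               class = "rescuerank_validation_error")
})

test_that("CSV round trip preserves the table and renders absent as None", {
  tab <- example_summary_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_protocol_csv(tab, path)
  raw <- utils::read.csv(path, colClasses = "character")
  expect_equal(names(raw), protocol_columns)
  expect_equal(raw$buffer_name[3], "None")
  back <- read_protocol_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("transcription artifacts in pH cells warn instead of passing through", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(protocol_columns, collapse = ","),
    "Binding,binding buffer,25 mM HEPES,70,NaCI,None",
    "Dialysis,cleavage buffer,20 mM HEPES,\"7,6\",NaCI,None"
  ), path)
  back <- read_protocol_csv(path)
  expect_true(is.na(back$ph[1]))       # "70" is implausible, not corrected
  expect_equal(back$ph[2], 7.6)        # decimal comma repaired
  expect_gt(length(attr(back, "warnings")), 0L)
  expect_identical(validate_table(back), back)
})

test_that("step categories are inferred from labels and buffer names", {
  tab <- example_summary_table()
  expect_equal(
    step_category(tab$purification_step, tab$buffer_name),
    c("lysis", "capture", "elution", "cleavage", "wash", "polish")
  )
  expect_true(is.na(step_category("mystery step")))
})

test_that("concentration parsing covers the composition grammar", {
  conc <- parse_concentrations(
    "25 mM HEPES, 0.3 M NaCl, 5% glycerol, 500 mM Imidazole, 1.3 mg/ml protease inhibitor cocktail"
  )
  expect_equal(conc$value[conc$component == "hepes"], 25)
  expect_equal(conc$value[conc$component == "nacl"], 300)  # M -> mM
  expect_equal(conc$unit[conc$component == "glycerol"], "%")
  expect_equal(conc$value[conc$component == "imidazole"], 500)
  expect_equal(conc$value[conc$component == "protease inhibitor cocktail"],
               1.3)
  expect_equal(nrow(parse_concentrations("no numbers here")), 0L)
})

test_that("identical protocols diff to an empty difference list", {
  tab <- example_summary_table()
  d <- diff_protocols(tab, list(tab))
  expect_equal(nrow(d), 0L)
})

test_that("planted differences are recovered with direction", {
  failed <- protocol_table(protocol_step(
    "Elution", "elution buffer",
    "25 mM HEPES, 300 mM NaCl, 250 mM Imidazole", 7.0, "NaCl", NA
  ))
  success <- protocol_table(protocol_step(
    "Elution", "elution buffer",
    "25 mM HEPES, 300 mM NaCl, 500 mM Imidazole", 7.0, "NaCl", NA
  ))
  d <- diff_protocols(failed, list(success))
  expect_equal(nrow(d), 1L)
  expect_equal(d$parameter, "imidazole (mM)")
  expect_equal(d$delta, 250)

  # anti-symmetry: swapping failed and success flips the sign
  d_rev <- diff_protocols(success, list(failed))
  expect_equal(d_rev$delta, -250)
})

test_that("supplements present only in successes are reported", {
  failed <- protocol_table(protocol_step(
    "Lysis", "lysis buffer", "20 mM HEPES, 300 mM NaCl", 7.4, "NaCl", NA
  ))
  success <- protocol_table(protocol_step(
    "Lysis", "lysis buffer", "20 mM HEPES, 300 mM NaCl", 7.4, "NaCl",
    "glycerol; lysozyme"
  ))
  d <- diff_protocols(failed, list(success))
  expect_setequal(d$parameter,
                  c("supplement: glycerol", "supplement: lysozyme"))
  expect_true(all(d$failed_value == "absent"))
})

test_that("no alignable steps yields an empty diff with a notice", {
  failed <- protocol_table(protocol_step("mystery step"))
  success <- protocol_table(protocol_step("Lysis"))
  expect_message(d <- diff_protocols(failed, list(success)),
                 "no alignable")
  expect_equal(nrow(d), 0L)
})

test_that("reports render both variants and the JSON re-parses to its inputs", {
  tree <- taxonomy_tree(small_two_domain_nodes())
  hits <- make_hit_rows(2)
  hits$staxid <- c(7, 8)
  ranked <- rank_hits(score_hits(hits, tree, query_taxon = 6))
  tab <- example_summary_table()
  mined <- protocol_table(as.data.frame(tab), provenance = list(
    article_title = "Worked purification", url = "https://example.org/a1",
    organism = "species_7", similarity_score = 0.81
  ))
  failed <- protocol_table(as.data.frame(tab),
                           provenance = "failed baseline")
  opt <- optimize_protocol(failed, list(mined))
  rep <- render_report(ranked, list(mined), optimization = opt,
                       failed = failed)
  expect_match(rep$markdown, "Ranked homologs")
  expect_match(rep$markdown, "Worked purification")
  expect_match(rep$markdown, "Failed protocol")

  back <- parse_report(rep$json)
  expect_equal(as.data.frame(back$protocols[[1]]), as.data.frame(mined))
  expect_equal(attr(back$protocols[[1]], "provenance"),
               attr(mined, "provenance"))
  expect_equal(as.data.frame(back$failed_baseline), as.data.frame(failed))
  expect_equal(back$ranked_hits$sseqid, ranked$sseqid)
})

test_that("every rendered table row has exactly the six columns in order", {
  tab <- example_summary_table()
  rep <- render_report(NULL, list(tab))
  header <- "| Purification step | Buffer name | Buffer composition | pH | Salt type | Buffer supplement |"
  expect_true(grepl(header, rep$markdown, fixed = TRUE))
  table_lines <- grep("^\\|", strsplit(rep$markdown, "\n")[[1]],
                      value = TRUE)
  cells <- vapply(table_lines, function(l) {
    length(strsplit(l, "|", fixed = TRUE)[[1]]) - 1L
  }, 1L)
  expect_true(all(cells == 6L))
})

test_that("a report with no mined protocols says so and omits optimization", {
  rep <- render_report(NULL, list())
  expect_match(rep$markdown, "No accessible literature")
  expect_false(grepl("## Optimization", rep$markdown, fixed = TRUE))
  back <- parse_report(rep$json)
  expect_length(back$protocols, 0L)
  expect_null(back$optimization)
})
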
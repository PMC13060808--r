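# Internal helpers: typed conditions, seed scoping, text utilities.

rr_error <- function(message, class, ...) {
  stop(structure(
    class = c(class, "rescuerank_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

rr_warn <- function(message, class = "rescuerank_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Collapse runs of whitespace and trim; used for verbatim-grounding checks.
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

# Sentence segmentation shared by the extraction and summarization rules.
split_sentences <- function(text) {
  text <- gsub("\r\n?", "\n", text)
  out <- unlist(strsplit(text, "(?<=[.!?])\\s+(?=[A-Z(])", perl = TRUE))
  out <- out[nzchar(squish(out))]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a plain-text lexicon (one entry per line, '#' comments allowed),
# falling back to a built-in default when the installed file is absent.
read_lexicon <- function(name, default) {
  path <- system.file("extdata", "lexicons", name, package = "rescuerank")
  if (nzchar(path) && file.exists(path)) {
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x <- trimws(x[!grepl("^\\s*(#|$)", x)])
    if (length(x)) return(x)
  }
  default
}
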
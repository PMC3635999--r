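# Shared internal helpers.

#' Normalize a phrase or free-text string for matching
#'
#' Lowercases, collapses every run of non-alphanumeric characters to a single
#' space and strips leading/trailing whitespace.  The same normalization is
#' applied to lexicon phrases and to gene description text, so dictionary
#' matching is case-insensitive and robust to punctuation.
#'
#' @param x character vector.
#' @return character vector of normalized strings.
#' @export
#' @examples
#' normalize_phrase("Parkinson's Disease")  # "parkinson s disease"
normalize_phrase <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# log(sum(exp(lx))) with max subtraction; -Inf-safe
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

# Classed error helper.  Classes used across the package:
#   oe_usage_error  - bad configuration / arguments (CLI exit 1)
#   oe_data_error   - malformed or inconsistent input data (CLI exit 2)
#   oe_domain_error - numeric argument outside its domain (CLI exit 2)
oe_stop <- function(msg, class = "oe_data_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `code` under a fixed Mersenne-Twister state, restoring the caller's
# RNG state afterwards.  Keeps fixture generation reproducible without
# clobbering user randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic TSV writer used for all package output files
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) oe_stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      oe_stop(sprintf("%s is missing required column(s): %s",
                      path, paste(miss, collapse = ", ")))
    }
  }
  df
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
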
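#' @importFrom data.table data.table as.data.table := .N .SD setkey setkeyv
#'   setnames setorder fwrite fread rbindlist fifelse uniqueN setDT copy
NULL

#' Normalize query text
#'
#' Lowercases, replaces every run of non-alphanumeric characters with a single
#' space, and trims. The same normalization is applied to query texts and to
#' lexicon synonyms, so that matching and news filtering operate on identical
#' strings.
#'
#' @param x character vector.
#' @return character vector of normalized texts.
#' @export
#' @examples
#' normalize_text("Is Marijuana legal in Ohio?")
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# Run code under a local RNG state: seeds deterministically, restores the
# caller's .Random.seed on exit so generators do not perturb user RNG streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
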
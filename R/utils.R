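# Internal helpers: seed streams and TSV io conventions.

#' Derive a reproducible substream seed from a master seed and a key
#'
#' Per-recording random streams are derived from one master seed plus a string
#' key (e.g. "S003/baseline/rest") with a multiplicative string hash, so any
#' subset of subjects or sessions can be regenerated without simulating the
#' rest of the cohort.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer((h + (abs(master) %% m) * 48271) %% m)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the conventions used by all pipeline artifacts:
#' header row, tab separator, no quoting, `NA` for missing.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table()` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero-length vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
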
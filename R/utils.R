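BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed from a master seed
#'
#' Small integer hash used to key independent random streams (per population,
#' per generation, per pipeline stage) off one master seed, so that runs are
#' reproducible while streams stay decoupled.
#'
#' @param seed master integer seed.
#' @param ... further integer or character keys.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  keys <- list(...)
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = ""))) else k <- as.double(k)
    x <- (x * 48271 + k + 11) %% 2147483647
    x <- (x * 69621) %% 2147483647
  }
  as.integer(x %% 2147483629)
}

## Half-open [start, end) window grid over one chromosome.  Windows start at
## 0, step `stepBp`; a chromosome shorter than one window yields a single
## truncated window (flagged via the `truncated` column).
windowGrid <- function(chromLength, windowBp, stepBp) {
  if (chromLength < windowBp) {
    return(data.frame(start = 0L, end = as.integer(chromLength),
                      truncated = TRUE))
  }
  starts <- seq.int(0L, as.integer(chromLength - windowBp), by = as.integer(stepBp))
  data.frame(start = starts, end = starts + as.integer(windowBp),
             truncated = FALSE)
}

## Stable (chrom, pos) ordering used everywhere: chromosomes alphabetically,
## positions numerically within chromosome.
siteOrder <- function(chrom, pos) order(chrom, pos)

siteKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a
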
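# The 20 standard amino acids, in the conventional (alphabetical by
# three-letter code) order used for profile score rows.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHARS <- c("-", ".")

#' Interval width under the 1-based inclusive coordinate convention
#'
#' All genomic coordinates in famscan are 1-based and inclusive (the GFF3
#' convention). This helper is the single place where +/- 1 interval
#' arithmetic happens.
#'
#' @param start,end integer vectors of 1-based inclusive interval bounds.
#' @return integer vector of widths in bp.
#' @export
iv_width <- function(start, end) {
  as.integer(end) - as.integer(start) + 1L
}

#' One-decimal percentage, rounded half away from zero
#'
#' Computes `100 * k / n` rounded to one decimal with halves rounded away
#' from zero, the convention used throughout the family summary (e.g.
#' 12/124 -> 9.7, 28/124 -> 22.6).
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @return numeric percentage with one decimal.
#' @export
percent1 <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  x <- 100 * k / n
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

fs_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
fs_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# chromosome ordering: the order chromosomes are declared in the genome
# (the generator and readers put the unanchored pseudo-chromosome first).
chrom_rank <- function(chrom, genome) {
  match(chrom, genome$chromosomes$name)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
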
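#' Poisson-corrected distance matrix with pairwise deletion
#'
#' For each sequence pair, alignment columns where either sequence has a
#' gap are removed (pairwise deletion); `p` is the proportion of
#' differing sites among the remaining columns and the Poisson-corrected
#' distance is `d = -ln(1 - p)`.
#'
#' @param aligned named character vector of equal-length aligned
#'   amino-acid sequences.
#' @return object of class `distance_matrix`: list with `labels`, `p`
#'   (observed difference proportions) and `d` (corrected distances),
#'   both symmetric matrices with zero diagonals.
#' @export
poisson_distance_matrix <- function(aligned) {
  n <- length(aligned)
  if (n < 2L) fs_stop("need at least 2 sequences")
  if (is.null(names(aligned))) fs_stop("sequences must be named")
  lens <- unique(nchar(aligned))
  if (length(lens) != 1L) fs_stop("aligned sequences must be equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  gap <- matrix(mat %in% GAP_CHARS, nrow = n)
  labels <- names(aligned)
  p <- d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      keep <- !gap[i, ] & !gap[j, ]
      if (!any(keep)) {
        fs_stop("pair (%s, %s) has no comparable columns",
                labels[[i]], labels[[j]])
      }
      pij <- mean(mat[i, keep] != mat[j, keep])
      if (pij >= 1) {
        fs_stop("pair (%s, %s) differs at every comparable site; %s",
                labels[[i]], labels[[j]],
                "Poisson distance undefined")
      }
      p[i, j] <- p[j, i] <- pij
      d[i, j] <- d[j, i] <- -log(1 - pij)
    }
  }
  structure(list(labels = labels, p = p, d = d),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Poisson-corrected distance matrix over %d sequences\n",
              length(x$labels)))
  cat(sprintf("  p range [%.3f, %.3f], d range [%.3f, %.3f]\n",
              min(x$p[upper.tri(x$p)]), max(x$p[upper.tri(x$p)]),
              min(x$d[upper.tri(x$d)]), max(x$d[upper.tri(x$d)])))
  invisible(x)
}
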
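#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 amino-acid substitution scores over the 20
#' standard residues plus `X` (scored -1 against everything), used as the
#' default for pairwise and progressive protein alignment.
#'
#' @return 21 x 21 integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  m <- matrix(NA_integer_, 21L, 21L,
              dimnames = list(c(AA20, "X"), c(AA20, "X")))
  m[seq_len(20L), seq_len(20L)] <- matrix(as.integer(v), 20L, 20L,
                                          byrow = TRUE)
  m["X", ] <- -1L
  m[, "X"] <- -1L
  m
}

# encode a residue string as 0-based indices into the substitution
# alphabet; unknown letters map to X
.encode_aa <- function(seq, alphabet = c(AA20, "X")) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], alphabet)
  idx[is.na(idx)] <- length(alphabet)
  idx - 1L
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment. A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`. Traceback ties are broken
#' deterministically: match preferred over a gap in `a`, preferred over a
#' gap in `b`.
#'
#' @param a,b non-empty amino-acid strings.
#' @param substitution_matrix square score matrix with residue dimnames
#'   (default [blosum62()]).
#' @param gap_open,gap_extend affine gap parameters (score units).
#' @return a `pairwise_alignment`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings) and `score`.
#' @export
global_align <- function(a, b, substitution_matrix = blosum62(),
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) fs_stop("sequences must be non-empty")
  alpha <- rownames(substitution_matrix)
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  res <- cpp_gotoh(.encode_aa(toupper(a), alpha), .encode_aa(toupper(b), alpha),
                   substitution_matrix + 0.0, gap_open, gap_extend)
  aa <- ifelse(res$ai == 0L, "-", ca[pmax(res$ai, 1L)])
  bb <- ifelse(res$bi == 0L, "-", cb[pmax(res$bi, 1L)])
  structure(list(aligned_a = paste(aa, collapse = ""),
                 aligned_b = paste(bb, collapse = ""),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment, score %.1f\n%s\n%s\n",
              x$score, x$aligned_a, x$aligned_b))
  invisible(x)
}

#' Identity and coverage of a pairwise alignment
#'
#' `alignment_similarity()` is the fraction of identical positions over
#' aligned (non-double-gap) columns; gap-versus-residue columns count as
#' mismatches. `alignment_coverage()` is the number of columns where both
#' sequences have a residue, divided by the length of the longer
#' (ungapped) sequence.
#'
#' @param aln a `pairwise_alignment`.
#' @return a fraction in `[0, 1]`.
#' @export
alignment_similarity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  keep <- !(ca == "-" & cb == "-")
  sum(ca[keep] == cb[keep]) / sum(keep)
}

#' @rdname alignment_similarity
#' @export
alignment_coverage <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  paired <- sum(ca != "-" & cb != "-")
  paired / max(sum(ca != "-"), sum(cb != "-"))
}

#' Progressive multiple alignment of protein sequences
#'
#' A deliberately small progressive aligner for the pipeline's synthetic
#' end-to-end path: pairwise Gotoh identities give a distance matrix, an
#' average-linkage guide tree orders the merges, and profiles are merged
#' by profile-profile Needleman-Wunsch with count-weighted mean BLOSUM62
#' column scores. For real data a dedicated MSA tool is expected; the
#' pipeline accepts any precomputed alignment.
#'
#' @param seqs named character vector of >= 2 protein sequences.
#' @param substitution_matrix square score matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap parameters.
#' @return named character vector of equal-length aligned sequences, in
#'   input order.
#' @export
align_proteins <- function(seqs, substitution_matrix = blosum62(),
                           gap_open = 10, gap_extend = 1) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  alpha <- rownames(substitution_matrix)
  if (n == 2L) {
    aln <- global_align(seqs[[1L]], seqs[[2L]], substitution_matrix,
                        gap_open, gap_extend)
    return(stats::setNames(c(aln$aligned_a, aln$aligned_b), names(seqs)))
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- global_align(seqs[[i]], seqs[[j]], substitution_matrix,
                          gap_open, gap_extend)
      D[i, j] <- D[j, i] <- 1 - alignment_similarity(aln)
    }
  }
  guide <- stats::hclust(stats::as.dist(D), method = "average")

  as_mat <- function(s) matrix(strsplit(s, "", fixed = TRUE)[[1L]],
                               nrow = 1L)
  counts <- function(mat) {
    apply(mat, 2L, function(col) {
      col <- col[!(col %in% GAP_CHARS)]
      tabulate(match(col, alpha), nbins = length(alpha))
    })
  }
  profiles <- vector("list", n - 1L)
  get_profile <- function(k) {
    if (k < 0) list(mat = as_mat(seqs[[-k]]), rows = names(seqs)[-k])
    else profiles[[k]]
  }
  for (step in seq_len(n - 1L)) {
    a <- get_profile(guide$merge[step, 1L])
    b <- get_profile(guide$merge[step, 2L])
    fa <- counts(a$mat); fb <- counts(b$mat)
    if (is.null(dim(fa))) fa <- matrix(fa, ncol = 1L)
    if (is.null(dim(fb))) fb <- matrix(fb, ncol = 1L)
    res <- cpp_profile_nw(fa + 0.0, fb + 0.0, substitution_matrix + 0.0,
                          gap_open, gap_extend)
    na <- nrow(a$mat); nb <- nrow(b$mat); L <- length(res$ai)
    merged <- matrix("-", na + nb, L)
    merged[seq_len(na), res$ai != 0L] <- a$mat[, res$ai[res$ai != 0L],
                                               drop = FALSE]
    merged[na + seq_len(nb), res$bi != 0L] <- b$mat[, res$bi[res$bi != 0L],
                                                    drop = FALSE]
    profiles[[step]] <- list(mat = merged, rows = c(a$rows, b$rows))
  }
  final <- profiles[[n - 1L]]
  out <- apply(final$mat, 1L, paste, collapse = "")
  names(out) <- final$rows
  out[names(seqs)]
}
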
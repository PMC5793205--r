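#' Build a log-odds domain profile from a seed alignment
#'
#' Each retained alignment column yields a vector of log-odds scores (in
#' bits) over the 20 standard amino acids:
#' `score(a) = log2(((count_a + pseudocount * bg_a) / (n + pseudocount)) / bg_a)`
#' where `n` is the number of residues observed in the column. Columns
#' with more than 50% gaps are dropped; `X` residues are ignored for
#' counting.
#'
#' @param seed_alignment named character vector of >= 2 aligned (equal
#'   length) amino-acid sequences; gaps are `-` or `.`.
#' @param pseudocount positive Laplace-style pseudocount weight.
#' @param background amino-acid background frequencies (named over the 20
#'   residues, summing to 1); default uniform.
#' @return an object of class `domain_profile` with elements `scores`
#'   (20 x ncols matrix, bits), `background`, `ncols`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL) {
  if (length(seed_alignment) < 2L) {
    fs_stop("seed alignment needs at least 2 sequences")
  }
  if (pseudocount <= 0) fs_stop("pseudocount must be > 0")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1L) {
    fs_stop("aligned sequences must have equal lengths (got %s)",
            paste(unique(lens), collapse = ", "))
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA20)
  }
  if (abs(sum(background) - 1) > 1e-12) {
    fs_stop("background frequencies must sum to 1")
  }
  background <- background[AA20]
  mat <- do.call(rbind, strsplit(toupper(seed_alignment), "", fixed = TRUE))
  gap_frac <- colMeans(matrix(mat %in% GAP_CHARS, nrow = nrow(mat)))
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0L) fs_stop("all alignment columns are majority-gap")
  scores <- vapply(keep, function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    counts <- tabulate(match(col, AA20), nbins = 20L)
    n <- length(col)
    log2(((counts + pseudocount * background) / (n + pseudocount)) /
           background)
  }, numeric(20L))
  rownames(scores) <- AA20
  structure(list(scores = scores, background = background,
                 ncols = length(keep)),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("domain profile: %d columns, max per-column score %.2f bits\n",
              x$ncols, max(apply(x$scores, 2L, max))))
  invisible(x)
}

#' Scan a protein with a domain profile (glocal alignment)
#'
#' Dynamic-programming alignment in which the profile is global (every
#' column is matched or deleted, with affine internal gap costs) and the
#' target is local (free overhangs on both sides, affine internal
#' insertions). The best placement is reported as a hit when its score
#' reaches `report_threshold`; `profile_coverage` is the fraction of
#' profile columns matched to a residue.
#'
#' @param protein amino-acid string.
#' @param profile a `domain_profile`.
#' @param gap_open,gap_extend affine gap parameters (bits); a gap of
#'   length k costs `gap_open + (k - 1) * gap_extend`.
#' @param report_threshold minimum score (bits) to report a hit.
#' @return a `domain_hit` (list with `score`, `profile_span`,
#'   `target_span`, `profile_coverage`, `matched`) or `NULL` when no
#'   placement reaches the threshold or the protein is empty.
#' @export
scan_profile <- function(protein, profile, gap_open = 11, gap_extend = 1,
                         report_threshold = 0) {
  stopifnot(inherits(profile, "domain_profile"))
  if (is.na(protein) || !nzchar(protein)) return(NULL)
  res_codes <- .encode_aa(toupper(protein), c(AA20, "X")) + 1L
  score_rows <- rbind(profile$scores, X = 0)  # unknown residue scores 0
  S <- t(score_rows)[, res_codes, drop = FALSE]  # ncols x target length
  res <- cpp_glocal(S, gap_open, gap_extend)
  if (res$score < report_threshold) return(NULL)
  matched <- res$matched
  hit_cols <- which(matched > 0L)
  if (length(hit_cols) == 0L) return(NULL)
  structure(list(score = res$score,
                 profile_span = range(hit_cols),
                 target_span = range(matched[hit_cols]),
                 profile_coverage = length(hit_cols) / profile$ncols,
                 matched = matched),
            class = "domain_hit")
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf(
    "domain hit: %.1f bits, profile cols %d-%d, target %d-%d, coverage %.2f\n",
    x$score, x$profile_span[1L], x$profile_span[2L],
    x$target_span[1L], x$target_span[2L], x$profile_coverage))
  invisible(x)
}
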
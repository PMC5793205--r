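# Average (not monoisotopic) residue masses in Da; MW of a peptide is the
# sum of residue masses plus one water (18.0153 Da). X contributes the
# mean residue mass and no charge.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Default pKa set for isoelectric-point calculation
#'
#' ExPASy/Bjellqvist-style values: N-terminus 9.094, C-terminus 2.869,
#' side chains C 7.555, D 3.872, E 4.412, H 5.637, K 9.052, R 11.84,
#' Y 10.85.
#'
#' @return named numeric vector of pKa values.
#' @export
default_pka <- function() {
  c(Nterm = 9.094, Cterm = 2.869, C = 7.555, D = 3.872, E = 4.412,
    H = 5.637, K = 9.052, R = 11.84, Y = 10.85)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and
#' ionizable side chains (C, D, E, H, K, R, Y).
#'
#' @param seq amino-acid string.
#' @param pH pH value(s).
#' @param pka pKa set as from [default_pka()].
#' @return net charge (vectorized over `pH`).
#' @export
peptide_charge <- function(seq, pH, pka = default_pka()) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = c(AA20, "X")))
  pos_groups <- c(Nterm = 1, K = unname(counts[["K"]]),
                  R = unname(counts[["R"]]), H = unname(counts[["H"]]))
  neg_groups <- c(Cterm = 1, D = unname(counts[["D"]]),
                  E = unname(counts[["E"]]), C = unname(counts[["C"]]),
                  Y = unname(counts[["Y"]]))
  charge <- rep(0, length(pH))
  for (g in names(pos_groups)) {
    if (pos_groups[[g]] > 0) {
      charge <- charge + pos_groups[[g]] / (1 + 10^(pH - pka[[g]]))
    }
  }
  for (g in names(neg_groups)) {
    if (neg_groups[[g]] > 0) {
      charge <- charge - neg_groups[[g]] / (1 + 10^(pka[[g]] - pH))
    }
  }
  charge
}

#' Length, molecular weight and isoelectric point of proteins
#'
#' Molecular weight uses average residue masses plus one water per chain
#' (the ExPASy convention); the isoelectric point is found by bisection
#' on the net-charge curve until `|charge| < tol`.
#'
#' @param seqs character vector of amino-acid sequences (20 standard
#'   residues plus `X`); names, if present, become the `id` column.
#' @param pka pKa set (see [default_pka()]).
#' @param tol net-charge tolerance at the returned pI.
#' @return data.frame with columns `id`, `length`, `molecular_weight`
#'   (Da) and `isoelectric_point`.
#' @export
protein_stats <- function(seqs, pka = default_pka(), tol = 1e-4) {
  ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs))
         else names(seqs)
  mass_x <- mean(AA_MASS)
  rows <- lapply(seq_along(seqs), function(k) {
    s <- toupper(seqs[[k]])
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), c(AA20, "X"))
    if (length(bad)) {
      fs_stop("illegal residue '%s' in %s", bad[[1L]], ids[[k]])
    }
    masses <- ifelse(chars == "X", mass_x, AA_MASS[chars])
    mw <- sum(masses) + WATER_MASS
    lo <- 0; hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- peptide_charge(s, mid, pka)
      if (abs(q) < tol || (hi - lo) < 1e-12) break
      if (q > 0) lo <- mid else hi <- mid
    }
    data.frame(id = ids[[k]], length = length(chars),
               molecular_weight = mw, isoelectric_point = mid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
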
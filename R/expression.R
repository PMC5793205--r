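#' Normalize an FPKM matrix (grand-mean equalization + log2)
#'
#' The raw FPKM values are equalized by the single grand mean of the
#' whole matrix (one scalar), then log2-transformed after adding a small
#' pseudocount so FPKM of zero stays finite. A per-row alternative is
#' available via `by_row = TRUE` for comparison.
#'
#' @param m numeric matrix of FPKM values (genes x conditions, all
#'   >= 0).
#' @param pseudocount added before log2 (default 0.01).
#' @param by_row equalize each row by its own mean instead of the grand
#'   mean (default FALSE).
#' @return object of class `expression_matrix`: list with `fpkm` (raw),
#'   `equalized` and `logged` views.
#' @export
normalize_matrix <- function(m, pseudocount = 0.01, by_row = FALSE) {
  if (!is.matrix(m) || length(m) == 0L) fs_stop("matrix must be non-empty")
  if (any(!is.finite(m)) || any(m < 0)) {
    fs_stop("FPKM values must be finite and >= 0")
  }
  if (mean(m) <= 0) fs_stop("all-zero matrix cannot be equalized")
  equalized <- if (by_row) {
    rm <- rowMeans(m)
    if (any(rm <= 0)) fs_stop("row with zero mean cannot be row-equalized")
    m / rm
  } else {
    m / mean(m)
  }
  structure(list(fpkm = m, equalized = equalized,
                 logged = log2(equalized + pseudocount),
                 pseudocount = pseudocount),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d conditions (grand mean %.3g)\n",
              nrow(x$fpkm), ncol(x$fpkm), mean(x$fpkm)))
  invisible(x)
}

#' Split genes into expressed and barely-expressed sets
#'
#' A gene is excluded when its raw FPKM is below `threshold` in every
#' condition ("barely expressed"); a gene at or above the threshold in
#' at least one condition is kept (the boundary value is kept, strict
#' `<`).
#'
#' @param m raw FPKM matrix (genes x conditions) or an
#'   `expression_matrix`.
#' @param threshold FPKM cutoff (default 2).
#' @return list with `kept` and `excluded` gene-name vectors.
#' @export
filter_expressed <- function(m, threshold = 2.0) {
  if (inherits(m, "expression_matrix")) m <- m$fpkm
  low <- apply(m, 1L, function(x) all(x < threshold))
  list(kept = rownames(m)[!low], excluded = rownames(m)[low])
}

#' Average-linkage hierarchical clustering of expression rows
#'
#' UPGMA-style agglomeration on Euclidean distances between logged
#' expression rows (the heatmap row ordering); average linkage is
#' monotone so merge heights never decrease. Rendering a heatmap is an
#' optional side effect (requires the pheatmap package).
#'
#' @param logged numeric matrix of log2 expression values (>= 2 rows,
#'   unique rownames, all finite) or an `expression_matrix` (its
#'   `logged` view is used).
#' @param metric `"euclidean"` (default) or `"correlation"` row distance.
#' @param heatmap_file optional path to write a heatmap image.
#' @return an `hclust` object.
#' @export
cluster_heatmap <- function(logged, metric = c("euclidean", "correlation"),
                            heatmap_file = NULL) {
  metric <- match.arg(metric)
  if (inherits(logged, "expression_matrix")) logged <- logged$logged
  if (nrow(logged) < 2L) fs_stop("need at least 2 rows to cluster")
  if (is.null(rownames(logged)) || anyDuplicated(rownames(logged))) {
    fs_stop("rows must have unique labels")
  }
  if (any(!is.finite(logged))) fs_stop("rows contain non-finite values")
  d <- if (metric == "euclidean") {
    stats::dist(logged)
  } else {
    stats::as.dist(1 - stats::cor(t(logged)))
  }
  hc <- stats::hclust(d, method = "average")
  if (!is.null(heatmap_file) &&
      requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(heatmap_file, width = 900, height = 1200, res = 120)
    pheatmap::pheatmap(logged, clustering_method = "average",
                       cluster_cols = ncol(logged) >= 2L)
    grDevices::dev.off()
  }
  hc
}

#' Relative expression from qPCR Cq tables (2^-dCt / 2^-ddCt)
#'
#' Technical replicates are first averaged to one Cq per biological
#' replicate. Per biological replicate, `dCt = Cq(target) -
#' Cq(reference)`; in `"dct"` mode the fold is `2^-dCt`. In `"ddct"`
#' mode, `ddCt = dCt - mean(control dCt)` and the fold is `2^-ddCt`
#' (so the control condition's mean fold is 1 by construction). Means
#' and standard deviations are taken over biological replicates.
#'
#' @param cq_table data.frame with columns `gene`, `condition`,
#'   `bio_rep`, `tech_rep`, `cq`.
#' @param reference_gene name of the internal reference gene (e.g.
#'   `"ef1a"`), which must have a Cq in every sample.
#' @param mode `"dct"` (tissue profiles) or `"ddct"` (stress versus
#'   control).
#' @param control_condition calibrator condition (required for
#'   `"ddct"`).
#' @return data.frame with columns `gene`, `condition`, `mean_dct`,
#'   `fold` (mean over biological replicates) and `sd_fold`.
#' @export
relative_expression <- function(cq_table, reference_gene,
                                mode = c("dct", "ddct"),
                                control_condition = NULL) {
  mode <- match.arg(mode)
  need <- c("gene", "condition", "bio_rep", "tech_rep", "cq")
  if (!all(need %in% names(cq_table))) {
    fs_stop("cq_table must have columns %s", paste(need, collapse = ", "))
  }
  if (mode == "ddct" && is.null(control_condition)) {
    fs_stop("ddct mode requires a control condition")
  }
  if (!(reference_gene %in% cq_table$gene)) {
    fs_stop("reference gene %s not in table", reference_gene)
  }
  # collapse technical replicates
  agg <- stats::aggregate(cq ~ gene + condition + bio_rep,
                          data = cq_table, FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  tgt <- agg[agg$gene != reference_gene, ]
  key <- function(d) paste(d$condition, d$bio_rep, sep = "\r")
  ref_cq <- stats::setNames(ref$cq, key(ref))
  tgt$ref_cq <- ref_cq[key(tgt)]
  if (any(is.na(tgt$ref_cq))) {
    fs_stop("missing reference Cq for condition/replicate %s",
            key(tgt)[which(is.na(tgt$ref_cq))[1L]])
  }
  tgt$dct <- tgt$cq - tgt$ref_cq
  rows <- list()
  for (g in unique(tgt$gene)) {
    sub <- tgt[tgt$gene == g, ]
    if (mode == "ddct") {
      ctl <- sub$dct[sub$condition == control_condition]
      if (length(ctl) < 1L) {
        fs_stop("gene %s has no control-condition replicates", g)
      }
      sub$val <- sub$dct - mean(ctl)
    } else {
      sub$val <- sub$dct
    }
    for (cond in unique(sub$condition)) {
      v <- sub$val[sub$condition == cond]
      if (length(v) < 1L) fs_stop("no biological replicates for %s/%s",
                                  g, cond)
      folds <- 2^(-v)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond,
        mean_dct = mean(sub$dct[sub$condition == cond]),
        fold = 2^(-mean(v)),  # calibrator fold is exactly 1 this way
        sd_fold = if (length(folds) > 1L) stats::sd(folds) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
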
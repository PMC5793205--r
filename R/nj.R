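#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Neighbor-joining: the pair minimizing
#' `Q(i,j) = (n - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined
#' iteratively, with branch lengths from the standard NJ formulas. Ties
#' in Q are broken by the lexicographically smallest pair of
#' representative labels (the smallest leaf label inside each node), so
#' results are platform-independent. Tiny negative branch lengths are
#' clamped to zero with a warning. The result is exact on additive
#' matrices.
#'
#' @param m a `distance_matrix` (its `d` component is used) or a
#'   symmetric numeric matrix with dimnames.
#' @return an unrooted `phylo` tree (trifurcating root node).
#' @export
nj_tree <- function(m) {
  D <- if (inherits(m, "distance_matrix")) m$d else as.matrix(m)
  if (nrow(D) != ncol(D) || is.null(rownames(D))) {
    fs_stop("distance matrix must be square with labels")
  }
  if (max(abs(D - t(D))) > 1e-9) fs_stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) fs_stop("need at least 3 labels")
  labels <- rownames(D)
  frag <- labels       # growing newick fragments
  key <- labels        # representative (smallest) leaf label per node
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)
  while (length(frag) > 3L) {
    nn <- length(frag)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(key[ij[1L]], key[ij[2L]])), collapse = "\r")
    })
    best <- cand[order(pair_keys)[1L], ]
    i <- best[[1L]]; j <- best[[2L]]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))))
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newkey <- min(key[i], key[j])
    others <- setdiff(seq_len(nn), c(i, j))
    newd <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D <- rbind(cbind(D[others, others, drop = FALSE], newd),
               c(newd, 0))
    frag <- c(frag[others], newfrag)
    key <- c(key[others], newkey)
    rownames(D) <- colnames(D) <- key
  }
  a <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  cc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped) fs_warn("negative NJ branch length(s) clamped to 0")
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmt(a),
                 frag[2L], fmt(b), frag[3L], fmt(cc))
  ape::read.tree(text = txt)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix of leaf-to-leaf path lengths, ordered by tip
#'   label.
#' @export
tree_path_lengths <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}
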
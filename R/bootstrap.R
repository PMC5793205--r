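# tips descending from each node of a phylo tree (list indexed by node id)
.node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[[i]]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# canonical leaf bipartitions of an unrooted tree: one string per internal
# non-root edge, canonicalized to the side NOT containing the
# alphabetically first leaf; trivial splits excluded.
# Returns data.frame(node = child node id, split = canonical string).
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[[1L]]
  desc <- .node_descendants(tree)
  root <- ntip + 1L
  internal_children <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  rows <- lapply(internal_children, function(nd) {
    side <- sort(desc[[nd]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NULL)
    data.frame(node = nd, split = paste(side, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(), split = character(),
               stringsAsFactors = FALSE)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree of the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilding the
#' Poisson/pairwise-deletion distance matrix and NJ tree each time.
#' The support of an internal edge is 100 times the fraction of
#' successful replicates whose tree contains the same leaf bipartition;
#' supports are attached as internal node labels (the display
#' convention). Replicates in which a distance is undefined (a pair with
#' no comparable columns or p = 1) are skipped and excluded from the
#' denominator.
#'
#' @param aligned named character vector of equal-length aligned
#'   sequences.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; results are fully deterministic given
#'   (alignment, n_replicates, seed) and invariant to input order.
#' @return a `phylo` tree whose `node.label` holds supports (root label
#'   empty); attribute `bootstrap` records replicates run and skipped.
#' @export
bootstrap_supports <- function(aligned, n_replicates = 1000, seed = 1) {
  stopifnot(n_replicates >= 1)
  aligned <- aligned[order(names(aligned))]  # input-order invariance
  dm <- poisson_distance_matrix(aligned)
  main <- nj_tree(dm)
  splits <- tree_splits(main)
  counts <- stats::setNames(rep(0, nrow(splits)), splits$split)
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  rownames(mat) <- names(aligned)
  L <- ncol(mat)
  n_ok <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_seqs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
      dm_r <- tryCatch(poisson_distance_matrix(rep_seqs),
                       error = function(e) NULL)
      if (is.null(dm_r)) next
      tr <- suppressWarnings(nj_tree(dm_r))
      sp <- tree_splits(tr)$split
      hit <- names(counts) %in% sp
      counts[hit] <- counts[hit] + 1
      n_ok <- n_ok + 1L
    }
  })
  if (n_ok == 0L) fs_stop("all bootstrap replicates failed")
  support <- 100 * counts / n_ok
  ntip <- length(main$tip.label)
  labs <- rep("", main$Nnode)
  labs[splits$node - ntip] <- sprintf("%g", support)
  main$node.label <- labs
  attr(main, "bootstrap") <- list(n_replicates = n_replicates,
                                  n_ok = n_ok,
                                  n_skipped = n_replicates - n_ok)
  main
}
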
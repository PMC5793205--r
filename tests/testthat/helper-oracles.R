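# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (path enumeration, grid search, O(n^3) loops) so
# they share no code with the implementations they check.

# exhaustive global affine alignment score: enumerate every move
# sequence (match / gap-in-b / gap-in-a), scoring gaps open + (k-1)*ext
bf_global_score <- function(a, b, sub, open, ext) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, score + sub[ca[[i]], cb[[j]]], "M")
    }
    if (i <= length(ca)) {
      rec(i + 1L, j, score - if (identical(last, "X")) ext else open, "X")
    }
    if (j <= length(cb)) {
      rec(i, j + 1L, score - if (identical(last, "Y")) ext else open, "Y")
    }
  }
  rec(1L, 1L, 0, "S")
  best
}

# exhaustive glocal score: profile global (delete costs affine), target
# local (free overhangs), internal target insertions affine. S is the
# (profile columns x target positions) score matrix.
bf_glocal_score <- function(S, open, ext) {
  m <- nrow(S); L <- ncol(S)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > m) {  # all columns consumed; trailing overhang free
      best <<- max(best, score)
      return(invisible())
    }
    if (j <= L) rec(i + 1L, j + 1L, score + S[i, j], "M")
    rec(i + 1L, j, score - if (identical(last, "D")) ext else open, "D")
    if (j <= L && i > 1L) {
      rec(i, j + 1L, score - if (identical(last, "I")) ext else open, "I")
    }
  }
  for (start in seq_len(L + 1L)) rec(1L, start, 0, "S")
  best
}

# brute-force motif scan: every window of every pattern, all matches
bf_motif_hits <- function(protein, pattern) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  w <- pattern$width
  if (w > length(chars)) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(length(chars) - w + 1L)) {
    ok <- all(vapply(seq_len(w), function(k) {
      chars[[s + k - 1L]] %in% pattern$positions[[k]]
    }, TRUE))
    if (ok) hits <- c(hits, s)
  }
  hits
}

# grid-search pI: pH minimizing |net charge| on a uniform grid
bf_pi_grid <- function(seq, resolution = 1e-5) {
  grid <- seq(0, 14, by = resolution)
  q <- famscan::peptide_charge(seq, grid)
  grid[which.min(abs(q))]
}

# random unrooted binary tree with branch lengths in [0.1, 1]
random_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

# all unrooted binary topologies on the given labels (n <= 6 is sane):
# grow by inserting each new tip into every edge of every smaller tree
enumerate_topologies <- function(labels) {
  base <- ape::read.tree(text = sprintf("(%s:1,%s:1,%s:1);",
                                        labels[1], labels[2], labels[3]))
  trees <- list(base)
  for (k in seq(4L, length.out = max(0L, length(labels) - 3L))) {
    grown <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        g <- phytools::bind.tip(tr, labels[k], edge.length = 1,
                                where = tr$edge[e, 2L], position = 0.5)
        g$edge.length[] <- 1  # re-level so later insertions always fit
        grown[[length(grown) + 1L]] <- g
      }
    }
    trees <- grown
  }
  trees
}

# least-squares branch-length fit of a distance matrix on a fixed
# topology; returns the residual sum of squares
ls_fit_rss <- function(topology, D) {
  labs <- topology$tip.label
  ntip <- length(labs)
  # edge incidence: pair (i,j) crosses edge e iff i and j are on
  # opposite sides of e's bipartition
  po <- ape::reorder.phylo(topology, "postorder")
  desc <- vector("list", ntip + topology$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- labs[[i]]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  pairs <- t(utils::combn(labs, 2L))
  A <- matrix(0, nrow(pairs), nrow(topology$edge))
  for (e in seq_len(nrow(topology$edge))) {
    side <- desc[[topology$edge[e, 2L]]]
    crosses <- xor(pairs[, 1L] %in% side, pairs[, 2L] %in% side)
    A[crosses, e] <- 1
  }
  dvec <- D[cbind(pairs[, 1L], pairs[, 2L])]
  fit <- stats::lm.fit(A, dvec)
  sum(fit$residuals^2)
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
bf_average_linkage_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  groups <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq(i + 1L, length(groups))) {
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  sort(heights)
}

# canonical split strings of a tree (for topology comparison)
splits_of <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[[1L]]
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[[i]]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- character(0)
  for (nd in setdiff(unique(tree$edge[, 2L]), seq_len(ntip))) {
    side <- sort(desc[[nd]])
    if (anchor %in% side) side <- setdiff(sort(tree$tip.label), side)
    if (length(side) >= 2L && length(side) <= ntip - 2L) {
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  sort(unique(out))
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# substitute each position with probability `rate` by a different residue
mutate_peptide <- function(seq, rate) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
           "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[[i]] <- sample(setdiff(aas, chars[[i]]), 1L)
  paste(chars, collapse = "")
}

# small shared synthetic bundle (memoised per test run)
small_config <- function(seed = 11) {
  generator_config(seed = seed, n_chromosomes = 4L, n_members = 16L,
                   n_decoys = 8L, tandem_cluster_sizes = c(3L, 2L),
                   n_segmental_pairs = 1L, n_subfamilies = 3L,
                   n_refs_per_subfamily = 2L, n_unanchored = 1L)
}
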
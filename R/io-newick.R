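#' Write a phylogenetic tree to Newick
#'
#' Serializes an `ape` `phylo` tree with branch lengths; internal-node
#' support values (stored as `node.label`) are written as internal node
#' labels, the MEGA/Newick display convention.
#'
#' @param tree a `phylo` object with unique, non-empty tip labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) fs_stop("`tree` must be a phylo object")
  lab <- tree$tip.label
  if (is.null(lab) || any(is.na(lab)) || any(lab == "")) {
    fs_stop("tree has unlabeled leaves")
  }
  if (anyDuplicated(lab)) fs_stop("tree has duplicate leaf labels")
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return a `phylo` object (internal node labels, if any, hold supports).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) fs_stop("Newick file not found: %s", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) fs_stop("could not parse Newick in %s", path)
  tr
}
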
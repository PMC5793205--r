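#' Assign query leaves to subfamilies from labelled references
#'
#' Each query leaf receives the label of its nearest supported reference
#' clade: among all edge bipartitions with support at least
#' `support_min` whose query-containing side holds at least one
#' reference, the smallest such side decides — if its references carry
#' exactly one label the query gets that label, otherwise (a mixed
#' clade, or no supported reference-containing side at all) it is
#' `"unassigned"`. Pendant edges count as fully supported; trees without
#' node labels are treated as fully supported throughout.
#'
#' @param tree a `phylo` containing both reference and query leaves;
#'   internal `node.label`s, if present, are read as bootstrap supports.
#' @param reference_labels named character vector: reference leaf name ->
#'   group label (e.g. `"A"`..`"O"`).
#' @param support_min minimum bootstrap support for an edge to define a
#'   clade (default 50).
#' @return named character vector: query leaf -> assigned label or
#'   `"unassigned"`.
#' @export
assign_subfamilies <- function(tree, reference_labels, support_min = 50) {
  tips <- tree$tip.label
  refs <- intersect(names(reference_labels), tips)
  if (length(refs) == 0L) fs_stop("tree contains no reference leaves")
  queries <- setdiff(tips, refs)
  ntip <- length(tips)
  desc <- .node_descendants(tree)
  has_support <- !is.null(tree$node.label)
  edge_support <- vapply(seq_len(nrow(tree$edge)), function(k) {
    ch <- tree$edge[k, 2L]
    if (ch <= ntip || !has_support) return(100)
    lab <- tree$node.label[[ch - ntip]]
    s <- suppressWarnings(as.numeric(lab))
    if (is.na(s)) 100 else s
  }, 0)
  child_sets <- lapply(tree$edge[, 2L], function(ch) desc[[ch]])

  out <- stats::setNames(rep("unassigned", length(queries)), queries)
  for (q in queries) {
    best_size <- Inf
    best_label <- NA_character_
    for (k in seq_len(nrow(tree$edge))) {
      if (edge_support[[k]] < support_min) next
      side <- child_sets[[k]]
      qside <- if (q %in% side) side else setdiff(tips, side)
      rin <- intersect(qside, refs)
      if (length(rin) == 0L) next
      if (length(qside) < best_size) {
        best_size <- length(qside)
        labs <- unique(unname(reference_labels[rin]))
        best_label <- if (length(labs) == 1L) labs else NA_character_
      }
    }
    if (!is.na(best_label)) out[[q]] <- best_label
  }
  out
}
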
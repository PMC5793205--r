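#' Call duplicated gene pairs by alignment coverage and similarity
#'
#' Every unordered pair of family members is globally aligned; a pair is
#' called a duplication when (a) the shorter sequence's aligned share of
#' the longer exceeds `coverage_min` and (b) the identity fraction over
#' aligned columns exceeds `similarity_min` (both strict inequalities).
#'
#' @param members a `family_members` data.frame (the `protein` column is
#'   aligned).
#' @param coverage_min,similarity_min strict lower bounds (default 0.70).
#' @param substitution_matrix,gap_open,gap_extend passed to
#'   [global_align()].
#' @return data.frame of class `duplication_calls` with columns `gene_a`,
#'   `gene_b` (member names, `gene_a < gene_b`), `coverage`,
#'   `similarity`.
#' @export
call_duplications <- function(members, coverage_min = 0.70,
                              similarity_min = 0.70,
                              substitution_matrix = blosum62(),
                              gap_open = 10, gap_extend = 1) {
  if (nrow(members) < 2L) fs_stop("need at least 2 members")
  rows <- list()
  for (i in seq_len(nrow(members) - 1L)) {
    for (j in seq(i + 1L, nrow(members))) {
      aln <- global_align(members$protein[[i]], members$protein[[j]],
                          substitution_matrix, gap_open, gap_extend)
      cov <- alignment_coverage(aln)
      sim <- alignment_similarity(aln)
      if (cov > coverage_min && sim > similarity_min) {
        pair <- sort(c(members$name[[i]], members$name[[j]]))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = pair[[1L]], gene_b = pair[[2L]],
          coverage = cov, similarity = sim, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               coverage = numeric(), similarity = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("duplication_calls", class(out))
  out
}

# number of whole-genome genes whose span lies strictly between two genes
.n_intervening <- function(genome, ga, gb) {
  lo <- min(ga$end, gb$end)
  hi <- max(ga$start, gb$start)
  sum(vapply(genome$genes, function(g) {
    !(g$gene_id %in% c(ga$gene_id, gb$gene_id)) &&
      g$chromosome == ga$chromosome && g$start > lo && g$end < hi
  }, logical(1)))
}

#' Classify duplication calls as tandem clusters or segmental pairs
#'
#' A called pair is tandem when both genes sit on the same chromosome
#' within `window_bp` (start-to-start) and are separated by at most
#' `max_intervening` genes of the whole-genome annotation. Tandem pairs
#' are merged into clusters by single linkage. Remaining called pairs are
#' segmental when they lie on different chromosomes or at least
#' `window_bp` apart; same-chromosome pairs inside the window but with
#' too many intervening genes stay unclassified.
#'
#' @param calls a `duplication_calls` data.frame.
#' @param genome the `annotated_genome` (whole-genome gene order).
#' @param members the `family_members` table mapping member names to gene
#'   ids.
#' @param window_bp tandem window in bp (default 100,000).
#' @param max_intervening maximum intervening genes (default 5).
#' @return list with `calls` (input plus a `classification` column),
#'   `clusters` (list of `tandem_cluster` objects: member names ordered
#'   by position, plus chromosome) and `segmental` (subset of calls).
#' @export
classify_duplications <- function(calls, genome, members,
                                  window_bp = 1e5, max_intervening = 5L) {
  lookup <- function(name) {
    i <- match(name, members$name)
    if (is.na(i)) fs_stop("duplication call references unknown gene %s",
                          name)
    g <- genome$genes[[members$gene_id[[i]]]]
    if (is.null(g)) fs_stop("gene %s missing from genome",
                            members$gene_id[[i]])
    g
  }
  n <- nrow(calls)
  classification <- character(n)
  for (k in seq_len(n)) {
    ga <- lookup(calls$gene_a[[k]])
    gb <- lookup(calls$gene_b[[k]])
    same_chr <- ga$chromosome == gb$chromosome
    dist <- abs(ga$start - gb$start)
    if (same_chr && dist < window_bp &&
        .n_intervening(genome, ga, gb) <= max_intervening) {
      classification[[k]] <- "tandem"
    } else if (!same_chr || dist >= window_bp) {
      classification[[k]] <- "segmental"
    } else {
      classification[[k]] <- "unclassified"
    }
  }
  calls$classification <- classification

  # single-linkage merge of tandem pairs into clusters
  td <- calls[classification == "tandem", , drop = FALSE]
  clusters <- list()
  if (nrow(td)) {
    comp <- stats::setNames(seq_along(unique(c(td$gene_a, td$gene_b))),
                            unique(c(td$gene_a, td$gene_b)))
    for (k in seq_len(nrow(td))) {
      ca <- comp[[td$gene_a[[k]]]]
      cb <- comp[[td$gene_b[[k]]]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    for (cid in unique(comp)) {
      nm <- names(comp)[comp == cid]
      starts <- vapply(nm, function(x) lookup(x)$start, 0L)
      chrom <- lookup(nm[[1L]])$chromosome
      clusters[[length(clusters) + 1L]] <- structure(
        list(members = nm[order(starts)], chromosome = chrom),
        class = "tandem_cluster")
    }
    first_start <- vapply(clusters, function(cl) lookup(cl$members[[1L]])$start, 0L)
    chrom_order <- vapply(clusters, function(cl) {
      chrom_rank(cl$chromosome, genome)
    }, 0L)
    clusters <- clusters[order(chrom_order, first_start)]
  }
  list(calls = calls, clusters = clusters,
       segmental = calls[classification == "segmental", , drop = FALSE])
}

#' @export
print.tandem_cluster <- function(x, ...) {
  cat(sprintf("tandem cluster on %s: %s\n", x$chromosome,
              paste(x$members, collapse = ", ")))
  invisible(x)
}
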
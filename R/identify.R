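#' Select the representative transcript of a locus
#'
#' The representative transcript is the one with the longest total CDS
#' among transcripts whose protein is present in the proteome; ties break
#' to the lexicographically smallest transcript id.
#'
#' @param gene a gene model from an [new_annotated_genome()] genome.
#' @param proteome named character vector of protein sequences (names are
#'   protein ids).
#' @return the representative transcript id.
#' @export
select_representative <- function(gene, proteome) {
  coding <- Filter(function(tr) {
    nrow(tr$cds) > 0L && tr$protein_id %in% names(proteome)
  }, gene$transcripts)
  if (length(coding) == 0L) {
    fs_stop("gene %s has no coding transcript with a protein", gene$gene_id)
  }
  cds_len <- vapply(coding, function(tr) {
    sum(iv_width(tr$cds[, 1L], tr$cds[, 2L]))
  }, 0L)
  ids <- vapply(coding, `[[`, "", "transcript_id")
  ids[order(-cds_len, ids)][1L]
}

#' Identify family members in a proteome
#'
#' One candidate protein per locus (the representative transcript) is
#' scanned with the domain profile; a gene is accepted when its best hit
#' exists and covers at least `completeness_min` of the profile columns
#' (the "complete domain" rule). Accepted members are sorted by
#' chromosome order (the unanchored pseudo-chromosome, declared first,
#' sorts before all others), then start coordinate, then gene id, and
#' named `prefix1 .. prefixN`.
#'
#' @param proteome named character vector of protein sequences.
#' @param genome an `annotated_genome`.
#' @param profile a `domain_profile`.
#' @param completeness_min minimum profile coverage counted as a complete
#'   domain (default 0.9).
#' @param prefix name prefix for accepted members (e.g. `"StbHLH"`).
#' @param gap_open,gap_extend,report_threshold passed to [scan_profile()].
#' @return data.frame of class `family_members` with columns `name`,
#'   `gene_id`, `transcript_id`, `chromosome`, `start`, `end`, `strand`,
#'   `score`, `coverage`, `protein`.
#' @export
identify_family <- function(proteome, genome, profile,
                            completeness_min = 0.9, prefix = "FAM",
                            gap_open = 11, gap_extend = 1,
                            report_threshold = 0) {
  known <- unlist(lapply(genome$genes, function(g) {
    vapply(g$transcripts, `[[`, "", "protein_id")
  }), use.names = FALSE)
  unmapped <- setdiff(names(proteome), known)
  if (length(unmapped)) {
    fs_warn("%d protein(s) without a gene mapping excluded (e.g. %s)",
            length(unmapped), unmapped[[1L]])
  }
  rows <- list()
  for (g in genome$genes) {
    rep_id <- tryCatch(select_representative(g, proteome),
                       error = function(e) NA_character_)
    if (is.na(rep_id)) next
    tr <- g$transcripts[[which(vapply(g$transcripts, `[[`, "",
                                      "transcript_id") == rep_id)]]
    prot <- proteome[[tr$protein_id]]
    hit <- scan_profile(prot, profile, gap_open, gap_extend,
                        report_threshold)
    if (is.null(hit) || hit$profile_coverage < completeness_min) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, transcript_id = rep_id,
      chromosome = g$chromosome, start = g$start, end = g$end,
      strand = g$strand, score = hit$score,
      coverage = hit$profile_coverage, protein = prot,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(name = character(), gene_id = character(),
                      transcript_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      coverage = numeric(), protein = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("family_members", class(out))
    return(out)
  }
  df <- do.call(rbind, rows)
  df <- df[order(chrom_rank(df$chromosome, genome), df$start, df$gene_id), ,
           drop = FALSE]
  df <- cbind(name = paste0(prefix, seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("family_members", class(df))
  df
}

#' @export
print.family_members <- function(x, ...) {
  cat(sprintf("%d family members (%s..%s)\n", nrow(x),
              if (nrow(x)) x$name[[1L]] else "-",
              if (nrow(x)) x$name[[nrow(x)]] else "-"))
  print.data.frame(utils::head(as.data.frame(
    x[, setdiff(names(x), "protein")]), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
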
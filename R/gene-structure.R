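#' Intron count and intron phases of a coding transcript
#'
#' Intron phase follows the standard convention: a phase-0 intron splices
#' after the third nucleotide of a codon, phase 1 after the first, phase
#' 2 after the second; i.e. the phase of intron i is the cumulative CDS
#' length upstream of it modulo 3. CDS segments must already be in
#' transcription order (the GFF3 reader guarantees this on both strands).
#'
#' @param transcript a transcript model (list with a `cds` interval
#'   matrix in transcription order).
#' @return list with `intron_count` and `phases` (integer vector over
#'   {0, 1, 2}, one per intron, in transcription order). A mono-exonic
#'   CDS gives count 0 and an empty phase vector.
#' @export
intron_phases <- function(transcript) {
  cds <- transcript$cds
  if (is.null(cds) || nrow(cds) == 0L) {
    fs_stop("transcript %s has no CDS",
            if (!is.null(transcript$transcript_id))
              transcript$transcript_id else "<unnamed>")
  }
  lens <- iv_width(cds[, 1L], cds[, 2L])
  total <- sum(lens)
  if (total %% 3L != 0L) {
    fs_warn("CDS length %d not divisible by 3; phases may be unreliable",
            total)
  }
  n_intron <- nrow(cds) - 1L
  phases <- if (n_intron > 0L) {
    as.integer(cumsum(lens)[seq_len(n_intron)] %% 3L)
  } else integer(0)
  list(intron_count = n_intron, phases = phases)
}

#' Intron annotation for every member of a family
#'
#' @param members a `family_members` data.frame.
#' @param genome the `annotated_genome` the members came from.
#' @return data.frame with columns `name`, `gene_id`, `intron_count`,
#'   `phases` (comma-separated string, empty for intronless genes).
#' @export
family_gene_structure <- function(members, genome) {
  rows <- lapply(seq_len(nrow(members)), function(i) {
    g <- genome$genes[[members$gene_id[[i]]]]
    if (is.null(g)) fs_stop("gene %s not in genome", members$gene_id[[i]])
    tid <- members$transcript_id[[i]]
    tr <- g$transcripts[[which(vapply(g$transcripts, `[[`, "",
                                      "transcript_id") == tid)]]
    ann <- intron_phases(tr)
    data.frame(name = members$name[[i]], gene_id = members$gene_id[[i]],
               intron_count = ann$intron_count,
               phases = paste(ann$phases, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
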
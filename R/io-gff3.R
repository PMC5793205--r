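#' Construct an annotated genome object
#'
#' The in-memory coordinate model shared by the whole pipeline: an ordered
#' chromosome table plus a list of gene models, each holding its
#' transcripts with exon and CDS intervals in transcription order.
#' Coordinates are 1-based inclusive throughout. Unanchored genes live on a
#' pseudo-chromosome (conventionally `"chr00"`) that is declared first and
#' therefore sorts before all real chromosomes.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp); row
#'   order defines chromosome sort order.
#' @param genes list of gene models as built by [read_gff3()].
#' @return an object of class `annotated_genome`.
#' @export
new_annotated_genome <- function(chromosomes, genes) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name)) {
    fs_stop("duplicate chromosome names")
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  g <- structure(list(chromosomes = chromosomes, genes = genes),
                 class = "annotated_genome")
  for (gene in genes) {
    len <- chromosomes$length[match(gene$chromosome, chromosomes$name)]
    if (is.na(len)) {
      fs_stop("gene %s on undeclared chromosome %s", gene$gene_id,
              gene$chromosome)
    }
    if (gene$start < 1L || gene$end > len || gene$start > gene$end) {
      fs_stop("gene %s span [%d,%d] outside chromosome %s (length %d)",
              gene$gene_id, gene$start, gene$end, gene$chromosome, len)
    }
    if (length(gene$transcripts) == 0L) {
      fs_stop("gene %s has no transcripts", gene$gene_id)
    }
  }
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated genome: %d chromosomes, %d genes, %d transcripts\n",
              nrow(x$chromosomes), length(x$genes),
              sum(vapply(x$genes, function(g) length(g$transcripts), 0L))))
  invisible(x)
}

#' Gene table of an annotated genome
#'
#' @param genome an `annotated_genome`.
#' @return data.frame of genes sorted by chromosome order then start.
#' @export
gene_table <- function(genome) {
  df <- do.call(rbind, lapply(genome$genes, function(g) {
    data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
               start = g$start, end = g$end, strand = g$strand,
               n_transcripts = length(g$transcripts),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df[order(chrom_rank(df$chromosome, genome), df$start, df$gene_id), ,
     drop = FALSE]
}

# order intervals in transcription order: ascending genomic coordinate on
# "+", descending on "-"
.transcription_order <- function(mat, strand) {
  mat <- mat[order(mat[, 1L]), , drop = FALSE]
  if (strand == "-") mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  mat
}

#' Read a GFF3 annotation into an annotated genome
#'
#' Parses gene/mRNA/exon/CDS features linked by `ID`/`Parent` (via
#' rtracklayer) into the package's hierarchical gene model. Chromosome
#' lengths are taken from `##sequence-region` pragmas when present,
#' otherwise inferred from the right-most feature. Minus-strand transcripts
#' have their exons and CDS segments ordered 5'->3' in transcription order
#' (descending genomic coordinate). A transcript whose CDS length is not
#' divisible by 3 raises a warning and is flagged (`cds_flagged = TRUE`);
#' an exon/CDS/mRNA pointing at an unknown `Parent` is an error.
#'
#' @param path path to a GFF3 file (the `##gff-version 3` pragma is
#'   required).
#' @return an `annotated_genome`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) fs_stop("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^##gff-version\\s+3", lines[[1L]])) {
    fs_stop("missing '##gff-version 3' pragma in %s", path)
  }
  sr <- grep("^##sequence-region\\s", lines, value = TRUE)
  chrom_tab <- NULL
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    chrom_tab <- data.frame(
      name = vapply(parts, `[[`, "", 2L),
      length = as.integer(vapply(parts, `[[`, "", 4L)),
      stringsAsFactors = FALSE)
  }

  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  feat <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    id = if (!is.null(md$ID)) as.character(md$ID) else NA_character_,
    stringsAsFactors = FALSE)
  parent <- if (!is.null(md$Parent)) {
    vapply(as.list(md$Parent),
           function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else rep(NA_character_, nrow(feat))
  feat$parent <- parent

  gene_rows <- which(feat$type == "gene")
  mrna_rows <- which(feat$type %in% c("mRNA", "transcript"))
  gene_ids <- feat$id[gene_rows]
  mrna_ids <- feat$id[mrna_rows]

  orphan <- function(rows, what, universe) {
    bad <- !(feat$parent[rows] %in% universe)
    if (any(bad)) {
      fs_stop("%s feature(s) with unknown Parent: %s", what,
              paste(unique(feat$parent[rows][bad]), collapse = ", "))
    }
  }
  orphan(mrna_rows, "mRNA", gene_ids)
  seg_rows <- which(feat$type %in% c("exon", "CDS"))
  orphan(seg_rows, "exon/CDS", mrna_ids)

  genes <- vector("list", length(gene_rows))
  for (k in seq_along(gene_rows)) {
    gi <- gene_rows[[k]]
    gid <- feat$id[[gi]]
    tr_rows <- mrna_rows[feat$parent[mrna_rows] == gid]
    transcripts <- lapply(tr_rows, function(ti) {
      tid <- feat$id[[ti]]
      strand <- feat$strand[[ti]]
      ex <- feat[seg_rows, ][feat$type[seg_rows] == "exon" &
                               feat$parent[seg_rows] == tid, , drop = FALSE]
      cds <- feat[seg_rows, ][feat$type[seg_rows] == "CDS" &
                                feat$parent[seg_rows] == tid, , drop = FALSE]
      exm <- .transcription_order(cbind(start = ex$start, end = ex$end),
                                  strand)
      cdm <- .transcription_order(cbind(start = cds$start, end = cds$end),
                                  strand)
      flagged <- FALSE
      if (nrow(cdm)) {
        total <- sum(iv_width(cdm[, 1L], cdm[, 2L]))
        if (total %% 3L != 0L) {
          fs_warn("transcript %s: CDS length %d not divisible by 3",
                  tid, total)
          flagged <- TRUE
        }
      }
      list(transcript_id = tid, exons = exm, cds = cdm,
           protein_id = tid, cds_flagged = flagged)
    })
    genes[[k]] <- list(gene_id = gid, chromosome = feat$chromosome[[gi]],
                       start = feat$start[[gi]], end = feat$end[[gi]],
                       strand = feat$strand[[gi]], transcripts = transcripts)
  }
  if (is.null(chrom_tab)) {
    agg <- stats::aggregate(end ~ chromosome, data = feat, FUN = max)
    chrom_tab <- data.frame(name = agg$chromosome, length = agg$end,
                            stringsAsFactors = FALSE)
    chrom_tab <- chrom_tab[order(chrom_tab$name), , drop = FALSE]
  }
  new_annotated_genome(chrom_tab, genes)
}

#' Write an annotated genome as GFF3
#'
#' Emits `##gff-version 3` and `##sequence-region` pragmas followed by
#' gene/mRNA/exon/CDS features (intervals in ascending genomic coordinate,
#' per GFF3 convention; transcription order is recovered on read from the
#' strand).
#'
#' @param genome an `annotated_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  out <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d",
                   genome$chromosomes$name, genome$chromosomes$length))
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, start, end, strand, attrs)
  }
  for (g in genome$genes) {
    out <- c(out, fmt(g$chromosome, "famscan", "gene", g$start, g$end,
                      g$strand, sprintf("ID=%s", g$gene_id)))
    for (tr in g$transcripts) {
      all_iv <- rbind(tr$exons, tr$cds)
      out <- c(out, fmt(g$chromosome, "famscan", "mRNA",
                        min(all_iv[, 1L]), max(all_iv[, 2L]), g$strand,
                        sprintf("ID=%s;Parent=%s", tr$transcript_id,
                                g$gene_id)))
      ex <- tr$exons[order(tr$exons[, 1L]), , drop = FALSE]
      for (i in seq_len(nrow(ex))) {
        out <- c(out, fmt(g$chromosome, "famscan", "exon",
                          ex[i, 1L], ex[i, 2L], g$strand,
                          sprintf("ID=%s.exon%d;Parent=%s",
                                  tr$transcript_id, i, tr$transcript_id)))
      }
      cd <- tr$cds[order(tr$cds[, 1L]), , drop = FALSE]
      for (i in seq_len(nrow(cd))) {
        out <- c(out, fmt(g$chromosome, "famscan", "CDS",
                          cd[i, 1L], cd[i, 2L], g$strand,
                          sprintf("ID=%s.cds%d;Parent=%s",
                                  tr$transcript_id, i, tr$transcript_id)))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
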
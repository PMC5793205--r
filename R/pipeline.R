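#' Pipeline configuration
#'
#' Collects the input paths, thresholds and seed of a full family
#' analysis. Paths for optional stages (`fpkm`, `cq`, `ref_labels`) may
#' be `NULL`, in which case those stages are skipped. All referenced
#' files must exist at configuration time — a missing input is a
#' configuration error raised before any computation.
#'
#' @param proteome,gff,seed_alignment required input paths (FASTA, GFF3,
#'   aligned FASTA).
#' @param refs optional FASTA of labelled reference proteins for
#'   subfamily assignment.
#' @param ref_labels optional TSV (`leaf`, `label`) mapping reference
#'   names to group labels; required if `refs` is given.
#' @param fpkm optional FPKM TSV (genes x conditions).
#' @param cq optional qPCR Cq TSV (`gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `cq`).
#' @param outdir output directory for stage TSVs.
#' @param prefix member name prefix.
#' @param completeness_min minimum profile coverage for a complete
#'   domain.
#' @param coverage_min,similarity_min duplication-call thresholds.
#' @param tandem_window_bp,max_intervening tandem classification rule.
#' @param fpkm_threshold barely-expressed FPKM cutoff.
#' @param support_min minimum bootstrap support for subfamily
#'   assignment.
#' @param bootstrap_replicates bootstrap replicate count.
#' @param qpcr_reference,qpcr_mode,qpcr_control qPCR analysis settings.
#' @param seed integer seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome, gff, seed_alignment,
                            refs = NULL, ref_labels = NULL, fpkm = NULL,
                            cq = NULL, outdir = tempfile("famscan_run_"),
                            prefix = "FAM", completeness_min = 0.9,
                            coverage_min = 0.70, similarity_min = 0.70,
                            tandem_window_bp = 1e5, max_intervening = 5L,
                            fpkm_threshold = 2.0, support_min = 50,
                            bootstrap_replicates = 100L,
                            qpcr_reference = "ef1a",
                            qpcr_mode = c("dct", "ddct"),
                            qpcr_control = NULL, seed = 1L) {
  qpcr_mode <- match.arg(qpcr_mode)
  for (p in c(proteome, gff, seed_alignment, refs, ref_labels, fpkm, cq)) {
    if (!is.null(p) && !file.exists(p)) {
      fs_stop("configured input does not exist: %s", p)
    }
  }
  if (!is.null(refs) && is.null(ref_labels)) {
    fs_stop("refs given without ref_labels")
  }
  stopifnot(completeness_min > 0, completeness_min <= 1,
            coverage_min >= 0, coverage_min <= 1,
            similarity_min >= 0, similarity_min <= 1,
            tandem_window_bp > 0, max_intervening >= 0,
            fpkm_threshold >= 0, support_min >= 0, support_min <= 100,
            bootstrap_replicates >= 1)
  structure(list(proteome = proteome, gff = gff,
                 seed_alignment = seed_alignment, refs = refs,
                 ref_labels = ref_labels, fpkm = fpkm, cq = cq,
                 outdir = outdir, prefix = prefix,
                 completeness_min = completeness_min,
                 coverage_min = coverage_min,
                 similarity_min = similarity_min,
                 tandem_window_bp = tandem_window_bp,
                 max_intervening = as.integer(max_intervening),
                 fpkm_threshold = fpkm_threshold,
                 support_min = support_min,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 qpcr_reference = qpcr_reference, qpcr_mode = qpcr_mode,
                 qpcr_control = qpcr_control, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full family analysis pipeline
#'
#' Stages run in order: identify -> characterize -> duplications ->
#' tree/classify -> expression/qPCR; each stage's table is written to
#' the output directory and the family summary is computed from the
#' stage outputs. Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return object of class `family_analysis`: list with `members`,
#'   `stats`, `structure`, `motifs`, `duplications`, `tree`,
#'   `subfamilies`, `expression`, `qpcr`, `summary`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fs_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## identification
  proteome <- stage("io", read_fasta(config$proteome))
  genome <- stage("io", read_gff3(config$gff))
  seed_aln <- stage("io", read_fasta(config$seed_alignment))
  profile <- stage("identify", build_profile(seed_aln))
  members <- stage("identify", suppressWarnings(
    identify_family(proteome, genome, profile,
                    completeness_min = config$completeness_min,
                    prefix = config$prefix)))
  if (nrow(members) == 0L) fs_stop("pipeline: no family members found")
  write_tsv <- function(df, file) {
    utils::write.table(df, file.path(config$outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(members[, setdiff(names(members), "protein")], "members.tsv")

  ## characterization
  prots <- stats::setNames(members$protein, members$name)
  stats_df <- stage("characterize", protein_stats(prots))
  structure_df <- stage("characterize",
                        family_gene_structure(members, genome))
  motif_list <- stage("characterize", lapply(prots, scan_motifs,
                                             patterns = stbhlh_motifs()))
  write_tsv(cbind(stats_df,
                  intron_count = structure_df$intron_count,
                  phases = structure_df$phases), "stats.tsv")

  ## duplication
  dup <- stage("duplication", {
    calls <- call_duplications(members, config$coverage_min,
                               config$similarity_min)
    classify_duplications(calls, genome, members,
                          window_bp = config$tandem_window_bp,
                          max_intervening = config$max_intervening)
  })
  write_tsv(dup$calls, "dup.tsv")

  ## phylogeny
  tree <- NULL; subfam <- NULL
  if (nrow(members) >= 3L) {
    tree <- stage("phylogeny", {
      seqs <- prots
      labels <- NULL
      if (!is.null(config$refs)) {
        refs <- read_fasta(config$refs)
        lab_df <- utils::read.delim(config$ref_labels,
                                    stringsAsFactors = FALSE)
        labels <- stats::setNames(lab_df$label, lab_df$leaf)
        seqs <- c(seqs, refs)
      }
      aligned <- align_proteins(seqs)
      tr <- bootstrap_supports(aligned,
                               n_replicates = config$bootstrap_replicates,
                               seed = config$seed)
      if (!is.null(labels)) {
        subfam <- assign_subfamilies(tr, labels,
                                     support_min = config$support_min)
      }
      tr
    })
    write_newick(tree, file.path(config$outdir, "tree.nwk"))
    if (!is.null(subfam)) {
      write_tsv(data.frame(name = names(subfam), group = unname(subfam),
                           stringsAsFactors = FALSE), "groups.tsv")
    }
  }

  ## expression
  expr <- NULL
  if (!is.null(config$fpkm)) {
    expr <- stage("expression", {
      m <- read_matrix_tsv(config$fpkm)
      em <- normalize_matrix(m)
      flt <- filter_expressed(m, threshold = config$fpkm_threshold)
      hc <- if (length(flt$kept) >= 2L) {
        cluster_heatmap(em$logged[flt$kept, , drop = FALSE])
      } else NULL
      list(matrix = em, filter = flt, clustering = hc)
    })
    write_tsv(data.frame(gene = rownames(expr$matrix$fpkm),
                         expressed = rownames(expr$matrix$fpkm) %in%
                           expr$filter$kept), "expressed.tsv")
  }
  qpcr <- NULL
  if (!is.null(config$cq)) {
    qpcr <- stage("qpcr", {
      tab <- utils::read.delim(config$cq, stringsAsFactors = FALSE)
      relative_expression(tab, config$qpcr_reference,
                          mode = config$qpcr_mode,
                          control_condition = config$qpcr_control)
    })
    write_tsv(qpcr, "relexpr.tsv")
  }

  summ <- family_summary(members, structure_df, stats_df, dup,
                         expression_filter = if (!is.null(expr))
                           expr$filter else NULL)
  write_tsv(data.frame(field = names(unlist(summ)),
                       value = unname(unlist(summ))), "summary.tsv")
  writeLines(c(sprintf("famscan %s",
                       as.character(utils::packageVersion("famscan"))),
               sprintf("seed: %d", config$seed),
               sprintf("thresholds: completeness=%g coverage=%g %s",
                       config$completeness_min, config$coverage_min,
                       sprintf("similarity=%g fpkm=%g support=%g",
                               config$similarity_min,
                               config$fpkm_threshold, config$support_min)),
               sprintf("bootstrap: %d replicates",
                       config$bootstrap_replicates)),
             file.path(config$outdir, "run.log"))

  structure(list(members = members, stats = stats_df,
                 structure = structure_df, motifs = motif_list,
                 duplications = dup, tree = tree, subfamilies = subfam,
                 expression = expr, qpcr = qpcr, summary = summ,
                 config = config),
            class = "family_analysis")
}

#' @export
print.family_analysis <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Family summary statistics
#'
#' The per-family headline numbers: member count, per-chromosome counts,
#' intronless/one-intron counts, intron-phase distribution, duplication
#' counts and length/MW/pI extrema, with percentages as 100 k/n rounded
#' to one decimal, half away from zero. The duplicated-gene count is the
#' size of the union of tandem-cluster genes and genes in segmental
#' pairs.
#'
#' @param members `family_members` table.
#' @param structure_df output of [family_gene_structure()].
#' @param stats_df output of [protein_stats()] on the member proteins.
#' @param dup output of [classify_duplications()].
#' @param expression_filter optional output of [filter_expressed()].
#' @return object of class `family_summary` (a named list).
#' @export
family_summary <- function(members, structure_df, stats_df, dup,
                           expression_filter = NULL) {
  n <- nrow(members)
  if (!identical(sort(members$name), sort(structure_df$name))) {
    fs_stop("member/structure tables disagree")
  }
  per_chrom <- table(members$chromosome)
  intronless <- sum(structure_df$intron_count == 0L)
  one_intron <- sum(structure_df$intron_count == 1L)
  all_phases <- unlist(lapply(strsplit(structure_df$phases, ","),
                              function(x) as.integer(x[nzchar(x)])))
  phase_counts <- vapply(0:2, function(ph) sum(all_phases == ph), 0L)
  names(phase_counts) <- paste0("phase", 0:2)
  tandem_genes <- unique(unlist(lapply(dup$clusters, `[[`, "members")))
  seg_genes <- unique(c(dup$segmental$gene_a, dup$segmental$gene_b))
  duplicated_genes <- union(tandem_genes, seg_genes)
  rng <- function(v) {
    i <- which.min(v); j <- which.max(v)
    list(min = v[[i]], min_name = stats_df$id[[i]],
         max = v[[j]], max_name = stats_df$id[[j]])
  }
  out <- list(
    n_members = n,
    per_chromosome = as.list(per_chrom),
    intronless = intronless,
    intronless_pct = percent1(intronless, n),
    one_intron = one_intron,
    one_intron_pct = percent1(one_intron, n),
    n_introns = length(all_phases),
    phase_counts = as.list(phase_counts),
    phase_pct = if (length(all_phases)) as.list(stats::setNames(
      percent1(unname(phase_counts), length(all_phases)),
      names(phase_counts))) else
        list(phase0 = NA, phase1 = NA, phase2 = NA),
    n_tandem_genes = length(tandem_genes),
    tandem_pct = percent1(length(tandem_genes), n),
    n_tandem_clusters = length(dup$clusters),
    n_segmental_pairs = nrow(dup$segmental),
    n_duplicated_genes = length(duplicated_genes),
    duplicated_pct = percent1(length(duplicated_genes), n),
    length_range = rng(stats_df$length),
    mw_range = rng(stats_df$molecular_weight),
    pi_range = rng(stats_df$isoelectric_point))
  if (!is.null(expression_filter)) {
    out$n_expressed <- length(expression_filter$kept)
    out$n_excluded <- length(expression_filter$excluded)
  }
  structure(out, class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat(sprintf("family of %d members\n", x$n_members))
  cat(sprintf("  intronless: %d (%.1f%%), one intron: %d (%.1f%%)\n",
              x$intronless, x$intronless_pct, x$one_intron,
              x$one_intron_pct))
  cat(sprintf("  introns: %d; phase 0/1/2 = %d/%d/%d\n", x$n_introns,
              x$phase_counts$phase0, x$phase_counts$phase1,
              x$phase_counts$phase2))
  cat(sprintf("  tandem: %d genes (%.1f%%) in %d clusters; %s\n",
              x$n_tandem_genes, x$tandem_pct, x$n_tandem_clusters,
              sprintf("%d segmental pairs", x$n_segmental_pairs)))
  cat(sprintf("  duplicated genes: %d (%.1f%%)\n", x$n_duplicated_genes,
              x$duplicated_pct))
  cat(sprintf("  length %d (%s) - %d (%s) aa\n",
              x$length_range$min, x$length_range$min_name,
              x$length_range$max, x$length_range$max_name))
  cat(sprintf("  MW %.1f - %.1f Da, pI %.2f (%s) - %.2f (%s)\n",
              x$mw_range$min, x$mw_range$max,
              x$pi_range$min, x$pi_range$min_name,
              x$pi_range$max, x$pi_range$max_name))
  if (!is.null(x$n_expressed)) {
    cat(sprintf("  expressed: %d kept, %d excluded by the FPKM filter\n",
                x$n_expressed, x$n_excluded))
  }
  invisible(x)
}
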
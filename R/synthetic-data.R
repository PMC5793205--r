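# Twelve tissue labels used by default for synthetic FPKM matrices,
# mirroring a typical multi-tissue RNA-seq panel.
TISSUES12 <- c("leaf", "petiole", "stem", "root", "stolon", "tuber",
               "flower", "petal", "sepal", "stamen", "callus",
               "shoot_apex")

#' Configuration for the synthetic family-genome generator
#'
#' Bundles every knob of the generator with validation. Identical
#' (config, seed) pairs give byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes number of anchored chromosomes (chr01..).
#' @param n_members planted family members (complete domain).
#' @param n_decoys decoy genes (half domain-free, half carrying at most
#'   50% of the domain).
#' @param tandem_cluster_sizes integer vector of planted tandem-cluster
#'   sizes (each cluster sits on its own chromosome).
#' @param n_segmental_pairs planted high-similarity pairs on different
#'   chromosomes.
#' @param n_subfamilies planted phylogenetic groups (labelled A, B, ...).
#' @param n_refs_per_subfamily labelled reference proteins emitted per
#'   subfamily.
#' @param domain_length planted domain length in residues.
#' @param mutation_rate_within_pair substitutions/site between members of
#'   a planted duplicate pair or cluster.
#' @param subfamily_divergence substitutions/site between a subfamily
#'   ancestor's flanking regions and those of its members/references;
#'   set high enough that non-duplicate members fall near or below the
#'   70% identity line, as in real families.
#' @param domain_divergence substitutions/site applied to the planted
#'   domain region of each member (kept low: the domain is conserved).
#' @param n_tissues conditions in the synthetic FPKM matrix (12 gives
#'   named tissues).
#' @param baseline_fpkm location of the log-normal FPKM distribution for
#'   expressed genes.
#' @param noise_sd log-scale noise of expressed FPKM values.
#' @param unexpressed_fraction fraction of members planted as barely
#'   expressed (all FPKM drawn uniformly in `[0, 2)`).
#' @param n_unanchored members placed on the unanchored pseudo-chromosome
#'   `chr00` (named before all anchored members).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_chromosomes = 5L,
                             n_members = 24L, n_decoys = 12L,
                             tandem_cluster_sizes = c(3L, 2L),
                             n_segmental_pairs = 2L,
                             n_subfamilies = 4L,
                             n_refs_per_subfamily = 3L,
                             domain_length = 60L,
                             mutation_rate_within_pair = 0.05,
                             subfamily_divergence = 0.30,
                             domain_divergence = 0.03,
                             n_tissues = 12L, baseline_fpkm = 20,
                             noise_sd = 0.25,
                             unexpressed_fraction = 0.25,
                             n_unanchored = 2L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_members = as.integer(n_members), n_decoys = as.integer(n_decoys),
              tandem_cluster_sizes = as.integer(tandem_cluster_sizes),
              n_segmental_pairs = as.integer(n_segmental_pairs),
              n_subfamilies = as.integer(n_subfamilies),
              n_refs_per_subfamily = as.integer(n_refs_per_subfamily),
              domain_length = as.integer(domain_length),
              mutation_rate_within_pair = mutation_rate_within_pair,
              subfamily_divergence = subfamily_divergence,
              domain_divergence = domain_divergence,
              n_tissues = as.integer(n_tissues),
              baseline_fpkm = baseline_fpkm, noise_sd = noise_sd,
              unexpressed_fraction = unexpressed_fraction,
              n_unanchored = as.integer(n_unanchored))
  stopifnot(is_count(cfg$n_chromosomes), cfg$n_chromosomes >= 1,
            is_count(cfg$n_members), is_count(cfg$n_decoys),
            all(cfg$tandem_cluster_sizes >= 2),
            is_count(cfg$n_segmental_pairs),
            cfg$n_subfamilies >= 1, cfg$domain_length >= 10,
            cfg$mutation_rate_within_pair >= 0,
            cfg$mutation_rate_within_pair < 1,
            cfg$subfamily_divergence >= 0, cfg$subfamily_divergence < 1,
            cfg$domain_divergence >= 0, cfg$domain_divergence < 1,
            cfg$n_tissues >= 1, cfg$baseline_fpkm > 0,
            cfg$noise_sd >= 0,
            cfg$unexpressed_fraction >= 0, cfg$unexpressed_fraction <= 1)
  if (any(cfg$tandem_cluster_sizes > 9L)) {
    fs_stop("tandem cluster of size > 9 cannot fit a 100 kb window")
  }
  if (length(cfg$tandem_cluster_sizes) > cfg$n_chromosomes) {
    fs_stop("more tandem clusters than chromosomes")
  }
  if (cfg$n_segmental_pairs > 0 && cfg$n_chromosomes < 2L) {
    fs_stop("segmental pairs need at least 2 chromosomes")
  }
  singles <- cfg$n_members - sum(cfg$tandem_cluster_sizes) -
    2L * cfg$n_segmental_pairs
  if (singles < cfg$n_unanchored) {
    fs_stop("layout infeasible: %d singleton members but %d unanchored slots",
            singles, cfg$n_unanchored)
  }
  structure(cfg, class = "generator_config")
}

.random_protein <- function(len) paste(sample(AA20, len, TRUE),
                                       collapse = "")

# substitute each position with probability `rate` by a different residue
.mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(AA20, chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

# build one gene model from a protein: random intron count 0..7, CDS cut
# at arbitrary (phase-mixing) positions, strand-aware genomic layout.
# Optionally an extra, non-representative transcript encoding a truncated
# protein. Returns list(gene, proteins) where proteins is a named vector.
.build_gene <- function(gene_id, chrom, start, strand, protein,
                        extra_transcript = FALSE) {
  total_cds <- 3L * (nchar(protein) + 1L)  # + stop codon
  n_intron <- sample(0:7, 1L)
  if (n_intron > 0L) {
    repeat {
      cuts <- sort(sample(seq(10L, total_cds - 10L), n_intron))
      if (all(diff(c(0L, cuts, total_cds)) >= 10L)) break
    }
    piece <- diff(c(0L, cuts, total_cds))
    intron_len <- sample(80:400, n_intron, replace = TRUE)
  } else {
    piece <- total_cds
    intron_len <- integer(0)
  }
  span <- sum(piece) + sum(intron_len)
  # transcription-order offsets within the gene span
  off <- 0L
  iv <- matrix(0L, length(piece), 2L)
  for (k in seq_along(piece)) {
    iv[k, ] <- c(off, off + piece[[k]] - 1L)
    off <- off + piece[[k]] + if (k <= length(intron_len))
      intron_len[[k]] else 0L
  }
  to_genomic <- function(ivm) {
    if (strand == "+") cbind(start + ivm[, 1L], start + ivm[, 2L])
    else {
      gend <- start + span - 1L
      cbind(gend - ivm[, 2L], gend - ivm[, 1L])
    }
  }
  cds <- to_genomic(iv)
  colnames(cds) <- c("start", "end")
  t1 <- list(transcript_id = paste0(gene_id, ".t1"), exons = cds,
             cds = cds, protein_id = paste0(gene_id, ".t1"),
             cds_flagged = FALSE)
  transcripts <- list(t1)
  proteins <- stats::setNames(protein, t1$protein_id)
  if (extra_transcript) {
    trunc <- substr(protein, 1L, max(20L, floor(0.6 * nchar(protein))))
    tl <- 3L * (nchar(trunc) + 1L)
    iv2 <- matrix(c(0L, tl - 1L), 1L, 2L)
    cds2 <- to_genomic(iv2)
    colnames(cds2) <- c("start", "end")
    t2 <- list(transcript_id = paste0(gene_id, ".t2"), exons = cds2,
               cds = cds2, protein_id = paste0(gene_id, ".t2"),
               cds_flagged = FALSE)
    transcripts <- c(transcripts, list(t2))
    proteins <- c(proteins, stats::setNames(trunc, t2$protein_id))
  }
  gene <- list(gene_id = gene_id, chromosome = chrom, start = start,
               end = start + span - 1L, strand = strand,
               transcripts = transcripts)
  list(gene = gene, span = span, proteins = proteins)
}

#' Generate a synthetic family genome with planted ground truth
#'
#' Emits an annotated genome, proteome, domain seed alignment, labelled
#' reference proteins and a `synthetic_truth` record. Members carry a
#' complete copy of a hidden domain consensus (mutated at under 10% of
#' sites); "partial" decoys carry at most half of it and the rest carry
#' none. Planted tandem clusters are consecutive high-similarity genes
#' within 100 kb (with occasional intervening decoys); planted segmental
#' pairs are high-similarity members on different chromosomes. Members
#' fall into labelled subfamilies descended from independent ancestors,
#' and a subset is planted as barely expressed for the FPKM filter.
#'
#' @param config a [generator_config()].
#' @return object of class `family_bundle`: list with `genome`,
#'   `proteome`, `seed_alignment`, `refs`, `ref_labels`, `truth`,
#'   `config`.
#' @export
generate_family_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    L <- config$domain_length
    consensus <- .random_protein(L)
    seed_alignment <- stats::setNames(
      vapply(seq_len(20L), function(i) .mutate_protein(consensus, 0.06), ""),
      sprintf("seed%02d", seq_len(20L)))

    S <- config$n_subfamilies
    # subfamily ancestors keep their flanks and domain separate so
    # divergence can be concentrated in the flanks (domains stay
    # conserved, as in real families)
    ancestors <- lapply(seq_len(S), function(s) {
      list(fN = .random_protein(sample(30:50, 1L)),
           dom = .mutate_protein(consensus, 0.02),
           fC = .random_protein(sample(40:70, 1L)))
    })
    subfam_label <- LETTERS[seq_len(S)]
    descend <- function(anc) {
      paste0(.mutate_protein(anc$fN, config$subfamily_divergence),
             .mutate_protein(anc$dom, config$domain_divergence),
             .mutate_protein(anc$fC, config$subfamily_divergence))
    }

    refs <- character(0); ref_labels <- character(0)
    for (s in seq_len(S)) {
      for (k in seq_len(config$n_refs_per_subfamily)) {
        nm <- sprintf("REF_%s_%d", subfam_label[[s]], k)
        refs[[nm]] <- descend(ancestors[[s]])
        ref_labels[[nm]] <- subfam_label[[s]]
      }
    }

    # ---- member proteins, grouped into clusters / pairs / singles ----
    n_cl <- length(config$tandem_cluster_sizes)
    n_sp <- config$n_segmental_pairs
    singles <- config$n_members - sum(config$tandem_cluster_sizes) - 2L * n_sp
    next_subfam <- function(i) ((i - 1L) %% S) + 1L
    unit_id <- 0L
    gene_ctr <- 0L
    new_gid <- function() {
      gene_ctr <<- gene_ctr + 1L
      sprintf("g%03d", gene_ctr)
    }
    member_prots <- list()   # gene_id -> protein
    member_subfam <- character(0)
    clusters_gids <- list()
    pairs_gids <- list()
    cluster_layout <- list() # per cluster: gene ids in placement order
    for (ci in seq_len(n_cl)) {
      unit_id <- unit_id + 1L
      s <- next_subfam(unit_id)
      head_seq <- descend(ancestors[[s]])
      gids <- character(0)
      for (k in seq_len(config$tandem_cluster_sizes[[ci]])) {
        gid <- new_gid()
        member_prots[[gid]] <- if (k == 1L) head_seq else
          .mutate_protein(head_seq, config$mutation_rate_within_pair)
        member_subfam[[gid]] <- subfam_label[[s]]
        gids <- c(gids, gid)
      }
      clusters_gids[[ci]] <- gids
    }
    for (pi in seq_len(n_sp)) {
      unit_id <- unit_id + 1L
      s <- next_subfam(unit_id)
      a_seq <- descend(ancestors[[s]])
      ga <- new_gid(); gb <- new_gid()
      member_prots[[ga]] <- a_seq
      member_prots[[gb]] <- .mutate_protein(a_seq,
                                            config$mutation_rate_within_pair)
      member_subfam[[ga]] <- member_subfam[[gb]] <- subfam_label[[s]]
      pairs_gids[[pi]] <- c(ga, gb)
    }
    single_gids <- character(0)
    for (si in seq_len(singles)) {
      unit_id <- unit_id + 1L
      s <- next_subfam(unit_id)
      gid <- new_gid()
      member_prots[[gid]] <- descend(ancestors[[s]])
      member_subfam[[gid]] <- subfam_label[[s]]
      single_gids <- c(single_gids, gid)
    }

    # ---- decoys: domain-free and partial-domain ----
    decoy_prots <- list()
    n_partial <- config$n_decoys %/% 2L
    for (di in seq_len(config$n_decoys)) {
      gid <- new_gid()
      decoy_prots[[gid]] <- if (di <= n_partial) {
        paste0(.random_protein(sample(40:80, 1L)),
               .mutate_protein(substr(consensus, 1L, L %/% 2L), 0.05),
               .random_protein(sample(40:80, 1L)))
      } else {
        .random_protein(sample(120:300, 1L))
      }
    }
    decoy_ids <- names(decoy_prots)

    # ---- chromosome layout ----
    chroms <- c("chr00", sprintf("chr%02d", seq_len(config$n_chromosomes)))
    # slots[[chrom]] = list of list(gid, tight)
    slots <- stats::setNames(vector("list", length(chroms)), chroms)
    add_slot <- function(chrom, gid, tight = FALSE) {
      slots[[chrom]][[length(slots[[chrom]]) + 1L]] <<-
        list(gid = gid, tight = tight)
    }
    unanch <- utils::head(single_gids, config$n_unanchored)
    for (gid in unanch) add_slot("chr00", gid)
    anchored <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    decoy_pool <- decoy_ids
    for (ci in seq_along(clusters_gids)) {
      chrom <- anchored[[((ci - 1L) %% length(anchored)) + 1L]]
      gids <- clusters_gids[[ci]]
      for (k in seq_along(gids)) {
        add_slot(chrom, gids[[k]], tight = (k > 1L))
        # occasionally interleave a decoy inside the cluster (still tight)
        if (k < length(gids) && length(decoy_pool) && k == 1L) {
          add_slot(chrom, decoy_pool[[1L]], tight = TRUE)
          decoy_pool <- decoy_pool[-1L]
        }
      }
    }
    for (pi in seq_along(pairs_gids)) {
      ca <- anchored[[((2L * pi - 2L) %% length(anchored)) + 1L]]
      cb <- anchored[[((2L * pi - 1L) %% length(anchored)) + 1L]]
      if (ca == cb) cb <- anchored[[(pi %% length(anchored)) + 1L]]
      add_slot(ca, pairs_gids[[pi]][[1L]])
      add_slot(cb, pairs_gids[[pi]][[2L]])
    }
    rest <- c(setdiff(single_gids, unanch), decoy_pool)
    for (k in seq_along(rest)) {
      add_slot(anchored[[((k - 1L) %% length(anchored)) + 1L]], rest[[k]])
    }

    # ---- realize gene models ----
    all_prots <- c(member_prots, decoy_prots)
    genes <- list()
    proteome <- character(0)
    chrom_len <- stats::setNames(integer(length(chroms)), chroms)
    for (chrom in chroms) {
      pos <- 50000L
      first <- TRUE
      for (slot in slots[[chrom]]) {
        if (!first) {
          # the tight flag marks the start-to-start gap BEFORE this gene
          pos <- pos + if (slot$tight) sample(8000:12000, 1L) else
            sample(150000:250000, 1L)
        }
        first <- FALSE
        prot <- all_prots[[slot$gid]]
        built <- .build_gene(slot$gid, chrom, pos,
                             sample(c("+", "-"), 1L), prot,
                             extra_transcript =
                               slot$gid %in% names(member_prots) &&
                               stats::runif(1) < 0.5)
        genes[[length(genes) + 1L]] <- built$gene
        proteome <- c(proteome, built$proteins)
        chrom_len[[chrom]] <- built$gene$end + 50000L
      }
      if (chrom_len[[chrom]] == 0L) chrom_len[[chrom]] <- 100000L
    }
    genome <- new_annotated_genome(
      data.frame(name = chroms, length = as.integer(chrom_len),
                 stringsAsFactors = FALSE), genes)

    member_ids <- names(member_prots)
    expressed <- sort(sample(member_ids,
                             round((1 - config$unexpressed_fraction) *
                                     length(member_ids))))
    truth <- structure(list(
      member_gene_ids = member_ids,
      decoy_gene_ids = decoy_ids,
      tandem_clusters = clusters_gids,
      segmental_pairs = pairs_gids,
      subfamily_of = member_subfam,
      expressed_gene_ids = expressed), class = "synthetic_truth")

    structure(list(genome = genome, proteome = proteome,
                   seed_alignment = seed_alignment, refs = refs,
                   ref_labels = ref_labels, truth = truth,
                   config = config),
              class = "family_bundle")
  })
}

#' @export
print.family_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic family bundle: %d members, %d decoys, %d chromosomes, seed %d\n",
    length(x$truth$member_gene_ids), length(x$truth$decoy_gene_ids),
    nrow(x$genome$chromosomes), x$config$seed))
  invisible(x)
}

#' Generate a synthetic FPKM matrix with known expressed/unexpressed sets
#'
#' Genes planted as expressed draw log-normal FPKM around tissue-specific
#' means (one strongly upregulated "home" tissue per gene); genes planted
#' as barely expressed draw all values uniformly in `[0, 2)`, so the
#' FPKM < 2 filter has an exact oracle.
#'
#' @param truth a `synthetic_truth` from [generate_family_genome()].
#' @param config the matching [generator_config()].
#' @return numeric FPKM matrix (member genes x tissues).
#' @export
generate_expression_matrix <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tissues <- if (config$n_tissues == 12L) TISSUES12 else
    sprintf("tissue%02d", seq_len(config$n_tissues))
  genes <- truth$member_gene_ids
  with_seed(config$seed + 1000L, {
    m <- matrix(0, length(genes), length(tissues),
                dimnames = list(genes, tissues))
    for (g in genes) {
      if (g %in% truth$expressed_gene_ids) {
        base <- config$baseline_fpkm * 2^stats::rnorm(1L, 0, 0.5)
        eff <- rep(1, length(tissues))
        eff[[sample(seq_along(tissues), 1L)]] <- 8
        m[g, ] <- exp(log(base * eff) +
                        stats::rnorm(length(tissues), 0, config$noise_sd))
      } else {
        m[g, ] <- stats::runif(length(tissues), 0, 2)
      }
    }
    m
  })
}

#' Generate a synthetic qPCR Cq table with planted fold changes
#'
#' Cq values follow `Cq = baseline_cq - log2(abundance) + noise`; the
#' reference gene has abundance 1 in every condition, so its Cq is
#' constant in expectation. The default layout is 3 biological x 2
#' technical replicates.
#'
#' @param genes target gene names.
#' @param conditions condition names; the first is the control
#'   (calibrator).
#' @param config a [generator_config()] (supplies the seed).
#' @param fold optional genes x conditions matrix of planted relative
#'   abundance (control column forced to 1); random powers of two by
#'   default.
#' @param reference_gene reference gene name (default `"ef1a"`).
#' @param noise_sd Cq noise standard deviation (default 0: exact).
#' @param n_bio,n_tech biological and technical replicate counts.
#' @param baseline_cq Cq of unit abundance.
#' @return data.frame with columns `gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `cq`; the planted fold matrix is in attribute
#'   `"planted_fold"`.
#' @export
generate_qpcr_table <- function(genes, conditions, config, fold = NULL,
                                reference_gene = "ef1a", noise_sd = 0,
                                n_bio = 3L, n_tech = 2L,
                                baseline_cq = 24) {
  stopifnot(length(conditions) >= 1L)
  with_seed(config$seed + 2000L, {
    if (is.null(fold)) {
      fold <- matrix(2^sample(-2:3, length(genes) * length(conditions),
                              replace = TRUE),
                     length(genes), length(conditions),
                     dimnames = list(genes, conditions))
    }
    fold[, 1L] <- 1  # control/calibrator
    rows <- list()
    emit <- function(g, abund_by_cond) {
      for (ci in seq_along(conditions)) {
        for (b in seq_len(n_bio)) {
          for (t in seq_len(n_tech)) {
            cq <- baseline_cq - log2(abund_by_cond[[ci]]) +
              stats::rnorm(1L, 0, noise_sd)
            rows[[length(rows) + 1L]] <<- data.frame(
              gene = g, condition = conditions[[ci]], bio_rep = b,
              tech_rep = t, cq = cq, stringsAsFactors = FALSE)
          }
        }
      }
    }
    for (g in genes) emit(g, fold[g, ])
    emit(reference_gene, rep(1, length(conditions)))
    out <- do.call(rbind, rows)
    attr(out, "planted_fold") <- fold
    out
  })
}

#' Simulate an alignment of clearly separated clades
#'
#' Builds a random root sequence, derives `n_clades` clade ancestors at
#' `between` substitutions/site from it, and mutates each into
#' `per_clade` descendants at `within` substitutions/site. The true
#' clade structure is unambiguous while every pairwise distance stays
#' defined — the standard fixture for bootstrap calibration.
#'
#' @param n_clades,per_clade clade count and members per clade.
#' @param length alignment length in residues.
#' @param within substitutions/site within a clade.
#' @param between substitutions/site from the root to each clade
#'   ancestor.
#' @param seed RNG seed.
#' @return named character vector of aligned sequences; attribute
#'   `"clades"` maps each name to its true clade.
#' @export
simulate_clade_alignment <- function(n_clades = 4L, per_clade = 5L,
                                     length = 300L, within = 0.05,
                                     between = 0.4, seed = 1L) {
  with_seed(seed, {
    root <- .random_protein(length)
    seqs <- character(0); clade <- character(0)
    for (cl in seq_len(n_clades)) {
      anc <- .mutate_protein(root, between)
      for (k in seq_len(per_clade)) {
        nm <- sprintf("cl%s_%02d", LETTERS[[cl]], k)
        seqs[[nm]] <- .mutate_protein(anc, within)
        clade[[nm]] <- LETTERS[[cl]]
      }
    }
    attr(seqs, "clades") <- clade
    seqs
  })
}

#' Write a synthetic bundle to standard files
#'
#' Emits `proteome.fasta`, `genome.gff3`, `seed_alignment.fasta`,
#' `refs.fasta`, `ref_labels.tsv` and `truth.json` under `dir`.
#'
#' @param bundle a `family_bundle`.
#' @param dir output directory (created if missing).
#' @return named vector of the written paths, invisibly.
#' @export
write_family_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "family_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             gff = file.path(dir, "genome.gff3"),
             seed_alignment = file.path(dir, "seed_alignment.fasta"),
             refs = file.path(dir, "refs.fasta"),
             ref_labels = file.path(dir, "ref_labels.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(bundle$proteome, paths[["proteome"]])
  write_gff3(bundle$genome, paths[["gff"]])
  write_fasta(bundle$seed_alignment, paths[["seed_alignment"]])
  write_fasta(bundle$refs, paths[["refs"]])
  writeLines(c("leaf\tlabel",
               paste(names(bundle$ref_labels), bundle$ref_labels,
                     sep = "\t")),
             paths[["ref_labels"]])
  jsonlite::write_json(unclass(bundle$truth), paths[["truth"]],
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}
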
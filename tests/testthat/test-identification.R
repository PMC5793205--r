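test_that("profile columns score by the log-odds formula", {
  # identical sequences, uniform background: the observed residue has
  # the maximal score in every column
  aln <- c(a = "MKVW", b = "MKVW", c = "MKVW")
  prof <- build_profile(aln, pseudocount = 1)
  expect_equal(prof$ncols, 4L)
  obs <- strsplit("MKVW", "")[[1L]]
  for (j in seq_len(4L)) {
    expect_equal(names(which.max(prof$scores[, j])), obs[[j]])
  }

  # column A,A,C,C with uniform bg and vanishing pseudocount:
  # score(A) = score(C) = log2(0.5 / 0.05) = log2(10)
  aln2 <- c(s1 = "A", s2 = "A", s3 = "C", s4 = "C")
  prof2 <- build_profile(aln2, pseudocount = 1e-9)
  expect_equal(unname(prof2$scores["A", 1L]), log2(10), tolerance = 1e-6)
  expect_equal(unname(prof2$scores["C", 1L]), log2(10), tolerance = 1e-6)

  # majority-gap columns are dropped
  aln3 <- c(a = "M-A", b = "M-A", c = "M-A")
  prof3 <- build_profile(aln3)
  expect_equal(prof3$ncols, 2L)

  expect_error(build_profile(c(a = "MK", b = "MKV")), "equal length")
  expect_error(build_profile(c(a = "MK", b = "MK"), pseudocount = 0),
               "pseudocount")
})

test_that("glocal scan equals brute-force enumeration on small cases", {
  set.seed(42)
  for (rep in seq_len(25L)) {
    ncol <- sample(3:6, 1L)
    seed_aln <- setNames(
      vapply(1:4, function(i) random_peptide(ncol), ""),
      paste0("s", 1:4))
    prof <- build_profile(seed_aln)
    target <- random_peptide(sample(4:9, 1L))
    # S[i, j] = profile column i scored against target residue j
    S <- t(prof$scores[strsplit(target, "")[[1L]], , drop = FALSE])
    expected <- bf_glocal_score(S, 11, 1)
    hit <- scan_profile(target, prof, report_threshold = -Inf)
    got <- if (is.null(hit)) NA_real_ else hit$score
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("scan_profile finds exact consensus with full coverage", {
  set.seed(7)
  # conserved alignment: near-identical sequences give a sharp profile
  base <- random_peptide(20)
  seed_aln <- setNames(vapply(1:6, function(i) mutate_peptide(base, 0.05),
                              ""), paste0("s", 1:6))
  prof <- build_profile(seed_aln)
  consensus <- paste(rownames(prof$scores)[apply(prof$scores, 2L,
                                                 which.max)],
                     collapse = "")
  protein <- paste0(random_peptide(20), consensus, random_peptide(15))
  hit <- scan_profile(protein, prof)
  expect_equal(hit$profile_coverage, 1.0)
  expect_equal(hit$score, sum(apply(prof$scores, 2L, max)),
               tolerance = 1e-9)
  expect_equal(hit$target_span, c(21L, 20L + prof$ncols))

  # half the consensus: coverage about one half
  half <- paste0(random_peptide(20), substr(consensus, 1L, 10L),
                 random_peptide(15))
  hh <- scan_profile(half, prof, report_threshold = -Inf)
  expect_lt(hh$profile_coverage, 0.9)

  # unrelated random proteins score below 0 bits against a long profile
  set.seed(8)
  seed_aln2 <- setNames(replicate(8, random_peptide(40)), paste0("t", 1:8))
  prof2 <- build_profile(seed_aln2)
  hits <- vapply(seq_len(100L), function(i) {
    h <- scan_profile(random_peptide(200), prof2)
    is.null(h)
  }, TRUE)
  expect_true(all(hits))

  expect_null(scan_profile("", prof))
})

test_that("representative transcript selection follows longest-CDS", {
  mk_tr <- function(id, len) {
    list(transcript_id = id, exons = matrix(c(1L, len), 1L),
         cds = matrix(c(1L, len), 1L), protein_id = id,
         cds_flagged = FALSE)
  }
  gene <- list(gene_id = "g1", chromosome = "chr01", start = 1L,
               end = 450L, strand = "+",
               transcripts = list(mk_tr("g1.t1", 300L), mk_tr("g1.t2", 450L)))
  prot <- c(g1.t1 = "M", g1.t2 = "M")
  expect_equal(select_representative(gene, prot), "g1.t2")

  tie <- gene
  tie$transcripts <- list(mk_tr("g1.tb", 300L), mk_tr("g1.ta", 300L))
  expect_equal(select_representative(tie, c(g1.tb = "M", g1.ta = "M")),
               "g1.ta")

  single <- gene
  single$transcripts <- list(mk_tr("g1.t1", 300L))
  expect_equal(select_representative(single, prot), "g1.t1")

  expect_error(select_representative(gene, c(zzz = "M")), "no coding")
})

test_that("identify_family recovers exactly the planted members", {
  cfg <- generator_config(seed = 3, n_members = 10L, n_decoys = 5L,
                          tandem_cluster_sizes = c(2L),
                          n_segmental_pairs = 1L, n_unanchored = 1L)
  b <- generate_family_genome(cfg)
  prof <- build_profile(b$seed_alignment)
  mem <- suppressWarnings(identify_family(b$proteome, b$genome, prof,
                                          prefix = "SYN"))
  expect_setequal(mem$gene_id, b$truth$member_gene_ids)
  # precision and recall both 1
  expect_length(intersect(mem$gene_id, b$truth$decoy_gene_ids), 0)

  # names are dense ranks in chromosome order, pseudo-chromosome first
  expect_equal(mem$name, paste0("SYN", seq_len(nrow(mem))))
  expect_equal(mem$chromosome[[1L]], "chr00")
  ord <- order(match(mem$chromosome, b$genome$chromosomes$name),
               mem$start, mem$gene_id)
  expect_equal(ord, seq_len(nrow(mem)))
})

test_that("identification is invariant to proteome input order", {
  cfg <- generator_config(seed = 9, n_members = 8L, n_decoys = 4L,
                          tandem_cluster_sizes = c(2L),
                          n_segmental_pairs = 1L, n_unanchored = 1L)
  b <- generate_family_genome(cfg)
  prof <- build_profile(b$seed_alignment)
  m1 <- suppressWarnings(identify_family(b$proteome, b$genome, prof))
  shuffled <- b$proteome[sample(length(b$proteome))]
  m2 <- suppressWarnings(identify_family(shuffled, b$genome, prof))
  expect_equal(m1$name, m2$name)
  expect_equal(m1$gene_id, m2$gene_id)
})
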
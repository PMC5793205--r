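test_that("global alignment handles identity and single-gap cases", {
  aln <- global_align("MKV", "MKV")
  expect_equal(aln$aligned_a, "MKV")
  expect_equal(alignment_similarity(aln), 1.0)
  expect_equal(alignment_coverage(aln), 1.0)

  aln2 <- global_align("MKV", "MV")
  ga <- strsplit(aln2$aligned_a, "")[[1L]]
  gb <- strsplit(aln2$aligned_b, "")[[1L]]
  expect_equal(sum(gb == "-"), 1L)
  expect_equal(sum(ga == "-"), 0L)
  # degapping recovers the inputs exactly
  expect_equal(paste(ga[ga != "-"], collapse = ""), "MKV")
  expect_equal(paste(gb[gb != "-"], collapse = ""), "MV")
})

test_that("alignment score equals exhaustive enumeration", {
  sub <- blosum62()
  set.seed(4)
  for (i in seq_len(60L)) {
    la <- sample(1:6, 1L); lb <- sample(1:6, 1L)
    a <- random_peptide(la); b <- random_peptide(lb)
    open <- sample(c(5, 10), 1L); ext <- sample(c(0.5, 1), 1L)
    aln <- global_align(a, b, sub, open, ext)
    expect_equal(aln$score, bf_global_score(a, b, sub, open, ext),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("duplication calls apply strict coverage and similarity rules", {
  mk_members <- function(prots) {
    df <- data.frame(name = names(prots), gene_id = names(prots),
                     transcript_id = names(prots), chromosome = "chr01",
                     start = seq_along(prots) * 1000L,
                     end = seq_along(prots) * 1000L + 100L,
                     strand = "+", score = 1, coverage = 1,
                     protein = unname(prots), stringsAsFactors = FALSE)
    class(df) <- c("family_members", class(df))
    df
  }
  p <- random_peptide(80)
  same <- mk_members(c(a = p, b = p))
  calls <- call_duplications(same)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$coverage, 1.0)
  expect_equal(calls$similarity, 1.0)

  # roughly 50% identity: rejected
  set.seed(12)
  q <- paste0(substr(p, 1, 40), random_peptide(40))
  halfish <- mk_members(c(a = p, b = q))
  expect_equal(nrow(call_duplications(halfish)), 0L)
  expect_error(call_duplications(mk_members(c(a = p))), "at least 2")
})

test_that("planted duplicate pairs are recovered on synthetic genomes", {
  b <- generate_family_genome(small_config())
  prof <- build_profile(b$seed_alignment)
  mem <- suppressWarnings(identify_family(b$proteome, b$genome, prof))
  calls <- call_duplications(mem)
  n2g <- setNames(mem$gene_id, mem$name)
  called <- apply(calls, 1L, function(r) {
    paste(sort(unname(n2g[c(r[["gene_a"]], r[["gene_b"]])])),
          collapse = ",")
  })
  planted_pairs <- c(
    vapply(b$truth$segmental_pairs,
           function(p) paste(sort(p), collapse = ","), ""),
    unlist(lapply(b$truth$tandem_clusters, function(cl) {
      combn(sort(cl), 2L, paste, collapse = ",")
    })))
  expect_true(all(planted_pairs %in% called))
})

test_that("classification separates tandem from segmental", {
  # hand-built genome: three family genes close together on chr01, one
  # far away on chr01, one on chr02
  mk_gene <- function(id, chrom, start, len = 900L) {
    list(gene_id = id, chromosome = chrom, start = start,
         end = start + len - 1L, strand = "+",
         transcripts = list(list(transcript_id = paste0(id, ".t1"),
                                 exons = matrix(c(start, start + len - 1L),
                                                1L),
                                 cds = matrix(c(start, start + len - 1L),
                                              1L),
                                 protein_id = paste0(id, ".t1"),
                                 cds_flagged = FALSE)))
  }
  genes <- list(mk_gene("gA", "chr01", 10000L),
                mk_gene("gB", "chr01", 60000L),   # 50 kb from gA
                mk_gene("gC", "chr01", 75000L),   # 15 kb from gB
                mk_gene("gD", "chr01", 300000L),  # 290 kb away
                mk_gene("gE", "chr02", 10000L),
                # decoy filler genes between gA and gB (3 intervening)
                mk_gene("d1", "chr01", 20000L), mk_gene("d2", "chr01", 30000L),
                mk_gene("d3", "chr01", 40000L))
  genome <- new_annotated_genome(
    data.frame(name = c("chr01", "chr02"), length = c(400000L, 100000L)),
    genes)
  p <- random_peptide(90)
  members <- data.frame(
    name = c("gA", "gB", "gC", "gD", "gE"),
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    transcript_id = paste0(c("gA", "gB", "gC", "gD", "gE"), ".t1"),
    chromosome = c("chr01", "chr01", "chr01", "chr01", "chr02"),
    start = c(10000L, 60000L, 75000L, 300000L, 10000L),
    end = c(10899L, 60899L, 75899L, 300899L, 10899L),
    strand = "+", score = 1, coverage = 1, protein = p,
    stringsAsFactors = FALSE)
  class(members) <- c("family_members", class(members))
  calls <- call_duplications(members)  # identical proteins: all pairs
  cls <- classify_duplications(calls, genome, members)

  # 50 kb apart with 3 intervening genes -> tandem; chain merges
  # gA-gB-gC into one cluster
  expect_length(cls$clusters, 1L)
  expect_equal(cls$clusters[[1L]]$members, c("gA", "gB", "gC"))
  # same chromosome, 290-225 kb apart -> segmental; different
  # chromosome -> segmental
  seg <- cls$segmental
  expect_true(all(c("gD", "gE") %in% c(seg$gene_a, seg$gene_b)))
  get_cls <- function(a, b) {
    cls$calls$classification[cls$calls$gene_a == a & cls$calls$gene_b == b]
  }
  expect_equal(get_cls("gA", "gD"), "segmental")
  expect_equal(get_cls("gA", "gE"), "segmental")
  expect_equal(get_cls("gA", "gB"), "tandem")
  expect_error(classify_duplications(
    data.frame(gene_a = "nope", gene_b = "gA", coverage = 1,
               similarity = 1), genome, members), "unknown gene")
})

test_that("too many intervening genes blocks the tandem call", {
  mk_gene <- function(id, chrom, start, len = 300L) {
    list(gene_id = id, chromosome = chrom, start = start,
         end = start + len - 1L, strand = "+",
         transcripts = list(list(transcript_id = paste0(id, ".t1"),
                                 exons = matrix(c(start, start + len - 1L),
                                                1L),
                                 cds = matrix(c(start, start + len - 1L),
                                              1L),
                                 protein_id = paste0(id, ".t1"),
                                 cds_flagged = FALSE)))
  }
  fillers <- lapply(seq_len(6L), function(k) {
    mk_gene(paste0("f", k), "chr01", 10000L + k * 5000L)
  })
  genes <- c(list(mk_gene("gA", "chr01", 5000L),
                  mk_gene("gB", "chr01", 50000L)), fillers)
  genome <- new_annotated_genome(
    data.frame(name = "chr01", length = 100000L), genes)
  p <- random_peptide(60)
  members <- data.frame(name = c("gA", "gB"), gene_id = c("gA", "gB"),
                        transcript_id = c("gA.t1", "gB.t1"),
                        chromosome = "chr01", start = c(5000L, 50000L),
                        end = c(5299L, 50299L), strand = "+", score = 1,
                        coverage = 1, protein = p,
                        stringsAsFactors = FALSE)
  class(members) <- c("family_members", class(members))
  cls <- classify_duplications(call_duplications(members), genome, members)
  # inside the 100 kb window but 6 intervening genes: unclassified
  expect_length(cls$clusters, 0L)
  expect_equal(cls$calls$classification, "unclassified")
})

test_that("results are invariant to member input order", {
  b <- generate_family_genome(small_config(seed = 23))
  prof <- build_profile(b$seed_alignment)
  mem <- suppressWarnings(identify_family(b$proteome, b$genome, prof))
  c1 <- call_duplications(mem)
  mem2 <- mem[rev(seq_len(nrow(mem))), ]
  class(mem2) <- class(mem)
  c2 <- call_duplications(mem2)
  expect_equal(c1, c2)
})
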
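test_that("Poisson distances implement pairwise deletion and -ln(1-p)", {
  dm <- poisson_distance_matrix(c(a = "MKVW", b = "MKVW"))
  expect_equal(dm$p["a", "b"], 0)
  expect_equal(dm$d["a", "b"], 0)

  # 10 sites, 1 difference: p = 0.1, d = -ln(0.9)
  dm2 <- poisson_distance_matrix(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  expect_equal(dm2$p["a", "b"], 0.1)
  expect_equal(dm2$d["a", "b"], -log(0.9), tolerance = 1e-12)

  # pairwise deletion: only columns 1 and 3 are comparable
  dm3 <- poisson_distance_matrix(c(a = "A-C", b = "AGC"))
  expect_equal(dm3$p["a", "b"], 0)
  dm4 <- poisson_distance_matrix(c(a = "A-C", b = "GGC"))
  expect_equal(dm4$p["a", "b"], 0.5)

  expect_error(poisson_distance_matrix(c(a = "AA", b = "CC")),
               "\\(a, b\\)")
  expect_error(poisson_distance_matrix(c(a = "-A", b = "A-")),
               "comparable")
})

test_that("d >= p with equality only at p = 0", {
  set.seed(5)
  for (i in seq_len(20L)) {
    base <- random_peptide(50)
    seqs <- setNames(vapply(1:4, function(k) mutate_peptide(base, 0.4),
                            ""), letters[1:4])
    dm <- poisson_distance_matrix(seqs)
    up <- upper.tri(dm$p)
    expect_true(all(dm$d[up] >= dm$p[up]))
    expect_true(all((dm$d[up] == dm$p[up]) == (dm$p[up] == 0)))
  }
})

test_that("three-taxon NJ matches the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  # a = (dAB + dAC - dBC)/2 = 1, b = 2, c = 3
  lens <- setNames(tr$edge.length[tr$edge[, 2L] <= 3L],
                   tr$tip.label[tr$edge[tr$edge[, 2L] <= 3L, 2L]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ recovers additive four-taxon trees exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(true)
  got <- nj_tree(D[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
  expect_equal(splits_of(got), splits_of(ape::unroot(true)))
  expect_equal(tree_path_lengths(got), D[order(rownames(D)),
                                         order(colnames(D))],
               tolerance = 1e-9)
})

test_that("NJ equals brute-force least squares on additive matrices", {
  set.seed(2)
  for (i in seq_len(12L)) {
    n <- sample(4:6, 1L)
    true <- random_tree(n)
    D <- ape::cophenetic.phylo(true)
    got <- nj_tree(D)
    expect_equal(splits_of(got), splits_of(true))
    # the generating topology is the unique least-squares optimum
    topos <- enumerate_topologies(sort(true$tip.label))
    rss <- vapply(topos, ls_fit_rss, 0, D = D)
    best <- which(rss < 1e-16)
    for (b in best) {
      expect_equal(splits_of(topos[[b]]), splits_of(true))
    }
  }
})

test_that("NJ on ultrametric matrices matches UPGMA topology", {
  set.seed(14)
  for (i in seq_len(10L)) {
    n <- sample(4:7, 1L)
    tr <- ape::rcoal(n)  # ultrametric
    tr$tip.label <- paste0("t", seq_len(n))
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    upgma <- ape::as.phylo(stats::hclust(stats::as.dist(D), "average"))
    expect_equal(splits_of(got), splits_of(ape::unroot(upgma)))
  }
})

test_that("NJ validates its input and clamps negatives", {
  bad <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3L,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "not symmetric")
  expect_error(nj_tree(matrix(0, 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
})

test_that("bootstrap supports are deterministic and well-behaved", {
  aln <- simulate_clade_alignment(n_clades = 3L, per_clade = 3L,
                                  length = 120L, within = 0.05, seed = 2)
  t1 <- suppressWarnings(bootstrap_supports(aln, n_replicates = 25, seed = 10))
  t2 <- suppressWarnings(bootstrap_supports(aln, n_replicates = 25, seed = 10))
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # one replicate: supports are 0 or 100
  t3 <- suppressWarnings(bootstrap_supports(aln, n_replicates = 1, seed = 3))
  sup <- as.numeric(t3$node.label[t3$node.label != ""])
  expect_true(all(sup %in% c(0, 100)))

  # supports invariant to leaf input order
  t4 <- suppressWarnings(bootstrap_supports(rev(aln), n_replicates = 25, seed = 10))
  s1 <- setNames(t1$node.label, vapply(seq_len(t1$Nnode), function(i) {
    paste(sort(ape::extract.clade(t1, length(t1$tip.label) + i)$tip.label),
          collapse = "|")
  }, ""))
  s4 <- setNames(t4$node.label, vapply(seq_len(t4$Nnode), function(i) {
    paste(sort(ape::extract.clade(t4, length(t4$tip.label) + i)$tip.label),
          collapse = "|")
  }, ""))
  common <- intersect(names(s1)[s1 != ""], names(s4)[s4 != ""])
  expect_gt(length(common), 0L)
  expect_identical(s1[common], s4[common])
})

test_that("clean planted clades get high supports", {
  aln <- simulate_clade_alignment(n_clades = 4L, per_clade = 4L,
                                  length = 250L, within = 0.05, seed = 6)
  tr <- suppressWarnings(bootstrap_supports(aln, n_replicates = 50, seed = 1))
  clades <- attr(aln, "clades")
  sp <- famscan:::tree_splits(tr)
  sup <- setNames(as.numeric(tr$node.label[sp$node - length(tr$tip.label)]),
                  sp$split)
  for (cl in unique(clades)) {
    memb <- sort(names(clades)[clades == cl])
    key <- paste(memb, collapse = "|")
    key2 <- paste(sort(setdiff(names(clades), memb)), collapse = "|")
    val <- if (key %in% names(sup)) sup[[key]] else sup[[key2]]
    expect_gte(val, 90)
  }
})

test_that("subfamily assignment follows the nearest supported clade", {
  # query q sister to a single reference labelled I, support 90
  tr <- ape::read.tree(text = paste0(
    "((q:0.1,refI:0.1)90:0.5,(refJ1:0.1,refJ2:0.1)99:0.5,refK:0.6);"))
  labels <- c(refI = "I", refJ1 = "J", refJ2 = "J", refK = "K")
  asn <- assign_subfamilies(tr, labels, support_min = 50)
  expect_equal(asn[["q"]], "I")

  # mixed clade with two labels at every supported edge: unassigned
  tr2 <- ape::read.tree(text = paste0(
    "((q:0.1,(refA:0.1,refB:0.1)80:0.1)90:0.5,refC1:0.6,refC2:0.6);"))
  labels2 <- c(refA = "A", refB = "B", refC1 = "C", refC2 = "C")
  asn2 <- assign_subfamilies(tr2, labels2, support_min = 50)
  expect_equal(asn2[["q"]], "unassigned")

  # low support hides the nearest clade
  tr3 <- ape::read.tree(text = paste0(
    "((q:0.1,refI:0.1)20:0.5,(refJ1:0.1,refJ2:0.1)99:0.5,refK:0.6);"))
  asn3 <- assign_subfamilies(tr3, labels, support_min = 50)
  expect_false(asn3[["q"]] == "I")

  expect_error(assign_subfamilies(tr, c(zz = "A")), "no reference")
})

test_that("planted subfamily labels are recovered through the tree", {
  b <- generate_family_genome(small_config(seed = 31))
  prof <- build_profile(b$seed_alignment)
  mem <- suppressWarnings(identify_family(b$proteome, b$genome, prof))
  seqs <- c(setNames(mem$protein, mem$name), b$refs)
  aligned <- align_proteins(seqs)
  tr <- suppressWarnings(bootstrap_supports(aligned, n_replicates = 50,
                                            seed = 4))
  asn <- assign_subfamilies(tr, setNames(b$ref_labels,
                                         names(b$ref_labels)))
  n2g <- setNames(mem$gene_id, mem$name)
  for (q in names(asn)) {
    expect_equal(asn[[q]], unname(b$truth$subfamily_of[[n2g[[q]]]]),
                 label = q)
  }
})
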
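test_that("normalization equalizes by the grand mean then logs", {
  m <- matrix(c(1, 3, 2, 6), 2L, 2L,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  em <- normalize_matrix(m)
  # grand mean 3: equalized [[1/3, 2/3], [1, 2]]
  expect_equal(unname(em$equalized),
               matrix(c(1, 3, 2, 6) / 3, 2L, 2L))
  expect_equal(mean(em$equalized), 1, tolerance = 1e-12)
  expect_equal(em$logged, log2(em$equalized + 0.01))

  const <- matrix(5, 3L, 4L, dimnames = list(paste0("g", 1:3),
                                             paste0("c", 1:4)))
  emc <- normalize_matrix(const)
  expect_true(all(emc$equalized == 1))
  expect_true(all(abs(emc$logged - log2(1.01)) < 1e-12))

  expect_error(normalize_matrix(matrix(0, 2, 2)), "all-zero")
  expect_error(normalize_matrix(matrix(-1, 2, 2)), ">= 0")
})

test_that("normalization is scale-invariant", {
  set.seed(8)
  m <- matrix(rexp(30, 1 / 10), 5L, 6L,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  e1 <- normalize_matrix(m)
  for (k in c(0.5, 2, 17)) {
    ek <- normalize_matrix(k * m)
    expect_equal(ek$equalized, e1$equalized, tolerance = 1e-12)
    expect_equal(ek$logged, e1$logged, tolerance = 1e-12)
  }
})

test_that("the FPKM filter uses strict less-than in every condition", {
  m <- rbind(low = c(1.9, 0.5, 0.0),
             boundary = c(1.9, 2.0, 0.0),
             high = c(10, 0, 0))
  colnames(m) <- paste0("t", 1:3)
  flt <- filter_expressed(m)
  expect_equal(flt$excluded, "low")
  expect_setequal(flt$kept, c("boundary", "high"))
  # kept and excluded partition the genes
  expect_setequal(c(flt$kept, flt$excluded), rownames(m))

  b <- generate_family_genome(small_config(seed = 41))
  cfg <- small_config(seed = 41)
  fm <- generate_expression_matrix(b$truth, cfg)
  flt2 <- filter_expressed(fm)
  expect_setequal(flt2$excluded,
                  setdiff(b$truth$member_gene_ids,
                          b$truth$expressed_gene_ids))
})

test_that("average-linkage clustering merges near rows first", {
  m <- rbind(a = c(0, 0), b = c(0, 1), c = c(10, 10))
  hc <- cluster_heatmap(m)
  expect_equal(sort(hc$merge[1L, ]), c(-2L, -1L))  # a and b first

  dup <- m; rownames(dup) <- c("a", "a", "c")
  expect_error(cluster_heatmap(dup), "unique")
  bad <- m; bad[1L, 1L] <- NA
  expect_error(cluster_heatmap(bad), "non-finite")
  expect_error(cluster_heatmap(m[1L, , drop = FALSE]), "at least 2")
})

test_that("linkage heights are monotone and match direct recomputation", {
  set.seed(3)
  for (i in seq_len(25L)) {
    n <- sample(4:9, 1L)
    m <- matrix(rnorm(n * 4L), n, 4L,
                dimnames = list(paste0("g", seq_len(n)), paste0("c", 1:4)))
    hc <- cluster_heatmap(m)
    expect_true(all(diff(hc$height) >= -1e-12))
    expect_equal(sort(hc$height), bf_average_linkage_heights(m),
                 tolerance = 1e-9)
  }
})

test_that("qPCR fold changes follow the dCt / ddCt identities", {
  mk_cq <- function(target_cq_by_cond, ref_cq = 20) {
    rows <- list()
    for (cond in names(target_cq_by_cond)) {
      for (b in 1:3) for (t in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = "gX", condition = cond, bio_rep = b, tech_rep = t,
          cq = target_cq_by_cond[[cond]])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = "ref", condition = cond, bio_rep = b, tech_rep = t,
          cq = ref_cq)
      }
    }
    do.call(rbind, rows)
  }
  # Cq_target == Cq_ref: dct fold = 1
  tab <- mk_cq(c(CK = 20))
  rel <- relative_expression(tab, "ref", mode = "dct")
  expect_equal(rel$fold, 1)

  # treatment Cq drops by 1, reference unchanged: ddct fold = 2;
  # the calibrator condition itself has fold exactly 1
  tab2 <- mk_cq(c(CK = 22, heat = 21))
  rel2 <- relative_expression(tab2, "ref", mode = "ddct",
                              control_condition = "CK")
  expect_equal(rel2$fold[rel2$condition == "heat"], 2)
  expect_equal(rel2$fold[rel2$condition == "CK"], 1)

  expect_error(relative_expression(tab2, "ref", mode = "ddct"),
               "control")
  expect_error(relative_expression(tab2, "missing", mode = "dct"),
               "reference gene")
})

test_that("technical replicates collapse before biological statistics", {
  rows <- expand.grid(bio_rep = 1:3, tech_rep = 1:2)
  # technical replicates disagree wildly but average to the same Cq
  tab <- rbind(
    data.frame(gene = "gX", condition = "CK", rows,
               cq = ifelse(rows$tech_rep == 1L, 18, 22)),
    data.frame(gene = "ref", condition = "CK", rows, cq = 20))
  rel <- relative_expression(tab, "ref", mode = "dct")
  expect_equal(rel$fold, 1)     # mean tech Cq is 20 = reference
  expect_equal(rel$sd_fold, 0)  # no biological variation left
})

test_that("planted inductions are recovered from noisy synthetic Cq", {
  cfg <- small_config(seed = 2)
  fold <- matrix(c(1, 4, 1, 0.5), 2L, 2L, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("CK", "heat")))
  cq <- generate_qpcr_table(c("g1", "g2"), c("CK", "heat"), cfg,
                            fold = fold, noise_sd = 0.05)
  rel <- relative_expression(cq, "ef1a", mode = "ddct",
                             control_condition = "CK")
  f <- function(g, cond) rel$fold[rel$gene == g & rel$condition == cond]
  expect_equal(f("g1", "heat"), 4, tolerance = 0.25)
  expect_equal(f("g2", "heat"), 0.5, tolerance = 0.15)
})
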
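test_that("median-of-ratios size factors recover a planted 2x depth ratio", {
  m <- matrix(c(10, 50, 200, 1000,
                20, 100, 400, 2000), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("A", "B")))
  sf <- size_factors(count_matrix(m, "RNA"))
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  same <- size_factors(count_matrix(cbind(A = m[, 1], B = m[, 1]), "RNA"))
  expect_equal(unname(same), c(1, 1))

  shuffled <- m[c(3, 1, 4, 2), ]
  expect_equal(size_factors(count_matrix(shuffled, "RNA")),
               size_factors(count_matrix(m, "RNA")))
})

test_that("scaling one sample's counts scales its relative size factor", {
  set.seed(11)
  m <- matrix(rpois(300, 100) + 1, 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("A", "B", "C")))
  sf1 <- size_factors(count_matrix(m, "RNA"))
  m2 <- m; m2[, "B"] <- m2[, "B"] * 5L
  sf2 <- size_factors(count_matrix(m2, "RNA"))
  expect_equal(unname(sf2["B"] / sf2["A"]), unname(5 * sf1["B"] / sf1["A"]),
               tolerance = 1e-12)
  expect_equal(unname(sf2["C"] / sf2["A"]), unname(sf1["C"] / sf1["A"]))
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  set.seed(12)
  m <- matrix(rnbinom(500 * 4, mu = 200, size = 10), 500, 4,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:4)))
  ours <- size_factors(count_matrix(m, "RNA"))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # identical up to the geometric-mean-1 rescaling
  expect_equal(unname(ours / ref), rep(unname(ours[1] / ref[1]), 4),
               tolerance = 1e-10)
})

test_that("size factors error without an all-positive gene", {
  m <- matrix(c(0, 5, 5, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(size_factors(count_matrix(m, "RNA")), "total-count")
})

test_that("moment dispersion estimates recover the simulated alpha", {
  # NB with mu = 100, alpha = 0.1, 200 replicates, 2000 genes
  set.seed(1)
  n_rep <- 200
  m <- matrix(rnbinom(2000 * n_rep, mu = 100, size = 10), 2000, n_rep,
              dimnames = list(sprintf("g%04d", 1:2000),
                              paste0("RNA_WT_", 1:n_rep)))
  sheet <- sample_sheet(colnames(m), rep("WT", n_rep), rep("RNA", n_rep),
                        1:n_rep)
  disp <- estimate_dispersion(count_matrix(m, "RNA"), sheet,
                              method = "moments")
  expect_gt(mean(disp$dispersion), 0.08)
  expect_lt(mean(disp$dispersion), 0.12)
})

test_that("dispersion limits: constant counts floor at 1e-8, Poisson stays small", {
  m <- matrix(50L, 10, 4, dimnames = list(paste0("g", 1:10),
                                          paste0("RNA_WT_", 1:4)))
  sheet <- sample_sheet(colnames(m), rep("WT", 4), rep("RNA", 4), 1:4)
  disp <- estimate_dispersion(count_matrix(m, "RNA"), sheet,
                              method = "moments")
  expect_equal(disp$dispersion, rep(1e-8, 10))

  set.seed(2)
  mp <- matrix(rpois(200 * 100, 100), 200, 100,
               dimnames = list(sprintf("g%03d", 1:200),
                               paste0("RNA_WT_", 1:100)))
  shp <- sample_sheet(colnames(mp), rep("WT", 100), rep("RNA", 100), 1:100)
  dp <- estimate_dispersion(count_matrix(mp, "RNA"), shp,
                            method = "moments")
  expect_lt(mean(dp$dispersion), 0.005)
})

test_that("single-replicate groups are skipped; all-single errors", {
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(paste0("g", 1:10),
                              c("RNA_WT_1", "RNA_WT_2", "RNA_KO_1",
                                "RNA_WT_KD_1")))
  sheet <- sample_sheet(colnames(m), c("WT", "WT", "KO", "WT_KD"),
                        rep("RNA", 4), c(1, 2, 1, 1))
  expect_silent(estimate_dispersion(count_matrix(m, "RNA"), sheet))
  m1 <- m[, c(1, 3)]
  sh1 <- sample_sheet(colnames(m1), c("WT", "KO"), rep("RNA", 2), c(1, 1))
  expect_error(estimate_dispersion(count_matrix(m1, "RNA"), sh1),
               "single replicate")
})

test_that("BH adjustment matches the worked example and stays in bounds", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
})

test_that("BH agrees with the reference step-up on 1000 random vectors", {
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
})

test_that("Wald test matches hand arithmetic on planted group means", {
  # deterministic counts: lfc and the z -> p mapping are checkable by hand
  cm <- toy_count_matrix(rep(100, 5), rep(100, 5))
  sheet <- toy_sheet()
  de <- wald_test(cm, sheet, "WT", "KO")
  expect_equal(de$lfc, rep(0, 5))
  expect_equal(de$direction, rep("ns", 5))
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 1e-3)

  set.seed(21)
  m <- matrix(rnbinom(200 * 6, mu = 300, size = 20), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200),
                              c(paste0("RNA_WT_", 1:3),
                                paste0("RNA_KO_", 1:3))))
  m[1:50, 4:6] <- m[1:50, 4:6] * 4L
  cm2 <- count_matrix(m, "RNA")
  fwd <- wald_test(cm2, sheet, "WT", "KO")
  rev <- wald_test(cm2, sheet, "KO", "WT")
  expect_equal(fwd$lfc, -rev$lfc)
  expect_equal(fwd$wald, -rev$wald)
  expect_equal(fwd$p, rev$p)
  expect_true(all(fwd$padj >= fwd$p))
})

test_that("Wald test recovers planted two-fold effects with duplicates", {
  # responders limited to 20% of genes: median-of-ratios normalization
  # assumes the bulk of the transcriptome is unchanged
  ct <- default_class_table(p_rescued = 0, p_nonrescued = 0.2)
  sp <- sim_spec(seed = 33, n_genes = 2000, replicates = 2,
                 library_size = 1e6, class_table = ct)
  g <- generate_counts(sp)
  de <- suppressMessages(wald_test(g$rna, g$sheet, "WT", "KO"))
  truth <- g$truth[match(de$gene_id, g$truth$gene_id), ]
  up <- truth$lfc_ko_rna == 2
  down <- truth$lfc_ko_rna == -2
  expect_lt(abs(median(de$lfc[up]) - 2), 0.2)
  expect_lt(abs(median(de$lfc[down]) + 2), 0.2)
})

test_that("direction calls respect the two-fold and alpha thresholds jointly", {
  ct <- default_class_table(p_rescued = 0, p_nonrescued = 0.2)
  sp <- sim_spec(seed = 14, n_genes = 500, replicates = 3, class_table = ct)
  g <- generate_counts(sp)
  de <- suppressMessages(wald_test(g$rna, g$sheet, "WT", "KO"))
  up <- de$direction == "up"
  expect_true(all(de$padj[up] < 0.05 & de$lfc[up] >= 1))
  down <- de$direction == "down"
  expect_true(all(de$padj[down] < 0.05 & de$lfc[down] <= -1))
  ns <- de$direction == "ns"
  expect_true(all(de$padj[ns] >= 0.05 | abs(de$lfc[ns]) < 1))
})

test_that("wald_test rejects unknown conditions and drops all-zero genes", {
  cm <- toy_count_matrix(c(0, 10, 20), c(0, 10, 20))
  sheet <- toy_sheet()
  expect_error(wald_test(cm, sheet, "WT", "KO_KD"), "no RNA samples")
  expect_message(de <- wald_test(cm, sheet, "WT", "KO"), "all-zero")
  expect_equal(nrow(de), 2)
})

test_that("count matrices round-trip through TSV", {
  m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_counts(tmp, "RNA")
  expect_equal(cm$counts, m)
})
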
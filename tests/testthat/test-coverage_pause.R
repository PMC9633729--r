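toy_positions <- function() {
  # 3 reads assigned to position 5 (0-based), 1 to position 7, one sample
  data.frame(transcript_id = "tx",
             start = c(5, 5, 5, 7), end = c(35, 35, 35, 37),
             read_id = paste0("r", 1:4), weight = 1L,
             sample_id = "s1", stringsAsFactors = FALSE)
}

test_that("position assignment follows the 5' end or a clipped P-site offset", {
  expect_equal(assign_position(100, 130), 100L)
  expect_equal(assign_position(100, 130, "p_site"), 112L)
  expect_equal(assign_position(100, 105, "p_site"), 104L)  # clipped
  expect_error(assign_position(10, 10), "start < end")
})

test_that("coverage profiles count reads per nucleotide in rpm", {
  tab <- read_position_table(toy_positions(), library_sizes = c(s1 = 1e6),
                             transcript_lengths = c(tx = 100))
  prof <- coverage_profile(tab, "tx", "s1")
  expect_equal(prof$values[6], 3)   # 0-based 5 -> 1-based 6
  expect_equal(prof$values[8], 1)
  expect_equal(sum(prof$values), 4)
  # conservation: rpm total * lib / 1e6 equals assigned reads
  expect_equal(sum(prof$values) * prof$library_size / 1e6, 4)
})

test_that("doubling weights and library size leaves the profile unchanged", {
  pos <- toy_positions()
  tab1 <- read_position_table(pos, library_sizes = c(s1 = 1e6),
                              transcript_lengths = c(tx = 100))
  pos2 <- pos; pos2$weight <- 2L
  tab2 <- read_position_table(pos2, library_sizes = c(s1 = 2e6),
                              transcript_lengths = c(tx = 100))
  expect_equal(coverage_profile(tab1, "tx", "s1")$values,
               coverage_profile(tab2, "tx", "s1")$values)
})

test_that("an absent transcript yields a zero profile with a warning", {
  tab <- read_position_table(toy_positions(), library_sizes = c(s1 = 1e6),
                             transcript_lengths = c(tx = 100, other = 50))
  expect_warning(prof <- coverage_profile(tab, "other", "s1"), "no reads")
  expect_equal(prof$values, numeric(50))
})

test_that("window counts implement the inclusive 25-nt window", {
  pos <- data.frame(transcript_id = "tx",
                    start = c(429, 441, 453, 454),  # 1-based 430,442,454,455
                    end = c(459, 471, 483, 484),
                    read_id = paste0("r", 1:4), weight = 1L,
                    sample_id = "s1", stringsAsFactors = FALSE)
  tab <- read_position_table(pos, library_sizes = c(s1 = 1e6),
                             transcript_lengths = c(tx = 1000))
  expect_equal(window_count(tab, "tx", "s1", 442), 3L)  # [430, 454]
  expect_equal(window_count(tab, "tx", "s1", 442, halfwidth = 0), 1L)
  expect_warning(window_count(tab, "tx", "s1", 5), "truncated")
})

test_that("window counts agree with the interval-membership oracle", {
  set.seed(123)
  for (i in 1:20) {
    n <- 50
    start <- sample(0:500, n, replace = TRUE)
    pos <- data.frame(transcript_id = "tx", start = start,
                      end = start + 30,
                      read_id = sprintf("r%03d", sample(n, n)),
                      weight = 1L, sample_id = "s1",
                      stringsAsFactors = FALSE)
    tab <- read_position_table(pos, library_sizes = c(s1 = 1e6),
                               transcript_lengths = c(tx = 600))
    center <- sample(30:500, 1)
    expect_equal(window_count(tab, "tx", "s1", center),
                 oracle_window_count(pos, center, 12))
  }
})

test_that("window count equals the per-nucleotide sum for unique reads", {
  set.seed(124)
  start <- sample(50:150, 200, replace = TRUE)
  pos <- data.frame(transcript_id = "tx", start = start, end = start + 28,
                    read_id = sprintf("u%03d", 1:200), weight = 1L,
                    sample_id = "s1", stringsAsFactors = FALSE)
  tab <- read_position_table(pos, library_sizes = c(s1 = 1e6),
                             transcript_lengths = c(tx = 400))
  prof <- coverage_profile(tab, "tx", "s1")
  raw_per_nt <- prof$values * 1e6 / 1e6
  center <- 100
  expect_equal(window_count(tab, "tx", "s1", center),
               as.integer(sum(raw_per_nt[(center - 12):(center + 12)])))
})

test_that("the pooled t test matches closed-form arithmetic", {
  res <- pause_test(c(10, 12), c(30, 28))
  expect_equal(abs(res$t), 12.73, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-abs(res$t), 2))
  expect_equal(res$p, 0.0061, tolerance = 1e-2)

  same <- pause_test(c(5, 7, 6), c(5, 7, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sw <- pause_test(c(30, 28), c(10, 12))
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)
})

test_that("degenerate zero-variance cases are flagged, not mangled", {
  flat <- pause_test(c(10, 10), c(10, 10))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_warning(hard <- pause_test(c(10, 10), c(20, 20)),
                 "machine precision")
  expect_equal(hard$p, 0)
  expect_true(hard$degenerate)
})

test_that("library normalization feeds the t test in reads per million", {
  r1 <- pause_test(c(10, 12), c(30, 28), lib_a = 1e6, lib_b = 1e6)
  r2 <- pause_test(c(20, 24), c(60, 56), lib_a = 2e6, lib_b = 2e6)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$norm_a, r2$norm_a)
})

test_that("scanning identical conditions or an infinite threshold finds nothing", {
  sp <- sim_spec(seed = 21, pause_spec = list(n_reads = 3000,
                                              peak_conditions = character(0)))
  gp <- generate_positions(sp)
  sc <- scan_pauses(gp$table, "tx1", gp$samples$WT, gp$samples$KO_KD)
  expect_equal(nrow(sc), 0)

  sp2 <- sim_spec(seed = 22, pause_spec = list(n_reads = 3000))
  gp2 <- generate_positions(sp2)
  sc2 <- scan_pauses(gp2$table, "tx1", gp2$samples$WT, gp2$samples$KO_KD,
                     min_ratio = Inf)
  expect_equal(nrow(sc2), 0)
})

test_that("a planted 3-fold peak is localized by the scan", {
  sp <- sim_spec(seed = 23)
  gp <- generate_positions(sp)
  sc <- scan_pauses(gp$table, "tx1", gp$samples$WT, gp$samples$KO_KD)
  expect_gt(nrow(sc), 0)
  best <- sc$center[which.max(sc$ratio)]
  expect_lte(abs(best - 442), 2)
  expect_lt(sc$p[which.max(sc$ratio)], 0.05)
})

test_that("pause null calibration stays near the nominal level", {
  # both conditions from the same Poisson window intensity, 4 replicates
  set.seed(13)
  rej <- replicate(1000, {
    suppressWarnings(pause_test(rpois(4, 20), rpois(4, 20))$p) < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("a 3-fold window enrichment is detected with quadruplicates", {
  # window intensities 30 vs 10 at matched 1e6 libraries; with
  # duplicate-level replication the pooled t at df 2 cannot reach 90%
  # power, so power is demonstrated at n = 4 per condition
  set.seed(14)
  hits <- replicate(200, {
    suppressWarnings(pause_test(rpois(4, 10), rpois(4, 30))$p) < 0.05
  })
  expect_gte(mean(hits), 0.90)
})

test_that("BED-like position tables round-trip through TSV", {
  pos <- toy_positions()
  tmp <- tempfile(fileext = ".tsv")
  write.table(pos, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_positions_bed(tmp, library_sizes = c(s1 = 1e6))
  expect_equal(tab$positions$start, pos$start)
  expect_equal(window_count(tab, "tx", "s1", 6, halfwidth = 0,
                            length = 100), 3L)
})
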
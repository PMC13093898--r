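test_that("identical value multisets are non-significant with p = 1", {
  vals <- list(a = as.numeric(1:15), b = as.numeric(1:15))
  r <- compare_scalar_feature(vals, c("a", "b"),
                              stats_config(policy = "nonparametric"))
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  deg <- compare_scalar_feature(list(a = rep(3, 5), b = rep(3, 6)),
                                c("a", "b"), stats_config())
  expect_equal(deg$p_value, 1)
  expect_identical(deg$test_name, "degenerate")
})

test_that("the auto policy keeps its nominal type-I error under the Gaussian null", {
  cfg <- stats_config()
  set.seed(501)
  reps <- 500
  hits <- vapply(seq_len(reps), function(r) {
    vals <- list(a = rnorm(15), b = rnorm(15))
    compare_scalar_feature(vals, c("a", "b"), cfg)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("power under a 1.5-SD shift matches a brute-force oracle within 3 points", {
  cfg <- stats_config()
  reps <- 1000
  set.seed(502)
  power_pkg <- mean(vapply(seq_len(reps), function(r) {
    vals <- list(a = rnorm(12), b = rnorm(12, mean = 1.5))
    compare_scalar_feature(vals, c("a", "b"), cfg)$p_value < 0.05
  }, logical(1)))
  set.seed(502)
  power_oracle <- mean(vapply(seq_len(reps), function(r) {
    a <- rnorm(12); b <- rnorm(12, mean = 1.5)
    t.test(a, b)$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(power_pkg - power_oracle), 0.03)
})

test_that("three identical groups give a non-significant omnibus and adjusted p = 1", {
  vals <- list(control = as.numeric(1:15), PAE_saline = as.numeric(1:15),
               PAE_NBOH = as.numeric(1:15))
  r <- compare_all_groups(vals, stats_config())
  expect_gt(r$omnibus$p_value, 0.95)
  expect_true(all(r$pairwise$p_adjusted > 0.99))
  expect_false(any(r$pairwise$significant))
})

test_that("a 2-SD shifted group is flagged in exactly its two contrasts", {
  set.seed(7)
  vals <- list(control = rnorm(20), PAE_saline = rnorm(20),
               PAE_NBOH = rnorm(20, mean = 2))
  r <- compare_all_groups(vals, stats_config())
  expect_lt(r$omnibus$p_value, 0.05)
  sig <- r$pairwise[r$pairwise$significant, ]
  expect_equal(nrow(sig), 2L)
  expect_true(all(sig$group_a == "PAE_NBOH" | sig$group_b == "PAE_NBOH"))
})

test_that("adjusted p-values never fall below raw p-values", {
  set.seed(11)
  for (i in 1:20) {
    vals <- list(control = rnorm(10), PAE_saline = rnorm(10),
                 PAE_NBOH = rnorm(10, mean = runif(1, 0, 1)))
    for (corr in c("holm", "dunn_kw", "none")) {
      r <- compare_all_groups(vals, stats_config(correction = corr))
      expect_true(all(r$pairwise$p_adjusted >= r$pairwise$p_value - 1e-12))
    }
  }
})

test_that("a missing study arm is an error", {
  expect_error(compare_all_groups(list(control = rnorm(5),
                                       PAE_saline = rnorm(5)),
                                  stats_config()),
               "missing study arm")
})

test_that("Kruskal-Wallis and Dunn contrasts reproduce independently computed values", {
  # frozen from an independent Python evaluation (scipy.stats.kruskal and
  # the rank-contrast arithmetic; Mann-Whitney from pingouin)
  vals <- list(
    control = c(3.1, 4.5, 2.2, 5.0, 3.3, 4.1, 2.8),
    PAE_saline = c(5.5, 6.1, 4.9, 7.2, 5.8, 6.6),
    PAE_NBOH = c(2.0, 1.5, 3.0, 2.6, 1.1, 2.4, 3.0))
  r <- compare_all_groups(vals, stats_config(correction = "dunn_kw"))
  expect_equal(r$omnibus$statistic, 14.393134831058, tolerance = 1e-10)
  expect_equal(r$omnibus$p_value, 0.000749152930640, tolerance = 1e-9)
  z <- r$pairwise$statistic
  expect_equal(z[1], -2.14202580, tolerance = 1e-7)   # control vs saline
  expect_equal(z[2], 1.71731074, tolerance = 1e-7)    # control vs NBOH
  expect_equal(z[3], 3.79196459, tolerance = 1e-7)    # saline vs NBOH
  expect_equal(r$pairwise$p_value,
               c(0.032191406, 0.085922410, 0.000149460), tolerance = 1e-6)

  rh <- compare_all_groups(vals, stats_config(policy = "nonparametric",
                                              correction = "holm"))
  expect_equal(rh$pairwise$p_value, c(0.002331, 0.021308, 0.003361),
               tolerance = 1e-3)
})

test_that("the f-I permutation test is symmetric, seeded, and null-calibrated on duplicates", {
  set.seed(21)
  a <- matrix(rnorm(10 * 9), 10)
  colnames(a) <- as.character(seq(0, 400, 50))
  curves <- list(g1 = a, g2 = a)   # identical groups (duplicated cells)
  cfg <- stats_config(permutations = 1000, seed = 5)
  expect_equal(compare_fi_curves(curves, c("g1", "g2"), cfg)$p_value, 1)

  b <- a + 0.5
  colnames(b) <- colnames(a)
  curves2 <- list(g1 = a, g2 = b[1:7, ])
  p_ab <- compare_fi_curves(curves2, c("g1", "g2"), cfg)$p_value
  p_ba <- compare_fi_curves(curves2, c("g2", "g1"), cfg)$p_value
  expect_identical(p_ab, p_ba)

  # doubling the permutations moves p by less than 2 Monte-Carlo SEs
  cfg2 <- stats_config(permutations = 2000, seed = 5)
  p2 <- compare_fi_curves(curves2, c("g1", "g2"), cfg2)$p_value
  se <- sqrt(p_ab * (1 - p_ab) / 1000) + sqrt(p2 * (1 - p2) / 2000)
  expect_lt(abs(p2 - p_ab), max(2 * se, 0.01))

  bad <- list(g1 = a, g2 = a[, 1:5])
  expect_error(compare_fi_curves(bad, c("g1", "g2"), cfg), "mismatched")
})

test_that("a detectable gain deficit is significant in the permutation test", {
  set.seed(31)
  currents <- seq(0, 400, 50)
  mk <- function(n, gain) {
    m <- t(vapply(seq_len(n), function(i) {
      pmax(0, gain * runif(1, 0.9, 1.1) * (currents - 120)) + rnorm(9, sd = 1)
    }, numeric(9)))
    colnames(m) <- as.character(currents)
    m
  }
  curves <- list(control = mk(15, 0.2), PAE_saline = mk(15, 0.14))
  r <- compare_fi_curves(curves, c("control", "PAE_saline"),
                         stats_config(permutations = 5000, seed = 9))
  expect_true(r$significant)
})

test_that("the summary table covers QC-passed cells with correct n and SEM", {
  set.seed(41)
  features <- data.frame(
    cell_id = sprintf("c%02d", 1:18),
    group_label = rep(c("control", "PAE_saline", "PAE_NBOH"), each = 6),
    feat_x = rnorm(18), feat_y = rnorm(18))
  qc <- data.frame(cell_id = features$cell_id,
                   passed = rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 3))
  out <- build_summary_table(features, qc, c("feat_x", "feat_y"),
                             stats_config())
  expect_equal(nrow(out$table), 6L)          # 2 features x 3 contrasts
  expect_true(all(out$table$n_a == 5 & out$table$n_b == 5))
  # SEM recomputed independently
  row1 <- out$table[out$table$feature == "feat_x" &
                      out$table$group_a == "control" &
                      out$table$group_b == "PAE_NBOH", ]
  keep <- features$cell_id %in% qc$cell_id[qc$passed]
  x <- features$feat_x[keep & features$group_label == "control"]
  expect_equal(row1$mean_a, mean(x))
  expect_equal(row1$sem_a, sd(x) / sqrt(length(x)))

  # excluded cells appear in no group mean
  x_all <- features$feat_x[features$group_label == "control"]
  expect_false(isTRUE(all.equal(row1$mean_a, mean(x_all))))

  expect_error(build_summary_table(features, qc[-1, ], "feat_x",
                                   stats_config()),
               "absent from qc")
})
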
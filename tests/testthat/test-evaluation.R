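test_that("precision-recall handles perfect and degenerate classifiers", {
  truth <- c(rep(TRUE, 20), rep(FALSE, 80))
  perfect <- as.numeric(truth)            # P in {0, 1}
  pr <- precision_recall_curve(perfect, truth, "probability")
  expect_true(all(pr$precision == 1))
  expect_true(all(pr$recall == 1))

  all_in <- rep(1, 100)                   # flags everything at every cutoff
  pr2 <- precision_recall_curve(all_in, truth, "probability")
  expect_true(all(pr2$precision == 0.2))  # prevalence
  expect_true(all(pr2$recall == 1))

  # no positives anywhere: precision missing, not zero
  none <- rep(0, 100)
  pr3 <- precision_recall_curve(none, truth, "probability")
  expect_true(all(is.na(pr3$precision)))
  expect_true(all(pr3$recall == 0))
  expect_error(precision_recall_curve(none, rep(FALSE, 100), "probability"),
               "ischemic")
})

test_that("confusion counts are exhaustive and match direct counting", {
  set.seed(12)
  n <- 500
  vals <- runif(n, 0, 20)
  truth <- runif(n) < 0.3
  pr <- precision_recall_curve(vals, truth, "cbf", grid = c(5, 10, 15))
  expect_true(all(pr$tp + pr$fp + pr$fn + pr$tn == n))
  # direct count at one cutoff
  flag <- vals < 10
  expect_equal(pr$tp[pr$cutoff == 10], sum(flag & truth))
  expect_equal(pr$precision[pr$cutoff == 10],
               sum(flag & truth) / sum(flag))

  # 3x3 toy: 2 true positives, 1 false positive
  toy_vals <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1)
  toy_truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  toy <- precision_recall_curve(toy_vals, toy_truth, "probability",
                                grid = 0.5)
  expect_equal(toy$precision, 2 / 3)
  expect_equal(toy$recall, 2 / 3)
})

test_that("volume difference statistics use interpolated quartiles", {
  est <- tibble::tibble(case_id = c("a", "b", "c"), method = "threshold",
                        volume_ml = c(0, 10, 30))
  tru <- tibble::tibble(case_id = c("a", "b", "c"),
                        true_volume_ml = c(10, 10, 20))
  vds <- volume_difference_stats(est, tru)
  # differences -10, 0, 10
  expect_equal(vds$median, 0)
  expect_equal(vds$q1, -5)
  expect_equal(vds$q3, 5)
  expect_equal(vds$iqr, 10)
  expect_equal(vds$mean, 0)

  single <- volume_difference_stats(est[1, ], tru)
  expect_equal(single$median, -10)
  expect_equal(single$iqr, 0)

  exact <- volume_difference_stats(
    tibble::tibble(case_id = c("a", "b"), method = "probabilistic",
                   volume_ml = c(10, 10)),
    tibble::tibble(case_id = c("a", "b"), true_volume_ml = c(10, 10)))
  expect_equal(exact$median, 0); expect_equal(exact$iqr, 0)

  expect_error(volume_difference_stats(
    tibble::tibble(case_id = "zz", method = "threshold", volume_ml = 1), tru),
    "zz")
})

test_that("the paired t-test matches the closed form and its symmetries", {
  res <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(res$t_statistic, 3), 3.464)
  expect_equal(res$df, 2L)
  expect_equal(res$p_two_tailed, 0.0742, tolerance = 1e-3)
  expect_false(res$significant)

  same <- paired_t_test(c(1, 2), c(1, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_tailed, 1)

  shifted <- paired_t_test(c(2, 3), c(1, 2))  # constant nonzero difference
  expect_equal(shifted$p_two_tailed, 0)
  expect_true(shifted$significant)

  a <- rnorm(10); b <- rnorm(10)
  fwd <- paired_t_test(a, b); rev <- paired_t_test(b, a)
  expect_equal(rev$t_statistic, -fwd$t_statistic)
  expect_equal(rev$p_two_tailed, fwd$p_two_tailed)
})

test_that("the paired t-test agrees with the closed form on random samples", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n, sd = runif(1, 0.5, 3))
    b <- rnorm(n, sd = runif(1, 0.5, 3))
    d <- a - b
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    res <- paired_t_test(a, b)
    expect_equal(res$t_statistic, t_ref, tolerance = 1e-10)
    expect_equal(res$p_two_tailed, p_ref, tolerance = 1e-10)
    expect_equal(res$df, n - 1L)
  }
})

small_cohort <- function(n_rec = 3, n_occ = 3, seed = 31) {
  dist <- cohort_distribution(grid_shape = c(32, 32, 8),
                              voxel_spacing = c(4, 4, 5),
                              core_radius_range = c(5, 7),
                              penumbra_margin_range = c(4, 6))
  generate_cohort(n_rec, n_occ, dist, seed = seed)
}

test_that("the experiment report keeps the books straight", {
  co <- small_cohort()
  res <- suppressWarnings(run_experiment(co))
  # one REC test case: exactly two volume rows for it
  rec_test <- co$case_id[co$scenario == "REC" & co$split == "test"]
  rows <- dplyr::filter(res$volumes, case_id == rec_test)
  expect_equal(sort(rows$method), c("probabilistic", "threshold"))
  expect_equal(nrow(res$volumes), 2 * sum(co$split == "test"))
  expect_true(all(c("REC", "OCC") %in% res$pr_curves$scenario))
  expect_s3_class(res$rules$REC, "threshold_rule")
  expect_s3_class(res$models$OCC, "logistic_model")

  # determinism: a rerun reproduces the tables exactly
  res2 <- suppressWarnings(run_experiment(co))
  expect_identical(res$volumes, res2$volumes)
  expect_identical(res$pr_curves, res2$pr_curves)
  expect_identical(res$stats, res2$stats)

  leaky <- co
  leaky$split[leaky$split == "test"] <- "train"
  leaky2 <- dplyr::bind_rows(co, dplyr::mutate(co[1, ], split = "test"))
  expect_error(run_experiment(leaky2), "leak|duplicate")
})

test_that("probability dominance fractions are computed against matched recall", {
  pr <- dplyr::bind_rows(
    tibble::tibble(source = "probability", cutoff = c(0.8, 0.5, 0.2),
                   precision = c(0.9, 0.8, 0.6), recall = c(0.2, 0.5, 0.9)),
    tibble::tibble(source = "cbf", cutoff = c(5, 10, 15),
                   precision = c(0.85, 0.5, 0.5), recall = c(0.2, 0.5, 0.9))
  )
  frac <- pr_dominance_fraction(pr, "cbf")
  expect_equal(frac, 1)    # probability curve at/above at every matched recall
  pr2 <- pr
  pr2$precision[pr2$source == "cbf"] <- c(0.95, 0.9, 0.7)
  expect_equal(pr_dominance_fraction(pr2, "cbf"), 0)
})
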
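make_maps <- function(cbf, mask = NULL, spacing = c(1, 1, 1)) {
  d <- dim(cbf)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  perfusion_maps(cbf, cbf * 0 + 2, cbf * 0 + 6, cbf * 0 + 7, mask, spacing)
}

test_that("the voxel table is restricted to infarcted slices of the ischemic hemisphere", {
  d <- c(4, 4, 6)
  cbf <- array(seq_len(prod(d)), dim = d)
  maps <- make_maps(cbf)
  hemisphere <- array(2L, dim = d); hemisphere[1:2, , ] <- 1L
  infarct <- array(FALSE, dim = d)
  infarct[1, 1, 3:4] <- TRUE  # left hemisphere, slices 3-4 only

  tab <- assemble_voxel_table(maps, infarct, hemisphere, case_id = "x")
  # only left-hemisphere voxels of slices 3 and 4
  expect_equal(nrow(tab), 2 * 4 * 2)
  slice_of <- function(v) (match(v, cbf) - 1) %/% (d[1] * d[2]) + 1
  expect_true(all(slice_of(tab$cbf) %in% 3:4))
  expect_equal(sum(tab$label == "ischemic"), 2)
  # contralateral voxels never appear
  right_vals <- cbf[3:4, , ]
  expect_false(any(tab$cbf %in% right_vals))
  expect_error(assemble_voxel_table(maps, array(FALSE, d), hemisphere), "empty")
})

test_that("1.5 IQR outlier rows are dropped on any parameter", {
  tab <- tibble::tibble(case_id = "o", cbf = c(10, 11, 12, 13, 100),
                        cbv = 2, mtt = 6, ttp = 7,
                        label = c("ischemic", "ischemic", "healthy", "healthy", "healthy"))
  out <- remove_outliers(tab)
  # Q3 + 1.5 IQR on {10,11,12,13,100} = 13 + 1.5*2 = 16: the 100 goes
  expect_equal(out$cbf, c(10, 11, 12, 13))
  expect_equal(attr(out, "n_removed"), 1L)

  # identical values: IQR 0, nothing strictly outside the fences
  same <- tibble::tibble(case_id = "o", cbf = rep(5, 6), cbv = rep(1, 6),
                         mtt = rep(8, 6), ttp = rep(9, 6),
                         label = rep(c("ischemic", "healthy"), 3))
  expect_equal(nrow(remove_outliers(same)), 6)

  # outlying in TTP only still drops the row
  tab2 <- tab
  tab2$cbf <- c(10, 11, 12, 13, 12)
  tab2$ttp <- c(7, 7.1, 7.2, 6.9, 50)
  expect_equal(nrow(remove_outliers(tab2)), 4)
})

test_that("ROC handles perfect, random and toy tables", {
  perf <- separated_table()
  roc <- roc_curve(perf, "cbf")
  expect_equal(attr(roc, "auc"), 1.0)
  expect_error(roc_curve(dplyr::filter(perf, label == "healthy"), "cbf"),
               "both classes")

  set.seed(42)
  n <- 4000
  rand <- tibble::tibble(case_id = "r", cbf = runif(n), cbv = runif(n),
                         mtt = runif(n), ttp = runif(n),
                         label = sample(c("ischemic", "healthy"), n, TRUE))
  expect_equal(attr(roc_curve(rand, "cbf"), "auc"), 0.5, tolerance = 0.05)

  toy <- tibble::tibble(case_id = "t", cbf = c(5, 8, 7, 20), cbv = 1,
                        mtt = 1, ttp = 1,
                        label = c("ischemic", "ischemic", "healthy", "healthy"))
  expect_equal(attr(roc_curve(toy, "cbf"), "auc"), 0.75)
})

test_that("trapezoidal AUC equals pairwise concordance on random tables", {
  for (s in 1:25) {
    tab <- random_table(sample(6:60, 1), seed = 100 + s)
    for (p in c("cbf", "mtt")) {
      roc <- roc_curve(tab, p)
      expect_equal(attr(roc, "auc"),
                   oracle_auc(tab[[p]], tab$label, attr(roc, "direction")),
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold selection maximizes AUC then Youden with the documented tie rules", {
  perf <- separated_table()
  rule <- select_threshold(perf)
  # CBF separates perfectly and wins the AUC tie-break order
  expect_equal(rule$parameter, "cbf")
  expect_equal(rule$cutoff, 9.0)
  expect_equal(rule$youden_j, 1.0)
  expect_equal(rule$direction, "below")

  for (s in 1:20) {
    tab <- random_table(sample(8:50, 1), seed = 500 + s)
    rule <- select_threshold(tab)
    roc <- roc_curve(tab, rule$parameter)
    oracle <- oracle_youden(tab[[rule$parameter]], tab$label,
                            attr(roc, "direction"))
    expect_equal(rule$cutoff, oracle$cutoff)
    expect_equal(rule$youden_j, oracle$j, tolerance = 1e-12)
    # no other parameter has a larger AUC
    aucs <- vapply(c("cbf", "cbv", "mtt", "ttp"),
                   function(p) attr(roc_curve(tab, p), "auc"), numeric(1))
    expect_gte(attr(roc, "auc") + 1e-12, max(aucs))
  }
})

test_that("logistic fitting recovers generating coefficients and their symmetries", {
  model <- reference_model("bSVD", "REC")
  tab <- simulate_model_voxels(model, 2e4, seed = 77)
  fit <- fit_logistic(tab, "REC")
  for (term in names(model$coefficients)) {
    est <- fit$coefficients[[term]]
    truth <- model$coefficients[[term]]
    expect_true(abs(est - truth) <= pmax(0.12 * abs(truth), 0.06),
                label = sprintf("coefficient %s: %.3f vs %.3f", term, est, truth))
  }

  # flipping labels negates every coefficient
  flipped <- tab
  flipped$label <- ifelse(tab$label == "ischemic", "healthy", "ischemic")
  fit_f <- fit_logistic(flipped, "REC")
  expect_equal(fit_f$coefficients, -fit$coefficients, tolerance = 1e-6)

  expect_error(fit_logistic(dplyr::filter(tab, label == "healthy"), "REC"),
               "class")
})

test_that("perfect separation is rejected with a diagnostic", {
  sep <- separated_table()
  sep <- dplyr::bind_rows(sep, sep, sep, sep)  # 12 rows per class pattern
  expect_error(fit_logistic(sep, "REC"), "separation|converge")
})

test_that("tidy and glance expose rules and models as tibbles", {
  rule <- threshold_rule("cbf", "below", 9, auc = 0.74, youden_j = 0.38)
  td <- tidy(rule)
  expect_equal(td$cutoff, 9)
  expect_equal(td$units, "mL/100g/min")

  model <- reference_model("bSVD", "OCC")
  tm <- tidy(model)
  expect_equal(tm$term, c("int", "cbf", "cbv", "mtt", "ttp"))
  expect_equal(tm$estimate[1], 3.09)
})
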
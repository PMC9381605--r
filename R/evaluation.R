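#' Evaluation cutoff grids for precision-recall curves
#'
#' The printed evaluation grids: for in-house processing, CBF 1-20 in steps
#' of 1 mL/100g/min, CBV 0.1-2.0 in steps of 0.1 mL/100g, MTT 25-5 in steps
#' of 1 s, TTP 15-5 in steps of 0.5 s; for the commercial (ISP) maps, CBF
#' 1-40 in steps of 2 and CBV 0.1-4.0 in steps of 0.2 with TTP in steps of
#' 1 s; probability 95% down to 5% in steps of 5% in both.
#'
#' @param style `"inhouse"` or `"isp"`.
#' @return Named list of numeric cutoff vectors (`cbf`, `cbv`, `mtt`,
#'   `ttp`, `probability`).
#' @export
pr_grids <- function(style = c("inhouse", "isp")) {
  style <- match.arg(style)
  if (style == "inhouse") {
    list(cbf = seq(1, 20, by = 1), cbv = seq(0.1, 2.0, by = 0.1),
         mtt = seq(25, 5, by = -1), ttp = seq(15, 5, by = -0.5),
         probability = seq(0.95, 0.05, by = -0.05))
  } else {
    list(cbf = seq(1, 40, by = 2), cbv = seq(0.1, 4.0, by = 0.2),
         mtt = seq(25, 5, by = -1), ttp = seq(15, 5, by = -1),
         probability = seq(0.95, 0.05, by = -0.05))
  }
}

#' Precision-recall curve of a parameter or probability map
#'
#' Voxels are pooled inside the ischemic hemisphere (and parenchyma). At
#' each cutoff of the grid a voxel is classified ischemic by the
#' parameter's fixed direction (CBF/CBV strictly below, MTT/TTP strictly
#' above) or by probability at `P >= cutoff` (inclusive, so both grid ends
#' are attainable). Precision = TP/(TP+FP) — recorded as `NA` when nothing
#' is classified positive — and recall = TP/(TP+FN).
#'
#' @param values Numeric vector of pooled voxel values (parameter units or
#'   probability), already restricted to the evaluation region.
#' @param truth Logical vector of the same length: voxel truly ischemic.
#' @param source `"cbf"`, `"cbv"`, `"mtt"`, `"ttp"` or `"probability"`.
#' @param grid Numeric cutoffs; defaults to the in-house grid of `source`.
#' @param scenario Bookkeeping tag.
#' @return An object of class `ctp_pr`: tibble of `cutoff`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall` with attributes `source`,
#'   `scenario`.
#' @export
precision_recall_curve <- function(values, truth, source,
                                   grid = NULL,
                                   scenario = NA_character_) {
  source <- match.arg(source, c(.ctp_parameters, "probability"))
  if (length(values) != length(truth)) abort("`values` and `truth` lengths differ")
  if (!any(truth)) abort("no truly ischemic voxels in the evaluation region")
  grid <- grid %||% pr_grids("inhouse")[[source]]
  n <- length(values)
  rows <- lapply(grid, function(cut) {
    flag <- switch(source,
      probability = values >= cut,
      cbf = values < cut, cbv = values < cut,
      mtt = values > cut, ttp = values > cut)
    tp <- sum(flag & truth); fp <- sum(flag & !truth)
    fn <- sum(!flag & truth); tn <- n - tp - fp - fn
    tibble(cutoff = cut, tp = tp, fp = fp, fn = fn, tn = tn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = tp / (tp + fn))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ctp_pr", class(out)),
            source = source, scenario = scenario)
}

#' @export
print.ctp_pr <- function(x, ...) {
  cat(sprintf("<ctp_pr> %s [%s], %d cutoffs\n",
              attr(x, "source"), attr(x, "scenario"), nrow(x)))
  NextMethod()
}

#' Volume-difference distribution over a test group
#'
#' Differences are predicted minus ground-truth volume per case; the
#' summary reports the median, first and third quartile (linear
#' interpolation), interquartile range and mean.
#'
#' @param estimates Tibble of volume estimates with columns `case_id`,
#'   `method`, `volume_ml` (from [threshold_volume()] /
#'   [probabilistic_volume()] rows).
#' @param truths Tibble with columns `case_id`, `true_volume_ml`.
#' @return An object of class `volume_diff_stats`: tibble with one row per
#'   method (`method`, `n`, `median`, `q1`, `q3`, `iqr`, `mean`), with the
#'   per-case differences in attribute `differences`.
#' @export
volume_difference_stats <- function(estimates, truths) {
  if (!all(estimates$case_id %in% truths$case_id)) {
    missing <- setdiff(estimates$case_id, truths$case_id)
    abort(sprintf("no ground truth for case(s): %s",
                  paste(missing, collapse = ", ")))
  }
  joined <- dplyr::left_join(estimates, truths, by = "case_id")
  diffs <- dplyr::mutate(joined, difference = .data$volume_ml - .data$true_volume_ml)
  out <- diffs |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$difference),
      q1 = quantile(.data$difference, 0.25, names = FALSE, type = 7),
      q3 = quantile(.data$difference, 0.75, names = FALSE, type = 7),
      mean = mean(.data$difference),
      .groups = "drop"
    ) |>
    dplyr::mutate(iqr = .data$q3 - .data$q1) |>
    dplyr::select("method", "n", "median", "q1", "q3", "iqr", "mean")
  structure(out, class = c("volume_diff_stats", class(out)),
            differences = dplyr::select(diffs, "case_id", "method", "difference"))
}

#' Paired two-tailed t-test of two per-case difference series
#'
#' Standard paired Student t-test on `a - b` with `n - 1` degrees of
#' freedom, two-tailed p-value, significance at p < 0.05. Degenerate
#' inputs: identical series give a no-difference result (t = 0, p = 1);
#' zero-variance paired differences with non-zero mean give p = 0.
#'
#' @param a,b Numeric vectors of equal length (n >= 2), same case order.
#' @return A one-row tibble: `t_statistic`, `df`, `p_two_tailed`,
#'   `significant`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must pair one-to-one")
  n <- length(a)
  if (n < 2) abort("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(t_statistic = 0, df = n - 1L, p_two_tailed = 1,
                    significant = FALSE))
    }
    return(tibble(t_statistic = sign(mean(d)) * Inf, df = n - 1L,
                  p_two_tailed = 0, significant = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble(t_statistic = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
         p_two_tailed = ht$p.value, significant = ht$p.value < 0.05)
}

#' Run the full threshold-versus-probability comparison on a cohort
#'
#' Per scenario (REC: infarct core; OCC: total hypoperfused region):
#' assembles the pooled voxel training table from the training split
#' (parenchymal voxels, ischemic hemisphere, infarcted slices; 1.5 x IQR
#' outlier rows removed), trains the best-AUC/Youden threshold rule and the
#' four-parameter logistic model, then scores the test split: pooled
#' precision-recall curves per parameter and for the probability on the
#' printed grids, threshold-based (morphology-cleaned, ischemic hemisphere)
#' and probabilistic (hemisphere-difference) volumes per case, the
#' volume-difference distributions and the paired t-test between the two
#' methods' differences.
#'
#' @param cohort Manifest tibble from [generate_cohort()].
#' @param map_mode `"sampled"` or `"ctp"`, see [case_maps()].
#' @param grids PR cutoff grids, see [pr_grids()].
#' @param settings [deconv_settings()] used when `map_mode = "ctp"`.
#' @return An object of class `ctp_experiment`: list with `rules`,
#'   `models`, `pr_curves`, `volumes`, `stats`, `tests`.
#' @export
run_experiment <- function(cohort, map_mode = c("sampled", "ctp"),
                           grids = pr_grids("inhouse"),
                           settings = deconv_settings()) {
  map_mode <- match.arg(map_mode)
  if (anyDuplicated(cohort$case_id)) abort("duplicate case_id in cohort")
  leak <- intersect(cohort$case_id[cohort$split == "train"],
                    cohort$case_id[cohort$split == "test"])
  if (length(leak)) abort("training/test leakage: case present in both splits")

  rules <- list(); models <- list()
  pr_all <- list(); vol_all <- list(); stats_all <- list()
  tests_all <- list(); diff_all <- list()

  for (scen in intersect(c("REC", "OCC"), unique(cohort$scenario))) {
    train <- dplyr::filter(cohort, .data$scenario == scen, .data$split == "train")
    test <- dplyr::filter(cohort, .data$scenario == scen, .data$split == "test")
    if (nrow(train) == 0 || nrow(test) == 0) next

    train_tab <- purrr::map2(train$case, train$case_id, function(case, id) {
      maps <- case_maps(case, map_mode, settings)
      assemble_voxel_table(maps, case$infarct_mask, case$tissue$hemisphere,
                           side = case$tissue$lesion_side, case_id = id)
    }) |> dplyr::bind_rows() |> remove_outliers(by = "label")

    rule <- select_threshold(train_tab)
    model <- fit_logistic(train_tab, scen)
    rules[[scen]] <- rule
    models[[scen]] <- model

    pooled_vals <- list(cbf = c(), cbv = c(), mtt = c(), ttp = c(),
                        probability = c())
    pooled_truth <- c()
    vols <- list()

    for (r in seq_len(nrow(test))) {
      case <- test$case[[r]]
      maps <- case_maps(case, map_mode, settings)
      hemi <- case$tissue$hemisphere
      side <- case$tissue$lesion_side
      pmap <- predict_probability(maps, model)
      smap <- apply_threshold(maps, rule)

      in_hemi <- maps$mask & hemi == .hemi[[side]]
      idx <- which(in_hemi)
      for (p in .ctp_parameters) {
        pooled_vals[[p]] <- c(pooled_vals[[p]], maps[[p]][idx])
      }
      pooled_vals$probability <- c(pooled_vals$probability, pmap[idx])
      pooled_truth <- c(pooled_truth, case$infarct_mask[idx])

      smap_hemi <- structure(smap & in_hemi, class = "summary_map",
                             rule = rule, spacing = maps$spacing)
      vols[[length(vols) + 1]] <- dplyr::bind_rows(
        threshold_volume(smap_hemi, maps$spacing,
                         case_id = case$case_id, scenario = scen),
        probabilistic_volume(pmap, hemi, maps$spacing, lesion_side = side,
                             case_id = case$case_id, scenario = scen)
      )
    }

    prs <- purrr::imap(pooled_vals, function(v, src) {
      pr <- precision_recall_curve(v, pooled_truth, src,
                                   grid = grids[[src]], scenario = scen)
      dplyr::mutate(as_tibble(pr), source = src, scenario = scen)
    })
    pr_all[[scen]] <- dplyr::bind_rows(prs)

    vol_tab <- dplyr::bind_rows(vols)
    vol_all[[scen]] <- vol_tab
    truths <- dplyr::select(test, "case_id", "true_volume_ml")
    vds <- volume_difference_stats(vol_tab, truths)
    stats_all[[scen]] <- dplyr::mutate(as_tibble(vds), scenario = scen)

    dd <- attr(vds, "differences")
    diff_all[[scen]] <- dplyr::mutate(dd, scenario = scen)
    wide <- tidyr::pivot_wider(dd, names_from = "method",
                               values_from = "difference")
    test_row <- if (nrow(wide) >= 2) {
      paired_t_test(wide$threshold, wide$probabilistic)
    } else {
      tibble(t_statistic = NA_real_, df = NA_integer_,
             p_two_tailed = NA_real_, significant = NA)
    }
    tests_all[[scen]] <- dplyr::mutate(test_row, scenario = scen)
  }

  structure(
    list(rules = rules, models = models,
         pr_curves = dplyr::bind_rows(pr_all),
         volumes = dplyr::bind_rows(vol_all),
         differences = dplyr::bind_rows(diff_all),
         stats = dplyr::bind_rows(stats_all),
         tests = dplyr::bind_rows(tests_all)),
    class = "ctp_experiment"
  )
}

#' @export
print.ctp_experiment <- function(x, ...) {
  cat("<ctp_experiment>\n")
  for (scen in names(x$rules)) {
    cat(sprintf("  %s rule: ", scen)); print(x$rules[[scen]])
    cat(sprintf("  %s model: ", scen)); print(x$models[[scen]])
  }
  cat(sprintf("  %d volume estimates, %d PR rows\n",
              nrow(x$volumes), nrow(x$pr_curves)))
  invisible(x)
}

#' Fraction of matched recall points where the probability curve dominates
#'
#' For every grid point of a single-parameter precision-recall curve with
#' defined precision whose recall lies inside the recall range attained by
#' the probability curve, the probability curve's precision is linearly
#' interpolated at the same recall and compared. Returns the fraction of
#' such matched points at which the probability precision is at least as
#' high. Parameter grid points outside the probability curve's recall
#' range have no matched probability operating point and are excluded.
#'
#' @param pr_curves Long PR tibble from [run_experiment()] (one scenario).
#' @param source Parameter curve to compare against the probability curve.
#' @param tol Comparison slack on precision.
#' @return Fraction in \[0, 1\].
#' @export
pr_dominance_fraction <- function(pr_curves, source, tol = 1e-9) {
  pc <- dplyr::filter(pr_curves, .data$source == "probability",
                      !is.na(.data$precision))
  par <- dplyr::filter(pr_curves, .data$source == !!source,
                       !is.na(.data$precision))
  if (nrow(pc) < 2 || nrow(par) == 0) return(NA_real_)
  par <- dplyr::filter(par, .data$recall >= min(pc$recall),
                       .data$recall <= max(pc$recall))
  if (nrow(par) == 0) return(NA_real_)
  pc <- dplyr::arrange(pc, .data$recall)
  interp <- approx(pc$recall, pc$precision, xout = par$recall, ties = max)
  mean(interp$y >= par$precision - tol)
}
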
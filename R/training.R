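#' Assemble the voxel training table for one case
#'
#' Restricts the sample space the way the threshold and logistic model
#' training requires: only parenchymal voxels, only the ischemic (lesion-
#' bearing) hemisphere, and only axial slices on which the follow-up infarct
#' segmentation is non-empty. Each remaining voxel becomes one row labelled
#' `ischemic` (inside the infarct mask) or `healthy`.
#'
#' @param maps A [perfusion_maps] object.
#' @param infarct 3D logical follow-up infarct mask, co-registered with the
#'   maps.
#' @param hemisphere 3D integer hemisphere labels (1 left, 2 right).
#' @param side Ischemic side, `"left"`, `"right"` or `"auto"` (majority side
#'   of the infarct mask).
#' @param case_id Identifier recorded in the rows.
#' @return A tibble with columns `case_id`, `cbf`, `cbv`, `mtt`, `ttp`,
#'   `label`.
#' @export
assemble_voxel_table <- function(maps, infarct, hemisphere,
                                 side = "auto", case_id = "case") {
  if (!inherits(maps, "perfusion_maps")) abort("`maps` must be perfusion_maps")
  if (!identical(dim(infarct), dim(maps$cbf)) ||
      !identical(dim(hemisphere), dim(maps$cbf))) {
    abort("`infarct` and `hemisphere` must share the map grid")
  }
  if (!any(infarct)) abort("infarct mask is empty: no training slices")
  if (identical(side, "auto")) {
    side <- names(.hemi)[which.max(c(sum(infarct & hemisphere == .hemi[["left"]]),
                                     sum(infarct & hemisphere == .hemi[["right"]])))]
  }
  side <- match.arg(side, c("left", "right"))

  slice_has_infarct <- apply(infarct, 3, any)
  slice_ok <- array(rep(slice_has_infarct, each = prod(dim(infarct)[1:2])),
                    dim = dim(infarct))
  keep <- maps$mask & (hemisphere == .hemi[[side]]) & slice_ok
  idx <- which(keep)
  tibble(
    case_id = case_id,
    cbf = maps$cbf[idx], cbv = maps$cbv[idx],
    mtt = maps$mtt[idx], ttp = maps$ttp[idx],
    label = ifelse(infarct[idx], "ischemic", "healthy")
  )
}

#' Drop rows with an outlying perfusion value
#'
#' A row is removed when any of its four parameters lies more than 1.5 times
#' the interquartile range below the first quartile or above the third
#' quartile, with quartiles by linear interpolation. With `by = "table"`
#' the fences are computed per parameter over the whole (pooled) table;
#' with `by = "label"` they are computed within each outcome class, which
#' targets exactly the high-leverage voxels (normally perfused voxels
#' labelled ischemic, hypoperfused voxels labelled healthy) without
#' eroding a rare ischemic class whose typical values sit far from the
#' healthy majority.
#'
#' @param table A voxel tibble from [assemble_voxel_table()] (possibly
#'   pooled over cases).
#' @param by Fence scope: `"table"` (pooled) or `"label"` (per class).
#' @return The filtered tibble, with attribute `n_removed`.
#' @export
remove_outliers <- function(table, by = c("table", "label")) {
  by <- match.arg(by)
  if (nrow(table) < 4) abort("need at least 4 rows to place outlier fences")
  groups <- if (by == "table") list(seq_len(nrow(table)))
            else split(seq_len(nrow(table)), table$label)
  keep <- rep(TRUE, nrow(table))
  for (idx in groups) {
    for (p in .ctp_parameters) {
      v <- table[[p]][idx]
      q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      keep[idx] <- keep[idx] & v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr
    }
  }
  out <- table[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

roc_direction <- function(parameter) {
  # ischemia shows as low flow/volume but long transit/delay
  if (parameter %in% c("cbf", "cbv")) "below" else "above"
}

#' ROC curve of one perfusion parameter
#'
#' Candidate cutoffs are midpoints between consecutive sorted unique values
#' (or a fixed grid), the classification direction is fixed a priori per
#' parameter (`ischemic` when CBF/CBV fall below the cutoff, when MTT/TTP
#' rise above it), and the AUC is the trapezoidal area over
#' (1 - specificity, sensitivity) including the degenerate end points.
#'
#' @param table Voxel tibble with both labels present.
#' @param parameter One of `"cbf"`, `"cbv"`, `"mtt"`, `"ttp"`.
#' @param cutoffs `"midpoints"` or a numeric vector of candidate cutoffs.
#' @return An object of class `ctp_roc`: a tibble of `cutoff`,
#'   `sensitivity`, `specificity` with attributes `parameter`, `direction`,
#'   `auc`.
#' @export
roc_curve <- function(table, parameter, cutoffs = "midpoints") {
  parameter <- match.arg(parameter, .ctp_parameters)
  v <- table[[parameter]]
  if (any(!is.finite(v))) abort("non-finite parameter values in the table")
  pos <- table$label == "ischemic"
  if (!any(pos) || all(pos)) abort("both classes must be present for a ROC curve")
  direction <- roc_direction(parameter)

  if (identical(cutoffs, "midpoints")) {
    u <- sort(unique(v))
    cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  } else {
    cand <- sort(as.numeric(cutoffs))
  }

  n_pos <- sum(pos); n_neg <- sum(!pos)
  pos_sorted <- sort(v[pos]); neg_sorted <- sort(v[!pos])
  if (direction == "below") {
    # flagged iff value < cutoff (strict)
    pos_flag <- findInterval(cand, pos_sorted, left.open = TRUE)
    neg_flag <- findInterval(cand, neg_sorted, left.open = TRUE)
  } else {
    # flagged iff value > cutoff (strict)
    pos_flag <- n_pos - findInterval(cand, pos_sorted)
    neg_flag <- n_neg - findInterval(cand, neg_sorted)
  }
  sens <- pos_flag / n_pos
  spec <- 1 - neg_flag / n_neg

  curve <- tibble(cutoff = cand, sensitivity = sens, specificity = spec)
  # reconstruct the monotone ROC path: joint ordering by (fpr, tpr)
  ord <- order(1 - spec, sens)
  fpr <- c(0, (1 - spec)[ord], 1)
  tpr <- c(0, sens[ord], 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)

  structure(curve, class = c("ctp_roc", class(curve)),
            parameter = parameter, direction = direction, auc = auc)
}

#' @export
print.ctp_roc <- function(x, ...) {
  cat(sprintf("<ctp_roc> %s (%s), AUC %.3f, %d candidate cutoffs\n",
              attr(x, "parameter"), attr(x, "direction"), attr(x, "auc"), nrow(x)))
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `ctp_roc` object.
#' @param ... Unused.
#' @method glance ctp_roc
#' @export
glance.ctp_roc <- function(x, ...) {
  tibble(parameter = attr(x, "parameter"), direction = attr(x, "direction"),
         auc = attr(x, "auc"), n_cutoffs = nrow(x))
}

#' Pick the best-AUC parameter and its Youden-optimal cutoff
#'
#' Computes the ROC curve of each of the four perfusion parameters, keeps
#' the parameter with the largest AUC (ties broken in the order CBF, CBV,
#' MTT, TTP), and sets the cutoff by maximizing the Youden index
#' `J = sensitivity + specificity - 1`. Ties in J break toward the cutoff
#' that classifies fewer voxels as ischemic (the clinically conservative
#' choice).
#'
#' @param table Pooled voxel training tibble.
#' @param cutoffs Passed to [roc_curve()].
#' @return An object of class `threshold_rule` with fields `parameter`,
#'   `direction`, `cutoff`, `auc`, `youden_j`, `units`.
#' @export
select_threshold <- function(table, cutoffs = "midpoints") {
  rocs <- lapply(.ctp_parameters, function(p) roc_curve(table, p, cutoffs))
  names(rocs) <- .ctp_parameters
  aucs <- vapply(rocs, attr, numeric(1), "auc")
  best <- .ctp_parameters[which.max(aucs)]  # which.max keeps first on ties
  roc <- rocs[[best]]
  j <- roc$sensitivity + roc$specificity - 1
  jmax <- max(j)
  tied <- which(j >= jmax - 1e-12)
  cand <- roc$cutoff[tied]
  cutoff <- if (attr(roc, "direction") == "below") min(cand) else max(cand)
  threshold_rule(best, attr(roc, "direction"), cutoff,
                 auc = attr(roc, "auc"), youden_j = jmax)
}

#' Construct a single-parameter threshold rule
#'
#' @param parameter One of `"cbf"`, `"cbv"`, `"mtt"`, `"ttp"`.
#' @param direction `"below"` or `"above"` (strict inequality).
#' @param cutoff Cutoff in the parameter's canonical units.
#' @param auc,youden_j Optional training provenance.
#' @param units Units string; defaults to the canonical units of the
#'   parameter.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(parameter, direction, cutoff,
                           auc = NA_real_, youden_j = NA_real_,
                           units = NULL) {
  parameter <- match.arg(parameter, .ctp_parameters)
  direction <- match.arg(direction, c("below", "above"))
  stopifnot_scalar_number(cutoff, "cutoff")
  structure(
    list(parameter = parameter, direction = direction, cutoff = cutoff,
         auc = auc, youden_j = youden_j,
         units = units %||% .ctp_units[[parameter]]),
    class = "threshold_rule"
  )
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s %s %.3g %s (AUC %.3f, J %.3f)\n",
              toupper(x$parameter), if (x$direction == "below") "<" else ">",
              x$cutoff, x$units, x$auc, x$youden_j))
  invisible(x)
}

#' @rdname threshold_rule
#' @param x A `threshold_rule`.
#' @param ... Unused.
#' @method tidy threshold_rule
#' @export
tidy.threshold_rule <- function(x, ...) {
  tibble(parameter = x$parameter, direction = x$direction, cutoff = x$cutoff,
         auc = x$auc, youden_j = x$youden_j, units = x$units)
}

#' Fit the four-parameter logistic probability model
#'
#' Maximum-likelihood logistic regression of tissue outcome (`ischemic`
#' against `healthy`) on CBF, CBV, MTT and TTP. Coefficients are reported
#' in the convention `P = 1 / (1 + exp(c_int + c_cbf*CBF + c_cbv*CBV +
#' c_mtt*MTT + c_ttp*TTP))`, i.e. the negated standard GLM coefficients, so
#' that reduced perfusion (low CBF/CBV) carries positive weights.
#'
#' @param table Voxel tibble with both labels present, at least 5 rows per
#'   class.
#' @param scenario `"REC"` (core model) or `"OCC"` (hypoperfused-region
#'   model).
#' @return An object of class `logistic_model` with the named coefficient
#'   vector `c(int, cbf, cbv, mtt, ttp)`.
#' @export
fit_logistic <- function(table, scenario = c("REC", "OCC")) {
  scenario <- match.arg(scenario)
  pos <- table$label == "ischemic"
  if (sum(pos) < 5 || sum(!pos) < 5) {
    abort("need at least 5 rows of each class to fit the logistic model")
  }
  dat <- data.frame(y = as.integer(pos),
                    cbf = table$cbf, cbv = table$cbv,
                    mtt = table$mtt, ttp = table$ttp)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ cbf + cbv + mtt + ttp, family = binomial(), data = dat,
        control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) abort("logistic regression did not converge")
  if (sep_warned && fit$deviance < 1e-6) {
    abort("perfect separation: the classes are linearly separable, coefficients diverge")
  }
  beta <- coef(fit)
  if (any(is.na(beta))) {
    abort("separation or collinear predictors: coefficients are not identifiable")
  }
  co <- -as.numeric(beta)  # printed sign convention: P = 1/(1 + e^{+z})
  names(co) <- c("int", .ctp_parameters)
  logistic_model(co, scenario, fit = fit)
}

#' Construct a logistic probability model from coefficients
#'
#' @param coefficients Named numeric vector `c(int, cbf, cbv, mtt, ttp)` in
#'   the sign convention `P = 1/(1 + exp(int + cbf*CBF + ...))`.
#' @param scenario `"REC"` or `"OCC"`.
#' @param fit Optional underlying `glm` fit.
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(coefficients, scenario = c("REC", "OCC"), fit = NULL) {
  scenario <- match.arg(scenario)
  need <- c("int", .ctp_parameters)
  if (!all(need %in% names(coefficients))) {
    abort("`coefficients` must be named int, cbf, cbv, mtt, ttp")
  }
  co <- as.numeric(coefficients[need])
  if (any(!is.finite(co))) abort("coefficients must be finite")
  names(co) <- need
  structure(list(coefficients = co, scenario = scenario, fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<logistic_model> [%s] P = 1/(1 + exp(%.3g %+.3g CBF %+.3g CBV %+.3g MTT %+.3g TTP))\n",
    x$scenario, co["int"], co["cbf"], co["cbv"], co["mtt"], co["ttp"]))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `logistic_model`.
#' @param ... Unused.
#' @method tidy logistic_model
#' @export
tidy.logistic_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = as.numeric(x$coefficients),
         scenario = x$scenario)
}

#' @rdname fit_logistic
#' @method glance logistic_model
#' @export
glance.logistic_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(scenario = x$scenario, nobs = NA_integer_,
                  deviance = NA_real_, aic = NA_real_, converged = NA))
  }
  tibble(scenario = x$scenario, nobs = length(x$fit$y),
         deviance = x$fit$deviance, aic = x$fit$aic,
         converged = x$fit$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
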
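#' Threshold a perfusion parameter map into a binary summary map
#'
#' A voxel is flagged ischemic when its parameter value falls strictly below
#' (`direction = "below"`) or strictly above (`"above"`) the cutoff, within
#' the parenchyma mask only.
#'
#' @param maps A [perfusion_maps] object.
#' @param rule A [threshold_rule()].
#' @return An object of class `summary_map`: 3D logical array with the rule
#'   and spacing attached.
#' @export
apply_threshold <- function(maps, rule) {
  if (!inherits(maps, "perfusion_maps")) abort("`maps` must be perfusion_maps")
  if (!inherits(rule, "threshold_rule")) abort("`rule` must be a threshold_rule")
  canonical <- maps$units[[rule$parameter]]
  if (!identical(rule$units, canonical)) {
    abort(sprintf("rule units '%s' do not match map units '%s' for %s",
                  rule$units, canonical, toupper(rule$parameter)))
  }
  v <- maps[[rule$parameter]]
  flag <- if (rule$direction == "below") v < rule$cutoff else v > rule$cutoff
  flag <- flag & maps$mask
  structure(flag, class = "summary_map", rule = rule, spacing = maps$spacing)
}

#' Evaluate a logistic probability map
#'
#' Per-voxel probability of belonging to the ischemic core (REC model) or
#' the total hypoperfused region (OCC model):
#' `P = 1/(1 + exp(c_int + c_cbf*CBF + c_cbv*CBV + c_mtt*MTT + c_ttp*TTP))`,
#' evaluated in overflow-safe form; 0 outside the parenchyma.
#'
#' @param maps A [perfusion_maps] object with all four parameters finite
#'   inside the parenchyma.
#' @param model A [logistic_model()].
#' @return An object of class `probability_map`: 3D numeric array in
#'   \[0, 1\] with the model and spacing attached.
#' @export
predict_probability <- function(maps, model) {
  if (!inherits(maps, "perfusion_maps")) abort("`maps` must be perfusion_maps")
  if (!inherits(model, "logistic_model")) abort("`model` must be a logistic_model")
  idx <- which(maps$mask)
  for (p in .ctp_parameters) {
    bad <- !is.finite(maps[[p]][idx])
    if (any(bad)) {
      v <- arrayInd(idx[which(bad)[1]], dim(maps$mask))
      abort(sprintf("non-finite %s at voxel (%d, %d, %d) inside the parenchyma",
                    toupper(p), v[1], v[2], v[3]))
    }
  }
  co <- model$coefficients
  z <- co[["int"]] +
    co[["cbf"]] * maps$cbf[idx] + co[["cbv"]] * maps$cbv[idx] +
    co[["mtt"]] * maps$mtt[idx] + co[["ttp"]] * maps$ttp[idx]
  p <- plogis(-z)  # stable: no overflow for |z| large
  out <- array(0, dim = dim(maps$mask))
  out[idx] <- p
  structure(out, class = "probability_map", model = model, spacing = maps$spacing)
}

#' Published reference logistic coefficients
#'
#' Reference coefficients of the voxelwise logistic models for the ischemic
#' core (REC) and total hypoperfused region (OCC), per CTP processing
#' method (ISP, bSVD, NLR), in the sign convention of
#' [predict_probability()]. Units: `cbf` in (mL/100g/min)^-1, `cbv` in
#' (mL/100g)^-1, `mtt` and `ttp` in s^-1. Shipped as fixtures for
#' regression testing and for applying the published models to new maps.
#'
#' @return A tibble with columns `method`, `scenario`, `int`, `cbf`, `cbv`,
#'   `mtt`, `ttp`.
#' @export
reference_coefficients <- function() {
  tibble::tribble(
    ~method, ~scenario, ~int,  ~cbf,  ~cbv,  ~mtt,   ~ttp,
    "ISP",   "REC",      2.31,  0.06,  0.26, -0.09,  -0.08,
    "ISP",   "OCC",      3.98,  0.04,  0.12, -0.21,  -0.17,
    "bSVD",  "REC",      2.58,  0.13,  0.57, -0.14,  -0.32,
    "bSVD",  "OCC",      3.09,  0.08,  0.30, -0.16,  -0.38,
    "NLR",   "REC",      3.45,  0.14,  0.66, -0.15,  -0.39,
    "NLR",   "OCC",      4.16,  0.09,  0.28, -0.17,  -0.48
  )
}

#' Fetch one published logistic model
#'
#' @param method `"ISP"`, `"bSVD"` or `"NLR"`.
#' @param scenario `"REC"` or `"OCC"`.
#' @return A [logistic_model()].
#' @export
reference_model <- function(method = c("bSVD", "ISP", "NLR"),
                            scenario = c("REC", "OCC")) {
  method <- match.arg(method)
  scenario <- match.arg(scenario)
  row <- dplyr::filter(reference_coefficients(),
                       .data$method == !!method, .data$scenario == !!scenario)
  logistic_model(c(int = row$int, cbf = row$cbf, cbv = row$cbv,
                   mtt = row$mtt, ttp = row$ttp), scenario)
}

#' Published reference ROC thresholds
#'
#' Best-AUC parameter, Youden-optimal cutoff, AUC and Youden index per CTP
#' processing method and patient scenario, as established on clinical
#' training data.
#'
#' @return A tibble with columns `method`, `scenario`, `parameter`,
#'   `direction`, `cutoff`, `auc`, `youden_j`.
#' @export
reference_thresholds <- function() {
  tibble::tribble(
    ~method, ~scenario, ~parameter, ~direction, ~cutoff, ~auc, ~youden_j,
    "ISP",   "REC",     "cbf",      "below",     14.0,    0.68, 0.29,
    "ISP",   "OCC",     "mtt",      "above",     11.0,    0.75, 0.44,
    "bSVD",  "REC",     "cbf",      "below",      9.0,    0.74, 0.38,
    "bSVD",  "OCC",     "ttp",      "above",      6.0,    0.79, 0.49,
    "NLR",   "REC",     "cbf",      "below",     10.0,    0.78, 0.41,
    "NLR",   "OCC",     "ttp",      "above",      6.5,    0.82, 0.54
  )
}

#' Vendor preset threshold rules
#'
#' The clinical core/penumbra definitions implemented by four commercial
#' CTP packages. Absolute-valued definitions are returned as evaluable
#' [threshold_rule()]s; definitions relative to the contralateral
#' hemisphere (prefixed "r") are returned flagged `supported = FALSE`, as
#' no standard definition of relative values exists.
#'
#' @param vendor One of `"ISP"`, `"syngo.via"`, `"Vitrea"`, `"RAPID"`.
#' @return A tibble with columns `vendor`, `region`, `description`,
#'   `supported` and a list-column `rule` (a `threshold_rule` or `NULL`).
#' @export
preset_rules <- function(vendor = c("ISP", "syngo.via", "Vitrea", "RAPID")) {
  vendor <- match.arg(vendor)
  all <- tibble::tribble(
    ~vendor,     ~region,    ~description,                       ~supported, ~parameter, ~direction, ~cutoff,
    "ISP",       "core",     "CBV < 2.0 mL/100g & rMTT > 150%",  FALSE,      NA,         NA,         NA,
    "ISP",       "penumbra", "rMTT > 150%",                      FALSE,      NA,         NA,         NA,
    "syngo.via", "core",     "CBV < 1.2 mL/100g",                TRUE,       "cbv",      "below",    1.2,
    "syngo.via", "penumbra", "CBF < 27.0 mL/100g/min",           TRUE,       "cbf",      "below",    27.0,
    "Vitrea",    "core",     "rCBV < 41%",                       FALSE,      NA,         NA,         NA,
    "Vitrea",    "penumbra", "TTP > 6.8 s",                      TRUE,       "ttp",      "above",    6.8,
    "RAPID",     "core",     "rCBF < 30%",                       FALSE,      NA,         NA,         NA,
    "RAPID",     "penumbra", "Tmax > 6 s",                       TRUE,       "ttp",      "above",    6.0
  )
  out <- dplyr::filter(all, .data$vendor == !!vendor)
  out$rule <- purrr::pmap(
    list(out$supported, out$parameter, out$direction, out$cutoff),
    function(s, p, d, c) if (s) threshold_rule(p, d, c) else NULL
  )
  dplyr::select(out, "vendor", "region", "description", "supported", "rule")
}
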
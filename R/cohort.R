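#' Distribution of lesion geometry and class means across a cohort
#'
#' Ranges from which per-case phantoms are drawn: uniform lesion radii,
#' uniform lesion centre within the hemisphere (either side with equal
#' probability), and a multiplicative jitter applied to every class mean so
#' that cases differ in severity the way patients do.
#'
#' @param core_radius_range,penumbra_margin_range Uniform ranges (mm) for
#'   the core radius and for the penumbra radius in excess of the core.
#' @param center_y_range,center_z_range Uniform ranges (mm) for the lesion
#'   centre in the sagittal plane.
#' @param mean_jitter Half-width of the uniform multiplicative jitter on
#'   class means (0.1 = +/-10%).
#' @param grid_shape,voxel_spacing,noise_sd,noise_correlation_mm Passed to
#'   [phantom_spec()].
#' @param tissue_params Baseline class table, see [default_tissue_params()].
#' @return An object of class `cohort_distribution`.
#' @export
cohort_distribution <- function(core_radius_range = c(7, 11),
                                penumbra_margin_range = c(5, 9),
                                center_y_range = c(-20, 20),
                                center_z_range = c(-4, 4),
                                mean_jitter = 0.1,
                                grid_shape = c(96, 96, 12),
                                voxel_spacing = c(2, 2, 5),
                                noise_sd = 1,
                                noise_correlation_mm = 4,
                                tissue_params = default_tissue_params()) {
  structure(
    list(core_radius_range = core_radius_range,
         penumbra_margin_range = penumbra_margin_range,
         center_y_range = center_y_range, center_z_range = center_z_range,
         mean_jitter = mean_jitter, grid_shape = grid_shape,
         voxel_spacing = voxel_spacing, noise_sd = noise_sd,
         noise_correlation_mm = noise_correlation_mm,
         tissue_params = validate_tissue_params(tissue_params)),
    class = "cohort_distribution"
  )
}

#' Generate a synthetic cohort of ground-truth cases
#'
#' Draws `n_rec` cases under the successful-recanalization scenario (REC:
#' the follow-up infarct equals the core) and `n_occ` cases under the
#' persistent-occlusion scenario (OCC: the follow-up infarct equals the
#' total hypoperfused region), each with randomized lesion size, location
#' and side and jittered class means. Each scenario is split 2:1 into
#' training and test cases. The whole draw is reproducible from `seed`.
#'
#' @param n_rec,n_occ Numbers of REC and OCC cases (>= 0).
#' @param dist A [cohort_distribution()].
#' @param seed Master seed; per-case seeds are derived deterministically.
#' @return A tibble manifest with columns `case_id`, `scenario`, `split`,
#'   `lesion_side`, `true_volume_ml`, `seed` and a list-column `case` of
#'   `ground_truth_case` objects.
#' @export
generate_cohort <- function(n_rec, n_occ, dist = cohort_distribution(), seed = 1L) {
  if (n_rec < 0 || n_occ < 0) abort("`n_rec` and `n_occ` must be >= 0")
  plan <- tibble(
    scenario = c(rep("REC", n_rec), rep("OCC", n_occ)),
    within = c(seq_len(n_rec), seq_len(n_occ))
  )
  if (nrow(plan) == 0) {
    return(tibble(case_id = character(), scenario = character(),
                  split = character(), lesion_side = character(),
                  true_volume_ml = numeric(), seed = integer(),
                  case = list()))
  }
  n_by <- c(REC = n_rec, OCC = n_occ)
  rows <- purrr::pmap(list(plan$scenario, plan$within, seq_len(nrow(plan))),
    function(scenario, within, i) {
      case_seed <- derive_seed(seed, i)
      case_id <- sprintf("%s%03d", tolower(scenario), within)
      case <- draw_case(case_id, scenario, dist, case_seed)
      n_train <- round(2 * n_by[[scenario]] / 3)
      tibble(
        case_id = case_id, scenario = scenario,
        split = if (within <= n_train) "train" else "test",
        lesion_side = case$tissue$lesion_side,
        true_volume_ml = case$true_volume_ml,
        seed = case_seed, case = list(case)
      )
    })
  dplyr::bind_rows(rows)
}

draw_case <- function(case_id, scenario, dist, case_seed) {
  set.seed(case_seed)
  tp <- dist$tissue_params
  if (dist$mean_jitter > 0) {
    tp$mean <- tp$mean * runif(nrow(tp), 1 - dist$mean_jitter, 1 + dist$mean_jitter)
  }
  half_x <- dist$grid_shape[1] * dist$voxel_spacing[1] / 2
  spec <- NULL
  for (try in 1:100) {
    core_r <- runif(1, dist$core_radius_range[1], dist$core_radius_range[2])
    pen_r <- core_r + runif(1, dist$penumbra_margin_range[1],
                            dist$penumbra_margin_range[2])
    side <- if (runif(1) < 0.5) -1 else 1
    x_lo <- pen_r + 4
    x_hi <- 0.9 * half_x - pen_r - 2
    if (x_hi <= x_lo) next
    center <- c(side * runif(1, x_lo, x_hi),
                runif(1, dist$center_y_range[1], dist$center_y_range[2]),
                runif(1, dist$center_z_range[1], dist$center_z_range[2]))
    cand <- try(phantom_spec(grid_shape = dist$grid_shape,
                             voxel_spacing = dist$voxel_spacing,
                             lesion_center = center, core_radius = core_r,
                             penumbra_radius = pen_r, tissue_params = tp,
                             noise_sd = dist$noise_sd,
                             noise_correlation_mm = dist$noise_correlation_mm,
                             seed = case_seed),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    tissue <- try(build_phantom(cand), silent = TRUE)
    if (inherits(tissue, "try-error")) next
    spec <- cand
    break
  }
  if (is.null(spec)) abort("could not place a lesion inside the parenchyma after 100 tries")
  mask <- infarct_mask(tissue, scenario)
  structure(
    list(case_id = case_id, tissue = tissue, scenario = scenario,
         infarct_mask = mask, true_maps = class_mean_maps(tissue, spec),
         true_volume_ml = mask_volume_ml(mask, tissue$spacing),
         spec = spec, seed = case_seed),
    class = "ground_truth_case"
  )
}

#' @export
print.ground_truth_case <- function(x, ...) {
  cat(sprintf("<ground_truth_case> %s [%s], true volume %.1f mL, lesion %s\n",
              x$case_id, x$scenario, x$true_volume_ml, x$tissue$lesion_side))
  invisible(x)
}

#' Perfusion maps for a ground-truth case
#'
#' `mode = "sampled"` draws per-voxel maps from the class-conditional
#' distributions (emulating the noise of measured maps directly);
#' `mode = "ctp"` simulates the full 4D acquisition and recovers the maps by
#' block-circulant SVD deconvolution.
#'
#' @param case A `ground_truth_case`.
#' @param mode `"sampled"` or `"ctp"`.
#' @param settings,aif,times Forward/deconvolution settings for
#'   `mode = "ctp"`.
#' @return A [perfusion_maps] object.
#' @export
case_maps <- function(case, mode = c("sampled", "ctp"),
                      settings = deconv_settings(), aif = aif_model(),
                      times = seq(0, 48, by = 2)) {
  mode <- match.arg(mode)
  if (!inherits(case, "ground_truth_case")) abort("`case` must be a ground_truth_case")
  map_seed <- derive_seed(case$seed, 17L)
  if (mode == "sampled") {
    sample_true_maps(case$tissue, case$spec, seed = map_seed)
  } else {
    series <- simulate_ctp(case$tissue, case$spec, aif = aif, times = times,
                           seed = map_seed, settings = settings)
    bsvd_deconvolve(series, settings,
                    mask = case$tissue$labels != .cls[["background"]])
  }
}
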
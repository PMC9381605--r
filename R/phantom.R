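#' Default class-conditional perfusion parameters
#'
#' Mean and standard deviation of each perfusion parameter for the three
#' tissue classes of the digital phantom: normally perfused parenchyma,
#' salvageable penumbra and irreversibly damaged core. The means are placed
#' so that ROC-trained cutoffs land in the range of published clinical
#' thresholds (core CBF well below 9-14 mL/100g/min, core CBV near
#' 1.2 mL/100g, hypoperfused TTP above ~6 s); the standard deviations encode
#' moderate biological and measurement spread so the classes overlap the way
#' noisy patient maps do.
#'
#' @return A tibble with columns `class`, `parameter`, `mean`, `sd`.
#' @export
default_tissue_params <- function() {
  tibble::tribble(
    ~class,      ~parameter, ~mean, ~sd,
    "healthy",   "cbf",       50,    20,
    "healthy",   "cbv",       3.3,   1.3,
    "healthy",   "mtt",       4,     2,
    "healthy",   "ttp",       6,     2.5,
    "penumbra",  "cbf",       20,    10,
    "penumbra",  "cbv",       2.7,   1.1,
    "penumbra",  "mtt",       8,     3.5,
    "penumbra",  "ttp",       8,     3,
    "core",      "cbf",       6,     5,
    "core",      "cbv",       1.2,   0.8,
    "core",      "mtt",       12,    5,
    "core",      "ttp",       11,    3.5
  )
}

#' Specify a digital CTP phantom
#'
#' Defines the geometry and statistics of a bilateral phantom with a
#' unilateral spherical ischemic lesion: a core of radius `core_radius`
#' nested inside a penumbra of radius `penumbra_radius`, embedded in a
#' brain-shaped ellipsoid of healthy tissue split into hemispheres at the
#' mid-sagittal plane of the grid.
#'
#' @param grid_shape Integer length-3 voxel grid extents.
#' @param voxel_spacing Numeric length-3 voxel sizes in mm.
#' @param lesion_center Numeric length-3 lesion centre in mm, in grid-centred
#'   coordinates (the mid-sagittal plane is x = 0); must lie inside one
#'   hemisphere.
#' @param core_radius,penumbra_radius Lesion radii in mm,
#'   `penumbra_radius > core_radius > 0`.
#' @param tissue_params Class-conditional parameter table as produced by
#'   [default_tissue_params()].
#' @param noise_sd Additive Gaussian noise (HU) for simulated 4D series.
#' @param noise_correlation_mm Spatial correlation length (mm) of the
#'   within-class variability of sampled parameter maps: deconvolved CTP
#'   maps carry spatially correlated noise (vessels, filtering,
#'   deconvolution coupling of neighbouring voxels), which is what makes
#'   morphological cleaning of summary maps necessary in the first place.
#'   0 gives independent voxels.
#' @param brain_axes Semi-axes (mm) of the ellipsoidal parenchyma; defaults
#'   to 90% of the half-extent of the grid on each axis.
#' @param seed Integer seed recorded with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 12),
                         voxel_spacing = c(2, 2, 5),
                         lesion_center = c(-45, 0, 0),
                         core_radius = 10,
                         penumbra_radius = 18,
                         tissue_params = default_tissue_params(),
                         noise_sd = 1,
                         noise_correlation_mm = 4,
                         brain_axes = NULL,
                         seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    abort("`grid_shape` must be 3 positive integers")
  }
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0)) {
    abort("`voxel_spacing` must be 3 positive voxel sizes in mm")
  }
  stopifnot_scalar_number(core_radius, "core_radius", positive = TRUE)
  stopifnot_scalar_number(penumbra_radius, "penumbra_radius", positive = TRUE)
  if (penumbra_radius <= core_radius) {
    abort("`penumbra_radius` must exceed `core_radius`")
  }
  if (length(lesion_center) != 3 || any(!is.finite(lesion_center))) {
    abort("`lesion_center` must be 3 finite coordinates in mm")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (noise_correlation_mm < 0) abort("`noise_correlation_mm` must be >= 0")
  tp <- validate_tissue_params(tissue_params)
  if (is.null(brain_axes)) {
    brain_axes <- 0.9 * grid_shape * voxel_spacing / 2
  }
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         lesion_center = as.numeric(lesion_center),
         core_radius = core_radius, penumbra_radius = penumbra_radius,
         tissue_params = tp, noise_sd = noise_sd,
         noise_correlation_mm = noise_correlation_mm,
         brain_axes = as.numeric(brain_axes), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

validate_tissue_params <- function(tp) {
  tp <- as_tibble(tp)
  need <- c("class", "parameter", "mean", "sd")
  if (!all(need %in% names(tp))) {
    abort("`tissue_params` needs columns class, parameter, mean, sd")
  }
  classes <- c("healthy", "penumbra", "core")
  for (cl in classes) for (p in .ctp_parameters) {
    row <- tp[tp$class == cl & tp$parameter == p, ]
    if (nrow(row) != 1) abort(sprintf("missing tissue_params row for %s/%s", cl, p))
  }
  if (any(tp$sd < 0)) abort("tissue parameter SDs must be >= 0")
  m <- function(cl, p) tp$mean[tp$class == cl & tp$parameter == p]
  if (!(m("core", "cbf") < m("penumbra", "cbf") &&
        m("penumbra", "cbf") < m("healthy", "cbf"))) {
    abort("class CBF means must be ordered core < penumbra < healthy")
  }
  if (!(m("core", "mtt") > m("penumbra", "mtt") &&
        m("penumbra", "mtt") > m("healthy", "mtt"))) {
    abort("class MTT means must be ordered core > penumbra > healthy")
  }
  tp
}

class_mean <- function(spec, cl, p) {
  tp <- spec$tissue_params
  tp$mean[tp$class == cl & tp$parameter == p]
}
class_sd <- function(spec, cl, p) {
  tp <- spec$tissue_params
  tp$sd[tp$class == cl & tp$parameter == p]
}

#' Rasterize a phantom specification into a tissue class map
#'
#' Builds the voxelwise tissue labels (background / healthy / penumbra /
#' core) and the hemisphere labels. The hemisphere split is the mid-sagittal
#' plane of the grid (first axis); the lesion must lie entirely inside one
#' hemisphere and inside the parenchyma ellipsoid. The construction is
#' deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `tissue_class_map` with elements `labels`
#'   (integer array: 0 background, 1 healthy, 2 penumbra, 3 core),
#'   `hemisphere` (integer array: 1 left, 2 right), `spacing` (mm).
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec")
  d <- spec$grid_shape; sp <- spec$voxel_spacing
  x <- axis_coords(d[1], sp[1])
  y <- axis_coords(d[2], sp[2])
  z <- axis_coords(d[3], sp[3])
  if (abs(spec$lesion_center[1]) < spec$penumbra_radius) {
    abort("lesion extends across the midline; keep |x| of `lesion_center` >= `penumbra_radius`")
  }
  X <- array(x, dim = d)
  Y <- array(rep(y, each = d[1]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)

  ax <- spec$brain_axes
  brain <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1

  lc <- spec$lesion_center
  r2 <- (X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2
  pen <- r2 <= spec$penumbra_radius^2
  core <- r2 <= spec$core_radius^2
  if (!any(core)) abort("lesion lies outside the voxel grid")
  if (any(pen & !brain)) abort("lesion extends outside the parenchyma; move or shrink it")

  labels <- array(.cls[["background"]], dim = d)
  labels[brain] <- .cls[["healthy"]]
  labels[pen] <- .cls[["penumbra"]]
  labels[core] <- .cls[["core"]]

  hemisphere <- array(.hemi[["right"]], dim = d)
  hemisphere[X < 0] <- .hemi[["left"]]

  lesion_side <- if (lc[1] < 0) "left" else "right"
  structure(
    list(labels = labels, hemisphere = hemisphere, spacing = sp,
         lesion_side = lesion_side),
    class = "tissue_class_map"
  )
}

#' @export
print.tissue_class_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = .cls, labels = names(.cls)))
  cat("<tissue_class_map>", paste(names(tab), tab, sep = "=", collapse = " "),
      sprintf("(lesion side: %s)\n", x$lesion_side))
  invisible(x)
}

#' Draw per-voxel perfusion maps from the class-conditional distributions
#'
#' Samples CBF, CBV, MTT and TTP for every parenchymal voxel from normal
#' distributions conditional on the voxel's tissue class, bounded at the
#' physically valid minimum (non-negative values). With
#' `noise_correlation_mm = 0` the draws are independent truncated normals;
#' otherwise the within-class deviates come from a unit-variance Gaussian
#' random field smoothed to the requested correlation length (clipped at
#' zero), emulating the spatially correlated noise of deconvolved CTP
#' maps. Background voxels carry 0 and are excluded from the mask.
#'
#' @param tissue A `tissue_class_map` from [build_phantom()].
#' @param spec The generating [phantom_spec()].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A [perfusion_maps] object.
#' @export
sample_true_maps <- function(tissue, spec, seed = spec$seed) {
  check_tissue(tissue)
  labs <- tissue$labels
  known <- labs %in% .cls
  if (!all(known)) abort("tissue map contains unknown class labels")
  d <- dim(labs)
  corr <- spec$noise_correlation_mm %||% 0
  maps <- setNames(
    lapply(.ctp_parameters, function(p) array(0, dim = d)),
    .ctp_parameters
  )
  set.seed(seed)
  for (p in .ctp_parameters) {
    field <- if (corr > 0) gaussian_field(d, tissue$spacing, corr) else NULL
    for (cl in c("healthy", "penumbra", "core")) {
      idx <- which(labs == .cls[[cl]])
      if (!length(idx)) next
      mu <- class_mean(spec, cl, p)
      sd_cl <- class_sd(spec, cl, p)
      vals <- if (is.null(field)) {
        rtruncnorm_lower(length(idx), mu, sd_cl, lower = 0)
      } else {
        pmax(0, mu + sd_cl * field[idx])
      }
      maps[[p]][idx] <- vals
    }
  }
  perfusion_maps(maps$cbf, maps$cbv, maps$mtt, maps$ttp,
                 mask = labs != .cls[["background"]],
                 spacing = tissue$spacing)
}

# Unit-variance Gaussian random field with approximately the requested
# correlation length (mm): white noise smoothed by a separable Gaussian
# kernel (sigma = corr_mm per axis, in voxels), then renormalised so the
# marginal variance is 1. Uses the caller's RNG state.
gaussian_field <- function(d, spacing, corr_mm) {
  x <- array(rnorm(prod(d)), dim = d)
  for (ax in 1:3) {
    sigma <- corr_mm / spacing[ax]
    if (sigma < 0.3) next
    r <- max(1L, ceiling(2.5 * sigma))
    w <- exp(-((-r:r)^2) / (2 * sigma^2))
    w <- w / sum(w)
    acc <- array(0, dim = d)
    for (k in -r:r) {
      off <- c(0L, 0L, 0L); off[ax] <- k
      acc <- acc + w[k + r + 1] * shift_array_num(x, off)
    }
    x <- acc / sqrt(sum(w^2))
  }
  x
}

# numeric variant of shift_array with edge replication (keeps the field
# variance stable at the boundary)
shift_array_num <- function(a, offset) {
  d <- dim(a)
  idx <- vector("list", 3)
  for (ax in 1:3) {
    o <- offset[ax]
    ii <- seq_len(d[ax]) - o
    ii <- pmin(pmax(ii, 1L), d[ax])
    idx[[ax]] <- ii
  }
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Noise-free class-mean perfusion maps
#'
#' Every voxel carries exactly its class mean; used as the phantom ground
#' truth against which recovered maps are scored.
#'
#' @inheritParams sample_true_maps
#' @return A [perfusion_maps] object.
#' @export
class_mean_maps <- function(tissue, spec) {
  check_tissue(tissue)
  labs <- tissue$labels
  d <- dim(labs)
  maps <- setNames(
    lapply(.ctp_parameters, function(p) array(0, dim = d)),
    .ctp_parameters
  )
  for (cl in c("healthy", "penumbra", "core")) {
    idx <- which(labs == .cls[[cl]])
    for (p in .ctp_parameters) maps[[p]][idx] <- class_mean(spec, cl, p)
  }
  perfusion_maps(maps$cbf, maps$cbv, maps$mtt, maps$ttp,
                 mask = labs != .cls[["background"]],
                 spacing = tissue$spacing)
}

check_tissue <- function(tissue) {
  if (!inherits(tissue, "tissue_class_map")) {
    abort("`tissue` must be a tissue_class_map from build_phantom()")
  }
  if (!identical(dim(tissue$labels), dim(tissue$hemisphere))) {
    abort("label and hemisphere grids must share one shape")
  }
  invisible(tissue)
}

#' Ground-truth infarct mask for a scenario
#'
#' Under successful recanalization (REC) the follow-up infarct equals the
#' core; under persistent occlusion (OCC) it equals the total hypoperfused
#' region (core plus penumbra).
#'
#' @param tissue A `tissue_class_map`.
#' @param scenario `"REC"` or `"OCC"`.
#' @return A 3D logical array.
#' @export
infarct_mask <- function(tissue, scenario = c("REC", "OCC")) {
  scenario <- match.arg(scenario)
  check_tissue(tissue)
  if (scenario == "REC") {
    tissue$labels == .cls[["core"]]
  } else {
    tissue$labels == .cls[["core"]] | tissue$labels == .cls[["penumbra"]]
  }
}

#' Volume of a voxel mask in mL
#'
#' @param mask 3D logical array.
#' @param spacing Voxel spacing in mm.
#' @return Volume in mL (voxel count times voxel volume).
#' @export
mask_volume_ml <- function(mask, spacing) {
  sum(mask) * prod(spacing) / 1000
}
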
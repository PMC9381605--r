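#' Read a 3D or 4D NIfTI volume
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @return A list with `data` (numeric array), `spacing` (mm, one value per
#'   spatial axis) and `affine` (4x4 voxel-to-world matrix, retained for
#'   round-tripping).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf("not a valid NIfTI file: %s (%s)",
                                                    path, conditionMessage(e))))
  nd <- length(dim(img))
  if (nd < 3 || nd > 4) abort(sprintf("expected a 3D or 4D volume, got %dD", nd))
  spacing <- RNifti::pixdim(img)[1:3]
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = as.numeric(spacing),
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write an array as NIfTI
#'
#' @param data 3D or 4D numeric/logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm.
#' @param datatype NIfTI storage type, e.g. `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing, datatype = "float") {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  attr(data, "pixdim") <- c(spacing, rep(1, length(dim(data)) - 3))
  img <- RNifti::asNifti(data, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write the phantom volumes of a ground-truth case to NIfTI
#'
#' Writes tissue labels, hemisphere labels, the infarct mask and the four
#' noise-free parameter maps into a directory.
#'
#' @param case A `ground_truth_case`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_case <- function(case, dir) {
  if (!inherits(case, "ground_truth_case")) abort("`case` must be a ground_truth_case")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$tissue$spacing
  paths <- c(
    labels = file.path(dir, sprintf("%s_labels.nii.gz", case$case_id)),
    hemisphere = file.path(dir, sprintf("%s_hemisphere.nii.gz", case$case_id)),
    infarct = file.path(dir, sprintf("%s_infarct.nii.gz", case$case_id))
  )
  write_volume(case$tissue$labels, paths["labels"], sp, datatype = "uint8")
  write_volume(case$tissue$hemisphere, paths["hemisphere"], sp, datatype = "uint8")
  write_volume(case$infarct_mask, paths["infarct"], sp, datatype = "uint8")
  for (p in .ctp_parameters) {
    f <- file.path(dir, sprintf("%s_true_%s.nii.gz", case$case_id, p))
    write_volume(case$true_maps[[p]], f, sp)
    paths[paste0("true_", p)] <- f
  }
  invisible(paths)
}

#' Write a cohort manifest as CSV
#'
#' @param cohort Manifest tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  readr::write_csv(dplyr::select(cohort, -"case"), path)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' @param path CSV with columns `case_id`, `scenario`, `split`,
#'   `lesion_side`, `true_volume_ml`, `seed`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("case_id", "scenario", "split", "lesion_side",
            "true_volume_ml", "seed")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    abort(sprintf("manifest is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(man$case_id)) abort("manifest case_ids must be unique")
  man
}

#' Load and validate a pipeline configuration
#'
#' YAML with optional blocks `cohort` (n_rec, n_occ, noise_sd), `deconv`
#' (svd_truncation_fraction, density_constant, hematocrit_factor),
#' `evaluation` (grid_style, map_mode) and `seed`. Every setting is
#' validated against the module preconditions at load time.
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    seed = as.integer(raw$seed %||% 1L),
    n_rec = as.integer(raw$cohort$n_rec %||% 12L),
    n_occ = as.integer(raw$cohort$n_occ %||% 12L),
    noise_sd = as.numeric(raw$cohort$noise_sd %||% 1),
    grid_shape = as.integer(raw$cohort$grid_shape %||% c(96L, 96L, 12L)),
    voxel_spacing = as.numeric(raw$cohort$voxel_spacing %||% c(2, 2, 5)),
    settings = deconv_settings(
      svd_truncation_fraction = raw$deconv$svd_truncation_fraction %||% 0.10,
      density_constant = raw$deconv$density_constant %||% 1.05,
      hematocrit_factor = raw$deconv$hematocrit_factor %||% 0.73
    ),
    grid_style = match.arg(raw$evaluation$grid_style %||% "inhouse",
                           c("inhouse", "isp")),
    map_mode = match.arg(raw$evaluation$map_mode %||% "sampled",
                         c("sampled", "ctp"))
  )
  if (cfg$n_rec < 0 || cfg$n_occ < 0) abort("cohort sizes must be >= 0")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Run the simulate-train-evaluate pipeline end to end
#'
#' Generates a cohort per the config, runs [run_experiment()] and writes
#' `manifest.csv`, `pr_curves.csv`, `volumes.csv`, `stats.csv`, `tests.csv`
#' and `summary.json` to `out_dir`. Idempotent given the seed: a rerun
#' reproduces identical outputs.
#'
#' @param config A `pipeline_config` from [load_pipeline_config()] (or a
#'   path to the YAML).
#' @param out_dir Output directory.
#' @return The `ctp_experiment` result, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dist <- cohort_distribution(noise_sd = config$noise_sd,
                              grid_shape = config$grid_shape,
                              voxel_spacing = config$voxel_spacing)
  cohort <- generate_cohort(config$n_rec, config$n_occ, dist,
                            seed = config$seed)
  write_manifest(cohort, file.path(out_dir, "manifest.csv"))

  result <- run_experiment(cohort, map_mode = config$map_mode,
                           grids = pr_grids(config$grid_style),
                           settings = config$settings)
  readr::write_csv(result$pr_curves, file.path(out_dir, "pr_curves.csv"))
  readr::write_csv(result$volumes, file.path(out_dir, "volumes.csv"))
  readr::write_csv(result$stats, file.path(out_dir, "stats.csv"))
  readr::write_csv(result$tests, file.path(out_dir, "tests.csv"))

  summary <- list(
    seed = config$seed,
    rules = lapply(result$rules, function(r) tidy(r)),
    models = lapply(result$models, function(m) as.list(m$coefficients))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(result)
}
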
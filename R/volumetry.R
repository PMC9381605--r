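# spherical structuring element rasterized in physical coordinates:
# a voxel offset is inside the element iff its centre lies within `radius`
# mm of the element centre
sphere_offsets <- function(spacing, radius = 2.5) {
  nmax <- pmax(0, floor(radius / spacing))
  offs <- expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2],
                      dz = -nmax[3]:nmax[3])
  d2 <- (offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 +
    (offs$dz * spacing[3])^2
  offs <- offs[d2 <= radius^2, , drop = FALSE]
  as.matrix(offs)
}

# `pad` is the assumed value outside the array: FALSE for opening
# (boundary islands must not survive), TRUE for the erosion inside closing
# (complement duality keeps closing extensive).
erode <- function(a, offsets, pad = FALSE) {
  out <- array(TRUE, dim = dim(a))
  for (r in seq_len(nrow(offsets))) {
    out <- out & shift_array(a, -offsets[r, ], fill = pad)
  }
  out
}

dilate <- function(a, offsets) {
  out <- array(FALSE, dim = dim(a))
  for (r in seq_len(nrow(offsets))) {
    out <- out | shift_array(a, offsets[r, ], fill = FALSE)
  }
  out
}

#' Morphological noise cleaning of a summary map
#'
#' Binary opening followed by binary closing, both with a spherical
#' structuring element of 5 mm diameter rasterized in physical coordinates
#' (a voxel belongs to the element iff its centre lies within 2.5 mm of the
#' element centre, per-axis by the voxel spacing). Opening removes islands
#' smaller than the element; closing fills comparable holes. When the
#' spacing exceeds the element radius along every axis the element
#' degenerates to a single voxel (cleaning becomes the identity) and a
#' warning is emitted.
#'
#' @param map A `summary_map` from [apply_threshold()] (or any 3D logical
#'   array if `spacing` is given).
#' @param spacing Voxel spacing in mm; taken from the map when omitted.
#' @param diameter_mm Element diameter, default 5 mm.
#' @return The cleaned `summary_map`.
#' @export
morphological_clean <- function(map, spacing = attr(map, "spacing"),
                                diameter_mm = 5) {
  if (is.null(spacing)) abort("voxel `spacing` is required")
  offs <- sphere_offsets(spacing, diameter_mm / 2)
  if (nrow(offs) == 1) {
    warn("structuring element degenerates to a single voxel at this spacing; map unchanged")
    return(map)
  }
  a <- map
  attrs <- attributes(map)
  a <- dilate(erode(a, offs), offs)               # opening
  a <- erode(dilate(a, offs), offs, pad = TRUE)   # closing
  attributes(a) <- attrs
  attr(a, "cleaned") <- TRUE
  a
}

#' Threshold-based volume of a summary map
#'
#' Sum of the voxel volumes of all flagged voxels, in mL. The map is
#' morphologically cleaned first unless it already carries the `cleaned`
#' flag or `clean = FALSE`.
#'
#' @param map A `summary_map`.
#' @param spacing Voxel spacing in mm; taken from the map when omitted.
#' @param clean Run [morphological_clean()] first (recorded in the result).
#' @param case_id,scenario Bookkeeping tags.
#' @return A one-row tibble: `case_id`, `scenario`, `method`
#'   (`"threshold"`), `volume_ml`.
#' @export
threshold_volume <- function(map, spacing = attr(map, "spacing"),
                             clean = TRUE, case_id = NA_character_,
                             scenario = NA_character_) {
  if (is.null(spacing)) abort("voxel `spacing` is required")
  if (clean && !isTRUE(attr(map, "cleaned"))) {
    map <- morphological_clean(map, spacing)
  }
  tibble(case_id = case_id, scenario = scenario, method = "threshold",
         volume_ml = sum(map) * prod(spacing) / 1000)
}

#' Probabilistic volume by hemisphere difference
#'
#' Sums probability times voxel volume over the left and the right
#' hemisphere separately and takes the absolute difference of the two sums.
#' Symmetric noise cancels between hemispheres, so no morphological
#' cleaning is applied. When the lesion side is known and the contralateral
#' sum exceeds the ipsilateral one, a warning flags likely model
#' miscalibration.
#'
#' @param pmap A `probability_map` from [predict_probability()].
#' @param hemisphere 3D integer hemisphere labels (1 left, 2 right) covering
#'   the parenchyma.
#' @param spacing Voxel spacing in mm; taken from the map when omitted.
#' @param lesion_side Optional `"left"`/`"right"`.
#' @param case_id,scenario Bookkeeping tags.
#' @return A one-row tibble: `case_id`, `scenario`, `method`
#'   (`"probabilistic"`), `volume_ml`.
#' @export
probabilistic_volume <- function(pmap, hemisphere,
                                 spacing = attr(pmap, "spacing"),
                                 lesion_side = NULL,
                                 case_id = NA_character_,
                                 scenario = NA_character_) {
  if (is.null(spacing)) abort("voxel `spacing` is required")
  if (!identical(dim(hemisphere), dim(pmap)[1:3])) {
    abort("`hemisphere` must share the map grid")
  }
  p <- as.numeric(pmap)
  covered <- hemisphere %in% .hemi
  if (any(p > 0 & !covered)) {
    abort("hemisphere labels must cover every voxel with non-zero probability")
  }
  vox_ml <- prod(spacing) / 1000
  s_left <- sum(p[hemisphere == .hemi[["left"]]]) * vox_ml
  s_right <- sum(p[hemisphere == .hemi[["right"]]]) * vox_ml
  if (!is.null(lesion_side)) {
    ipsi <- if (lesion_side == "left") s_left else s_right
    contra <- if (lesion_side == "left") s_right else s_left
    if (contra > ipsi) {
      warn("contralateral probability mass exceeds ipsilateral; model may be miscalibrated")
    }
  }
  tibble(case_id = case_id, scenario = scenario, method = "probabilistic",
         volume_ml = abs(s_left - s_right))
}
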
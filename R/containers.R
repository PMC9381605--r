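#' Bundle co-registered perfusion parameter maps
#'
#' Container for the four voxelwise perfusion parameters produced by CTP
#' processing — cerebral blood flow (CBF, mL/100g/min), cerebral blood volume
#' (CBV, mL/100g), mean transit time (MTT, s) and time to peak (TTP, s) —
#' together with a parenchyma mask and the voxel spacing.
#'
#' @param cbf,cbv,mtt,ttp 3D numeric arrays of identical dimension.
#' @param mask 3D logical array flagging parenchymal voxels.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `perfusion_maps`.
#' @export
perfusion_maps <- function(cbf, cbv, mtt, ttp, mask, spacing) {
  dims <- dim(cbf)
  if (length(dims) != 3) abort("maps must be 3D arrays")
  for (nm in list(cbv = cbv, mtt = mtt, ttp = ttp, mask = mask)) {
    if (!identical(dim(nm), dims)) abort("all maps and the mask must share one shape")
  }
  if (!is.logical(mask)) mask <- mask != 0
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive voxel sizes in mm")
  }
  inside <- mask
  for (m in list(cbf, cbv, mtt, ttp)) {
    v <- m[inside]
    if (any(is.finite(v) & v < 0)) abort("perfusion values inside the mask must be >= 0")
  }
  structure(
    list(cbf = cbf, cbv = cbv, mtt = mtt, ttp = ttp,
         mask = mask, spacing = as.numeric(spacing), units = .ctp_units),
    class = "perfusion_maps"
  )
}

#' @export
print.perfusion_maps <- function(x, ...) {
  d <- dim(x$cbf)
  cat(sprintf("<perfusion_maps> %d x %d x %d voxels @ %s mm, %d parenchymal\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Turn perfusion maps into a voxel tibble
#'
#' One row per parenchymal voxel with the voxel index and the four parameter
#' values; the workhorse for piping map data into the training and
#' evaluation verbs.
#'
#' @param x A [perfusion_maps] object.
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `k`, `cbf`, `cbv`, `mtt`, `ttp`.
#' @method tidy perfusion_maps
#' @export
tidy.perfusion_maps <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    cbf = x$cbf[x$mask], cbv = x$cbv[x$mask],
    mtt = x$mtt[x$mask], ttp = x$ttp[x$mask]
  )
}

#' Construct a 4D CTP time series
#'
#' @param data 4D array of attenuation (HU): three spatial axes plus time.
#' @param times Acquisition times in seconds, strictly increasing and
#'   uniformly spaced.
#' @param aif_curve Noise-free arterial input curve (HU), one value per frame.
#' @param aif_voxel Integer length-3 index of the designated arterial voxel.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `ctp_series`.
#' @export
ctp_series <- function(data, times, aif_curve, aif_voxel, spacing) {
  if (length(dim(data)) != 4) abort("`data` must be a 4D array (x, y, z, time)")
  nt <- length(times)
  if (dim(data)[4] != nt) abort("time axis of `data` must match `times`")
  if (nt < 2 || any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-8 * max(dts)) {
    abort("`times` must be uniformly spaced (deconvolution assumes uniform sampling)")
  }
  if (length(aif_curve) != nt) abort("`aif_curve` must have one value per frame")
  structure(
    list(data = data, times = as.numeric(times), aif_curve = as.numeric(aif_curve),
         aif_voxel = as.integer(aif_voxel), spacing = as.numeric(spacing)),
    class = "ctp_series"
  )
}

#' @export
print.ctp_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ctp_series> %d x %d x %d voxels, %d frames over %.0f s (dt %.1f s)\n",
              d[1], d[2], d[3], d[4], max(x$times) - min(x$times), diff(x$times)[1]))
  invisible(x)
}
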
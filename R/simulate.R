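#' Simulate a 4D CTP acquisition from a tissue class map
#'
#' Forward indicator-dilution model on the acquisition grid. Each voxel's
#' tissue curve is the block-circulant convolution of the arterial input
#' curve with a scaled exponential residue function,
#' `curve = kappa * CBF/6000 * (A %*% R)`, where `kappa` is the
#' density/hematocrit constant of `settings` and `A` the same operator that
#' [bsvd_deconvolve()] inverts. The residue decay is chosen so that the
#' discrete residue area equals the class MTT, which makes both the residue
#' peak (CBF) and the curve area (CBV) exact on the sample grid. The curve
#' is then delayed by a whole number of samples so that it peaks at the
#' class TTP, and Gaussian noise with `spec$noise_sd` HU is added. The
#' designated arterial voxel stores the noise-free AIF.
#'
#' Classes with MTT no larger than the sampling interval cannot be
#' represented on the grid and are rejected; target TTPs earlier than the
#' undelayed peak are clamped to zero delay with a warning.
#'
#' @param tissue A `tissue_class_map` from [build_phantom()].
#' @param spec The generating [phantom_spec()] (class means and `noise_sd`).
#' @param aif An [aif_model()].
#' @param times Uniformly spaced acquisition times (s).
#' @param seed Integer seed for the noise draw.
#' @param settings [deconv_settings()] supplying the density and hematocrit
#'   constants of the forward scaling.
#' @param aif_voxel Integer length-3 index of the voxel that carries the
#'   noise-free arterial curve; defaults to the grid corner (background).
#' @return A [ctp_series()].
#' @export
simulate_ctp <- function(tissue, spec, aif = aif_model(),
                         times = seq(0, 48, by = 2), seed = spec$seed,
                         settings = deconv_settings(),
                         aif_voxel = c(1L, 1L, 1L)) {
  check_tissue(tissue)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing")
  }
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-8 * max(dts)) {
    abort("`times` must be uniformly spaced (deconvolution assumes uniform sampling)")
  }
  dt <- dts[1]
  L <- length(times)
  aif_curve <- gamma_variate(aif, times)
  A <- circulant_operator(aif_curve, dt)
  kappa <- deconv_kappa(settings)

  d <- dim(tissue$labels)
  data_mat <- matrix(0, prod(d), L)
  for (cl in c("healthy", "penumbra", "core")) {
    vox <- which(tissue$labels == .cls[[cl]])
    if (!length(vox)) next
    curve <- class_tissue_curve(spec, cl, A, dt, L, kappa)
    data_mat[vox, ] <- matrix(curve, length(vox), L, byrow = TRUE)
  }
  data <- array(data_mat, dim = c(d, L))

  if (spec$noise_sd > 0) {
    set.seed(seed)
    data <- data + array(rnorm(length(data), 0, spec$noise_sd), dim = dim(data))
  }
  av <- as.integer(aif_voxel)
  data[av[1], av[2], av[3], ] <- aif_curve
  ctp_series(data, times, aif_curve, av, tissue$spacing)
}

# Noise-free tissue curve of one class on the acquisition grid.
class_tissue_curve <- function(spec, cl, A, dt, L, kappa) {
  cbf <- class_mean(spec, cl, "cbf")
  mtt <- class_mean(spec, cl, "mtt")
  ttp <- class_mean(spec, cl, "ttp")
  if (cbf == 0) return(numeric(L))
  if (mtt <= dt) {
    abort(sprintf("class MTT (%.2f s) must exceed the sampling interval (%.2f s)", mtt, dt))
  }
  # decay chosen so the discrete residue area equals the class MTT
  tau <- -dt / log(1 - dt / mtt)
  R <- exp(-seq(0, by = dt, length.out = 2L * L) / tau)
  ct <- as.vector(A %*% (kappa * cbf / 6000 * R))
  nat_peak <- (which.max(ct[seq_len(L)]) - 1L) * dt
  delay <- round((ttp - nat_peak) / dt)
  if (delay < 0) {
    warn(sprintf(
      "class '%s' TTP %.1f s precedes the undelayed curve peak %.1f s; using zero delay",
      cl, ttp, nat_peak))
    delay <- 0L
  }
  ct <- c(numeric(delay), ct)[seq_len(2L * L)]
  ct[seq_len(L)]
}
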
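# internal helpers shared across modules

# Draw from a normal truncated below at `lower` by inverse-CDF sampling.
# Exact (no rejection), vectorised, reproducible under the caller's RNG state.
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- pnorm((lower - mean) / sd)
  u <- runif(n, p_lo, 1)
  # guard u == 1 from floating roundoff
  u <- pmin(u, 1 - .Machine$double.eps)
  mean + sd * qnorm(u)
}

# Physical coordinates (mm) of voxel centres along one axis, centred on the
# grid so the mid-sagittal plane is x = 0. Even extents place no voxel on
# the midline; with odd extents the central voxel sits at exactly 0.
axis_coords <- function(n, spacing) {
  (seq_len(n) - (n + 1) / 2) * spacing
}

# Trapezoidal integral over uniformly spaced samples.
trapz <- function(y, dt) {
  n <- length(y)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Shift a 3D logical array by an integer voxel offset, padding with `fill`.
shift_array <- function(a, offset, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- offset[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]
      src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o)
      src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Stable per-case seed derived from a master seed and a case index; kept
# well inside the 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive", name))
  invisible(x)
}
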
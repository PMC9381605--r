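# Brute-force oracles and small fixture builders shared across tests.
# The oracles deliberately use naive enumeration, independent of the
# package's vectorised implementations.

# Pairwise concordance probability: for every (ischemic, healthy) pair,
# count 1 when the ischemic voxel is on the ischemic side of the healthy
# one (lower for below-directed parameters, higher for above-directed),
# 1/2 for ties.
oracle_auc <- function(values, labels, direction) {
  pos <- values[labels == "ischemic"]
  neg <- values[labels == "healthy"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p == q) 0.5 else {
      if (direction == "below") as.numeric(p < q) else as.numeric(p > q)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden maximization over midpoint candidate cutoffs with the
# package's tie rule (fewest voxels classified ischemic).
oracle_youden <- function(values, labels, direction) {
  u <- sort(unique(values))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best_j <- -Inf; best_cut <- NA
  scan <- if (direction == "below") cand else rev(cand)
  for (cut in scan) {
    flag <- if (direction == "below") values < cut else values > cut
    sens <- sum(flag & labels == "ischemic") / sum(labels == "ischemic")
    spec <- sum(!flag & labels == "healthy") / sum(labels == "healthy")
    j <- sens + spec - 1
    # strict > keeps the earliest-scanned maximiser, i.e. the cutoff
    # flagging fewest voxels
    if (j > best_j + 1e-12) { best_j <- j; best_cut <- cut }
  }
  list(cutoff = best_cut, j = best_j)
}

# Random voxel table with both labels.
random_table <- function(n, seed) {
  set.seed(seed)
  n_pos <- sample(1:(n - 1), 1)
  tibble::tibble(
    case_id = "t",
    cbf = round(runif(n, 0, 60), 1), cbv = round(runif(n, 0, 5), 1),
    mtt = round(runif(n, 2, 20), 1), ttp = round(runif(n, 0, 15), 1),
    label = sample(c(rep("ischemic", n_pos), rep("healthy", n - n_pos)))
  )
}

# Voxels drawn from the three tissue classes with outcome labels sampled
# from a logistic model; used for coefficient-recovery checks.
simulate_model_voxels <- function(model, n, seed) {
  set.seed(seed)
  tp <- ctprob::default_tissue_params()
  cls <- sample(c("healthy", "penumbra", "core"), n, replace = TRUE)
  draw <- function(p) {
    mu <- setNames(tp$mean[tp$parameter == p], tp$class[tp$parameter == p])
    sd <- setNames(tp$sd[tp$parameter == p], tp$class[tp$parameter == p])
    pmax(0, rnorm(n, mu[cls], sd[cls]))
  }
  tab <- tibble::tibble(case_id = "sim", cbf = draw("cbf"), cbv = draw("cbv"),
                        mtt = draw("mtt"), ttp = draw("ttp"))
  co <- model$coefficients
  z <- co[["int"]] + co[["cbf"]] * tab$cbf + co[["cbv"]] * tab$cbv +
    co[["mtt"]] * tab$mtt + co[["ttp"]] * tab$ttp
  p <- 1 / (1 + exp(z))
  tab$label <- ifelse(runif(n) < p, "ischemic", "healthy")
  tab
}

# Uniform single-class tissue map: every in-brain voxel is core, so the
# class means define a spatially constant ground truth.
uniform_core_tissue <- function(dim3 = c(6, 6, 4), spacing = c(4, 4, 4)) {
  labels <- array(3L, dim = dim3)   # core everywhere
  labels[1, 1, 1] <- 0L             # background corner for the AIF voxel
  hemisphere <- array(2L, dim = dim3)
  hemisphere[seq_len(floor(dim3[1] / 2)), , ] <- 1L
  structure(list(labels = labels, hemisphere = hemisphere,
                 spacing = spacing, lesion_side = "right"),
            class = "tissue_class_map")
}

# Phantom spec whose core class carries the given parameters (other
# classes keep valid orderings around them).
uniform_core_spec <- function(cbf, mtt, ttp, cbv = cbf * mtt / 60,
                              noise_sd = 0) {
  tp <- tibble::tribble(
    ~class,     ~parameter, ~mean,       ~sd,
    "healthy",  "cbf",      cbf + 20,    0,
    "healthy",  "cbv",      cbv + 1,     0,
    "healthy",  "mtt",      max(mtt - 2, 2.5), 0,
    "healthy",  "ttp",      ttp,         0,
    "penumbra", "cbf",      cbf + 10,    0,
    "penumbra", "cbv",      cbv + 0.5,   0,
    "penumbra", "mtt",      max(mtt - 1, 2.75), 0,
    "penumbra", "ttp",      ttp,         0,
    "core",     "cbf",      cbf,         0,
    "core",     "cbv",      cbv,         0,
    "core",     "mtt",      mtt,         0,
    "core",     "ttp",      ttp,         0
  )
  ctprob::phantom_spec(grid_shape = c(6, 6, 4), voxel_spacing = c(4, 4, 4),
                       lesion_center = c(-8, 0, 0), core_radius = 3,
                       penumbra_radius = 6, tissue_params = tp,
                       noise_sd = noise_sd, seed = 7L)
}

# Small two-class voxel table with exact separation at a known value.
separated_table <- function() {
  tibble::tibble(
    case_id = "s",
    cbf = c(4, 6, 8, 10, 12, 14),
    cbv = c(1, 1.2, 1.4, 3, 3.2, 3.4),
    mtt = c(14, 13, 12, 5, 4.5, 4),
    ttp = c(11, 10.5, 10, 5, 4.5, 4),
    label = c(rep("ischemic", 3), rep("healthy", 3))
  )
}
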
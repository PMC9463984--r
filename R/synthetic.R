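#' Simulate multi-subject volumetric fMRI with known networks
#'
#' Generates the kind of data the two-stage model is built for: each subject
#' is a linear mixture of `k1` spatial networks (Gaussian blobs inside a 3D
#' brain-like mask) driven by temporal sources that are partly shared across
#' subjects and partly subject-specific, plus i.i.d. Gaussian noise:
#' \deqn{X_s = S_s M^T + \sigma_n E_s,\qquad
#'       S_s \propto (1-\alpha) G + \alpha U_s,}
#' where `G` holds group-shared sources, `U_s` subject-specific sources, and
#' the mixing ratio `alpha` moves the population from perfectly synchronized
#' (`alpha = 0`, all subjects identical up to noise) to fully idiosyncratic
#' (`alpha = 1`). Composite maps — sums of 2-3 primitives — model the
#' combined networks a deep layer should express, and every ingredient is
#' returned as ground truth so recovery can be scored exactly.
#'
#' Sources are moving-average-smoothed white noise (width 5 TRs, a crude
#' stand-in for hemodynamic smoothness) rectified at zero, giving the
#' transient, burst-like activations typical of stimulus-driven network
#' time courses; rectification also makes the sources super-Gaussian, so
#' the mixture is identifiable by blind decomposition (a purely Gaussian
#' source model would be recoverable only up to an arbitrary rotation).
#' Columns are standardized so `alpha` changes synchrony but not
#' amplitude.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param v time points per subject (>= 30).
#' @param grid 3D grid dimensions (default `c(12, 12, 12)`).
#' @param k1 number of primitive networks; `k3` number of composite maps
#'   (`k1 >= k3 >= 1`).
#' @param alpha subject-specific mixing ratio in \[0, 1\].
#' @param noise_sd additive noise SD (>= 0).
#' @param seed integer seed; the whole dataset is a pure function of the
#'   arguments.
#' @param blob_sigma blob radius parameter in voxels.
#' @param out_dir optional directory: writes `mask.nii`, per-subject 4D
#'   `sub-*.nii`, ground-truth TSVs and a JSON manifest (byte-identical
#'   under the same seed).
#' @return a list with `subjects` (list of [data_matrix]) and `truth`, a
#'   `ground_truth` object holding `primitive_maps` (k1 x m),
#'   `composite_maps` (k3 x m), `group_sources` (v x k1), `subject_sources`
#'   (list of v x k1), the mask and all parameters.
#' @export
make_dataset <- function(n_subjects = 8, v = 100, grid = c(12L, 12L, 12L),
                         k1 = 8, k3 = 4, alpha = 0.2, noise_sd = 0.1,
                         seed = 1L, blob_sigma = max(grid) / 8,
                         out_dir = NULL) {
  stopifnot(n_subjects >= 1, v >= 30, k1 >= k3, k3 >= 1,
            alpha >= 0, alpha <= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  mask <- default_mask(grid)
  coords <- mask_coords(mask)
  if (mask$m < 10 * k1)
    stop("capacity error: grid too small to place ", k1, " networks")

  centers <- place_centers(coords, k1, min_sep = 1.5 * blob_sigma)
  primitive_maps <- t(vapply(seq_len(k1), function(j) {
    d2 <- colSums((t(coords) - centers[j, ])^2)
    w <- exp(-d2 / (2 * blob_sigma^2))
    w[w < 0.01] <- 0
    w
  }, numeric(mask$m)))

  combos <- lapply(seq_len(k3), function(j)
    sample.int(k1, sample(2:3, 1L)))
  composite_maps <- t(vapply(combos, function(ix)
    colSums(primitive_maps[ix, , drop = FALSE]), numeric(mask$m)))

  smooth_sources <- function(n, k) {
    z <- matrix(stats::rnorm((n + 4) * k), n + 4, k)
    s <- vapply(seq_len(k), function(j)
      stats::filter(z[, j], rep(1 / 5, 5), sides = 2)[3:(n + 2)],
      numeric(n))
    # rectify: transient event-like activations (super-Gaussian), which
    # keeps the linear mixture blind-source identifiable
    scale_pop(pmax(matrix(s, n, k), 0))
  }
  group_sources <- smooth_sources(v, k1)
  subject_sources <- lapply(seq_len(n_subjects), function(s)
    smooth_sources(v, k1))

  subjects <- lapply(seq_len(n_subjects), function(s) {
    mix <- (1 - alpha) * group_sources + alpha * subject_sources[[s]]
    if (alpha > 0 && alpha < 1) mix <- scale_pop(mix)
    x <- mix %*% primitive_maps
    if (noise_sd > 0)
      x <- x + noise_sd * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
    data_matrix(x, mask, subject_id = sprintf("sub-%02d", s))
  })

  truth <- structure(
    list(primitive_maps = primitive_maps, composite_maps = composite_maps,
         combos = combos, group_sources = group_sources,
         subject_sources = subject_sources, mask = mask,
         params = list(n_subjects = n_subjects, v = v, grid = grid,
                       k1 = k1, k3 = k3, alpha = alpha,
                       noise_sd = noise_sd, seed = as.integer(seed),
                       blob_sigma = blob_sigma)),
    class = "ground_truth")

  if (!is.null(out_dir)) write_dataset(subjects, truth, out_dir)
  list(subjects = subjects, truth = truth)
}

# super-ellipsoid brain-like mask: box-shaped enough to keep most of the grid
default_mask <- function(grid) {
  grid <- as.integer(grid)
  ctr <- (grid + 1) / 2
  r <- (grid - 1) / 2
  idx <- as.matrix(expand.grid(seq_len(grid[1]), seq_len(grid[2]),
                               seq_len(grid[3])))
  u <- sweep(sweep(idx, 2L, ctr, `-`), 2L, r, `/`)
  inside <- rowSums(u^4) <= 1
  brain_mask(array(inside, grid))
}

# greedy center placement with minimum separation; capacity error if stuck
place_centers <- function(coords, k, min_sep, max_tries = 500L) {
  chosen <- matrix(NA_real_, k, 3L)
  n_ok <- 0L
  for (t in seq_len(max_tries)) {
    cand <- coords[sample.int(nrow(coords), 1L), ]
    if (n_ok == 0L ||
        min(sqrt(colSums((t(chosen[seq_len(n_ok), , drop = FALSE]) -
                            cand)^2))) >= min_sep) {
      n_ok <- n_ok + 1L
      chosen[n_ok, ] <- cand
      if (n_ok == k) return(chosen)
    }
  }
  stop("capacity error: could not place ", k,
       " network centers with separation ", min_sep)
}

# column-wise population z-scoring of a plain matrix
scale_pop <- function(x) {
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(x^2) - mu^2)
  sweep(sweep(x, 2L, mu, `-`), 2L, sd_pop, `/`)
}

write_dataset <- function(subjects, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- truth$mask
  write_mask(mask, file.path(out_dir, "mask.nii"))
  for (s in subjects)
    write_volume_series(s$values, mask,
                        file.path(out_dir, paste0(s$subject_id, ".nii")))
  utils::write.table(truth$primitive_maps,
                     file.path(out_dir, "truth_primitive_maps.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(truth$composite_maps,
                     file.path(out_dir, "truth_composite_maps.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(truth$group_sources,
                     file.path(out_dir, "truth_group_sources.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(truth$params, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate time courses with planted connectivity states
#'
#' Builds component time courses whose sliding-window correlation structure
#' cycles through a set of planted connectivity states with a fixed dwell
#' time, the standard fixture for validating k-means state recovery. Within
#' each dwell segment the series is drawn from a zero-mean Gaussian with the
#' state's correlation matrix (eigenvalue-clipped to be positive definite),
#' plus optional white noise.
#'
#' @param states list of symmetric, unit-diagonal correlation matrices
#'   (one per state; they are visited cyclically).
#' @param dwell dwell time per state in TRs; must be at least the effective
#'   window length of `cfg`.
#' @param v total number of TRs.
#' @param noise_sd white-noise SD added to the series.
#' @param seed integer seed.
#' @param cfg a [dfc_config()]; used to validate `dwell` and to compute
#'   per-window planted labels.
#' @return a list with `series` (v x k matrix), `state_per_tr` (planted
#'   state index per TR) and `window_labels` (planted state per sliding
#'   window, by dominant taper weight).
#' @export
planted_dfc_series <- function(states, dwell, v, noise_sd = 0.1, seed = 1L,
                               cfg = dfc_config()) {
  stopifnot(is.list(states), length(states) >= 1L)
  L <- taper_length(cfg)
  if (dwell < L)
    stop("configuration error: dwell (", dwell,
         ") is shorter than the window length (", L, ")")
  k <- ncol(states[[1L]])
  chols <- lapply(states, function(C) {
    stopifnot(isTRUE(all.equal(C, t(C))), all(abs(diag(C) - 1) < 1e-8))
    e <- eigen(C, symmetric = TRUE)
    lam <- pmax(e$values, 1e-6)
    Cpd <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(Cpd))
    chol(Cpd / tcrossprod(d))
  })
  set.seed(as.integer(seed))
  state_per_tr <- rep(rep_len(seq_along(states),
                              ceiling(v / dwell)), each = dwell)[seq_len(v)]
  series <- matrix(0, v, k)
  for (seg in split(seq_len(v), cumsum(c(1L, diff(state_per_tr) != 0)))) {
    st <- state_per_tr[seg[1L]]
    z <- matrix(stats::rnorm(length(seg) * k), length(seg), k)
    series[seg, ] <- z %*% chols[[st]]
  }
  if (noise_sd > 0)
    series <- series + noise_sd * matrix(stats::rnorm(length(series)), v, k)
  w <- taper_weights(cfg)
  starts <- window_starts(v, cfg)
  window_labels <- vapply(starts, function(s) {
    lab <- state_per_tr[s:(s + L - 1L)]
    as.integer(names(which.max(tapply(w, lab, sum))))
  }, integer(1))
  list(series = series, state_per_tr = state_per_tr,
       window_labels = window_labels)
}
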
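# Shared fixture builders: everything is generated in code at test time.

tiny_axis <- function(n = 100, lo = 350, hi = 3100) {
  spectral_axis(seq(lo, hi, length.out = n))
}

# A small deterministic image set for container / bookkeeping tests.
tiny_image_set <- function(n_images = 2, h = 5, w = 5, nch = 100, seed = 1) {
  set.seed(seed)
  ax <- tiny_axis(nch)
  images <- lapply(seq_len(n_images), function(i) {
    mask <- matrix(runif(h * w) > 0.3, h, w)
    if (!any(mask)) mask[1, 1] <- TRUE
    raman_image(array(rnorm(h * w * nch, 100, 10), c(h, w, nch)),
                mask, donor_id = paste0("d", (i %% 2) + 1),
                phenotype = c("M0", "M1", "M2")[(i %% 3) + 1],
                cell_id = paste0("cell", i), axis = ax)
  })
  image_set(images)
}

# Scene config scaled down for unit tests (smaller cells and images);
# the study-condition defaults stay untouched in scene_config().
small_scene_config <- function(counts = c(M0 = 2L, M1 = 3L, M2 = 2L), ...) {
  scene_config(image_size = c(24L, 24L), cell_radius = c(6, 8),
               nucleus_radius = c(2, 3.2), counts = counts, ...)
}

# A clean single-cell scene: no noise, no baseline, no spikes.
noiseless_config <- function(...) {
  small_scene_config(noise_gain = 0, baseline_amplitude = c(0, 0),
                     spike_prob = 0, donor_intensity_log_sd = 0,
                     donor_shift_channels = 0L, donor_lipid_mult = c(1, 1),
                     ...)
}

# brute-force NNLS oracle: enumerate every active set, solve the
# unconstrained subproblem, keep the feasible solution of least residual
nnls_bruteforce <- function(E, y) {
  p <- nrow(E)
  best <- list(coefficients = rep(0, p), residual = sqrt(sum(y^2)))
  for (k in seq_len(p)) {
    for (sub in utils::combn(p, k, simplify = FALSE)) {
      A <- t(E[sub, , drop = FALSE])
      cf <- solve(crossprod(A), crossprod(A, y))
      if (all(cf >= -1e-12)) {
        full <- rep(0, p); full[sub] <- pmax(cf, 0)
        res <- sqrt(sum((y - drop(full %*% E))^2))
        if (res < best$residual - 1e-12)
          best <- list(coefficients = full, residual = res)
      }
    }
  }
  best
}

expect_no_silent_channels <- function(axis) {
  wn <- as.numeric(axis)
  expect_false(any(wn > 1800 & wn < 2650))
}
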
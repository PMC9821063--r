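test_that("SNIP has the spec'd fixed points and the hand-computed clip", {
  expect_equal(snip_baseline(rep(5, 5), 3), rep(5, 5))
  expect_equal(snip_baseline(0:4, 4), 0:4)          # linear ramp unchanged
  expect_equal(snip_baseline(c(0, 0, 10, 0, 0), 1), rep(0, 5))
})

test_that("SNIP baseline is pointwise below the input and monotone in iterations", {
  set.seed(21)
  for (rep in 1:5) {
    y <- abs(rnorm(200, 50, 20)) + 30 * exp(-(seq_len(200) - 80)^2 / 50)
    prev <- y
    for (m in c(1, 5, 20, 60)) {
      b <- snip_baseline(y, m)
      expect_true(all(b <= y + 1e-12))
      expect_true(all(b <= prev + 1e-12))  # monotone in iterations
      prev <- b
    }
  }
})

test_that("baseline recovery on signal-free channels is accurate", {
  # known exponential baseline + three bands, moderate detector noise
  set.seed(7)
  ax <- seq(350, 1799, by = 3)
  n <- length(ax)
  base <- 150 * exp(-(ax - 350) / 900)
  peaks <- 300 * (exp(-(ax - 1003)^2 / 128) + 0.8 * exp(-(ax - 1444)^2 / 392) +
                    1.2 * exp(-(ax - 1655)^2 / 392))
  free <- abs(ax - 1003) > 60 & abs(ax - 1444) > 90 & abs(ax - 1655) > 90
  err <- replicate(20, {
    y <- base + peaks + rnorm(n, 0, 0.3 * sqrt(base + peaks + 1))
    b <- ramanphen:::estimate_baseline_rows(matrix(y, 1), 200L, 5L)
    stats::median(abs(b[free] - base[free]) / base[free])
  })
  expect_lt(stats::median(err), 0.05)
})

test_that("apply_mask returns exactly the masked spectra with coordinates", {
  ax <- tiny_axis(10)
  cube <- array(seq_len(3 * 3 * 10), c(3, 3, 10))
  mask <- matrix(FALSE, 3, 3)
  mask[cbind(c(1, 2, 3, 2), c(1, 2, 3, 3))] <- TRUE
  im <- raman_image(cube, mask, "d1", "M0", "c1", ax)
  m <- apply_mask(im)
  expect_equal(nrow(m$spectra), 4)
  expect_setequal(paste(m$coords[, "y"], m$coords[, "x"]),
                  c("1 1", "2 2", "3 3", "2 3"))
  # single-pixel mask returns cube[y, x, ]
  mask1 <- matrix(FALSE, 3, 3); mask1[1, 1] <- TRUE
  m1 <- apply_mask(raman_image(cube, mask1, "d1", "M0", "c1", ax))
  expect_equal(drop(m1$spectra), cube[1, 1, ])
  # all-true mask yields h*w spectra
  mall <- apply_mask(raman_image(cube, NULL, "d1", "M0", "c1", ax))
  expect_equal(nrow(mall$spectra), 9)
  expect_error(apply_mask(raman_image(cube, matrix(FALSE, 3, 3), "d1", "M0",
                                      "c1", ax)),
               "empty cell mask")
})

test_that("the despiker replaces narrow spikes and keeps broad signal", {
  cfg <- preprocess_config()
  base <- rep(100, 60)
  neighbors <- lapply(1:4, function(i) base)
  expect_equal(remove_spikes(base, neighbors, cfg), base)  # zero residual
  spiked <- base; spiked[30] <- 5000
  out <- remove_spikes(spiked, neighbors, cfg)
  expect_equal(out[30], 100)
  expect_equal(out[-30], base[-30])
  broad <- base; broad[20:39] <- 5000  # 20-channel run: treated as signal
  expect_equal(remove_spikes(broad, neighbors, cfg), broad)
})

test_that("cube despiking matches the single-spectrum operation", {
  set.seed(31)
  cfg <- preprocess_config()
  cube <- array(rnorm(4 * 4 * 50, 200, 5), c(4, 4, 50))
  cube[2, 2, 25] <- 8000
  ds <- ramanphen:::despike_cube(cube, cfg)
  # replicate-edge 4-neighborhood of pixel (2,2)
  nb <- list(cube[1, 2, ], cube[3, 2, ], cube[2, 1, ], cube[2, 3, ])
  expect_equal(ds$cube[2, 2, ], remove_spikes(cube[2, 2, ], nb, cfg))
  expect_gte(ds$n_events[2, 2], 1)
})

test_that("despiking is the identity on spike-free homogeneous scenes", {
  ax <- tiny_axis(80)
  sp <- 200 * exp(-(as.numeric(ax) - 1500)^2 / 5000)
  cube <- array(rep(sp, each = 25), c(5, 5, 80))
  ds <- ramanphen:::despike_cube(cube, preprocess_config())
  expect_identical(ds$cube, cube)
  expect_equal(sum(ds$n_events), 0)
})

test_that("preprocessing cleans a noiseless image without losses", {
  cfg <- noiseless_config()
  cfg$morphology$M0$lambda <- 0  # no lipid droplets: the outlier statistic
  # (mean SNIP floor) then has no heavy upper tail and nothing is excluded
  out <- generate_cell_image(cfg, "M0", seed = 12)
  pp <- preprocess_image(out$image)
  expect_equal(pp$report$n_excluded, 0)
  expect_equal(pp$report$n_retained, sum(out$image$mask))
  expect_true(all(pp$spectra >= 0))
  expect_no_silent_channels(pp$axis)
  # coordinates survive: the retained coordinates are the mask pixels
  expect_setequal(paste(pp$coords[, 1], pp$coords[, 2]),
                  paste(which(out$image$mask, arr.ind = TRUE)[, 1],
                        which(out$image$mask, arr.ind = TRUE)[, 2]))
})

test_that("a planted high-fluorescence spectrum is excluded as an outlier", {
  ax <- spectral_axis(seq(350, 3098, by = 3))
  v <- as.numeric(ax)
  n <- length(v)
  h <- 6; w <- 6
  set.seed(5)
  sig <- 100 * exp(-(v - 1440)^2 / 300)
  bshape <- exp(-(v - v[1]) / 900)
  cube <- array(0, c(h, w, n))
  for (y in seq_len(h)) for (x in seq_len(w))
    cube[y, x, ] <- sig + 80 * bshape + rnorm(n, 0, 2)
  cube[3, 4, ] <- sig + 100 * 80 * bshape  # 100x the fluorescence
  im <- raman_image(cube, NULL, "d1", "M0", "fluor", ax)
  pp <- preprocess_image(im)
  expect_equal(pp$report$n_excluded, 1)
  excluded <- setdiff(paste(which(matrix(TRUE, h, w), arr.ind = TRUE)[, 1],
                            which(matrix(TRUE, h, w), arr.ind = TRUE)[, 2]),
                      paste(pp$coords[, 1], pp$coords[, 2]))
  expect_equal(excluded, "3 4")
})

test_that("preprocessing a small benchmark leaves no silent-region channels", {
  bench <- generate_benchmark_set(small_scene_config(seed = 3L))
  pp <- preprocess_set(bench$images)
  expect_no_silent_channels(pp$axis)
  expect_equal(pp$report$n_retained + pp$report$n_excluded, pp$report$n_in)
  expect_true(all(pp$report$n_retained > 0))
})
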
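# Spectrum cleaning: mask application, cosmic-ray despiking, fluorescence
# outlier screening, silent-region cut, and per-region SNIP baseline removal.

#' Preprocessing configuration
#'
#' @param snip_iterations_fingerprint SNIP clipping iterations for the
#'   fingerprint region (window half-width in channels grows to this count).
#' @param snip_iterations_highwave SNIP iterations for the high-wavenumber
#'   region.
#' @param fingerprint_region,highwave_region `c(lo, hi)` in cm^-1; the two
#'   retained regions (the gap between them is the silent region that is
#'   cut out).
#' @param outlier_mad_factor A spectrum is excluded as a fluorescence
#'   outlier when its mean fingerprint SNIP baseline exceeds the in-image
#'   median of that statistic by more than this many MADs.
#' @param snip_smooth_channels Width (channels, odd) of the moving average
#'   applied to a spectrum before SNIP when estimating the baseline to be
#'   subtracted; damps the downward noise bias of iterated min-clipping.
#'   `1` disables smoothing. The [snip_baseline()] operation itself is
#'   never smoothed.
#' @param spike_zscore Robust z-score above the neighbor median at which a
#'   channel is considered part of a cosmic-ray spike.
#' @param spike_max_width Maximum contiguous width (channels) of a run that
#'   is still treated as a spike; wider runs are kept as signal.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(snip_iterations_fingerprint = 200L,
                              snip_iterations_highwave = 50L,
                              fingerprint_region = c(350, 1800),
                              highwave_region = c(2650, 3100),
                              snip_smooth_channels = 5L,
                              outlier_mad_factor = 3,
                              spike_zscore = 8,
                              spike_max_width = 3L) {
  stopifnot(snip_iterations_fingerprint >= 1L, snip_iterations_highwave >= 1L,
            outlier_mad_factor > 0, spike_zscore > 0, spike_max_width >= 1L,
            snip_smooth_channels >= 1L, snip_smooth_channels %% 2L == 1L,
            fingerprint_region[2L] <= highwave_region[1L])
  structure(list(snip_iterations_fingerprint = as.integer(snip_iterations_fingerprint),
                 snip_iterations_highwave = as.integer(snip_iterations_highwave),
                 fingerprint_region = fingerprint_region,
                 highwave_region = highwave_region,
                 snip_smooth_channels = as.integer(snip_smooth_channels),
                 outlier_mad_factor = outlier_mad_factor,
                 spike_zscore = spike_zscore,
                 spike_max_width = as.integer(spike_max_width)),
            class = "preprocess_config")
}

#' Extract the masked spectra of an image
#'
#' @param image A [raman_image()].
#' @return List with `coords` (n x 2 matrix, columns `y`, `x`, one row per
#'   mask-`TRUE` pixel) and `spectra` (n x n_channels matrix) plus the
#'   `axis`.
#' @export
apply_mask <- function(image) {
  stopifnot(inherits(image, "raman_image"))
  idx <- which(image$mask)
  if (!length(idx))
    stop(sprintf("image '%s': empty cell mask", image$cell_id), call. = FALSE)
  h <- dim(image$cube)[1L]
  coords <- cbind(y = ((idx - 1L) %% h) + 1L, x = ((idx - 1L) %/% h) + 1L)
  flat <- matrix(image$cube, h * dim(image$cube)[2L], dim(image$cube)[3L])
  list(coords = coords, spectra = flat[idx, , drop = FALSE],
       axis = image$axis)
}

#' SNIP baseline estimate
#'
#' Statistics-sensitive non-linear iterative peak clipping: with the window
#' half-width p growing from 1 to `iterations`, each channel is replaced by
#' `min(y_i, (y_{i-p} + y_{i+p}) / 2)` (simultaneous update per pass; near
#' the spectrum edges the window shrinks symmetrically to the largest valid
#' half-width, so linear and convex baselines are fixed points everywhere). The plain variant is used: no
#' log-log-sqrt pre-transform. The estimate is pointwise below the input,
#' so baseline-corrected spectra are non-negative.
#'
#' @param intensities Numeric vector (or a [spectrum()]).
#' @param iterations Number of clipping passes (window half-width in
#'   channels reached at the last pass).
#' @return Numeric baseline vector of the same length.
#' @examples
#' snip_baseline(c(0, 0, 10, 0, 0), 1)  # peak clipped to 0
#' @export
snip_baseline <- function(intensities, iterations) {
  if (inherits(intensities, "spectrum")) intensities <- intensities$intensities
  stopifnot(iterations >= 1L)
  drop(.snip_rows(matrix(as.numeric(intensities), nrow = 1L),
                  as.integer(iterations)))
}

snip_matrix <- function(Y, iterations) {
  .snip_rows(Y, as.integer(iterations))
}

# Row-wise moving average with symmetrically shrinking windows at the
# edges; k = 1 is the identity.
smooth_rows <- function(Y, k) {
  if (k <= 1L) return(Y)
  h <- (k - 1L) %/% 2L
  n <- ncol(Y)
  acc <- Y
  cnt <- rep(1, n)
  for (o in seq_len(h)) {
    l <- seq_len(n) - o; r <- seq_len(n) + o
    ok <- l >= 1L & r <= n  # shrink symmetrically
    acc[, ok] <- acc[, ok] + Y[, l[ok], drop = FALSE] + Y[, r[ok], drop = FALSE]
    cnt[ok] <- cnt[ok] + 2
  }
  sweep(acc, 2L, cnt, "/")
}

# Pipeline baseline estimator: SNIP on a lightly smoothed copy of the
# spectra, damping the downward noise bias of iterated min-clipping.
estimate_baseline_rows <- function(Y, iterations, smooth_k) {
  snip_matrix(smooth_rows(Y, smooth_k), iterations)
}

# Flag channels whose variance-stabilized positive residual
# (y - ref) / sqrt(ref + 1) exceeds z * robust sd (MAD), in contiguous runs
# no wider than max_width; returns the replacement indices. The
# stabilization accounts for shot noise growing with the signal.
spike_channels <- function(y, ref, zscore, max_width) {
  residual <- (y - ref) / sqrt(pmax(ref, 0) + 1)
  s <- max(stats::mad(residual), 1e-12)
  flag <- residual > zscore * s
  if (!any(flag)) return(integer())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths <= max_width
  unlist(lapply(which(keep), function(i) starts[i]:ends[i]), use.names = FALSE)
}

#' Remove cosmic-ray spikes from one spectrum
#'
#' A simplified despiker: channels whose intensity exceeds the per-channel
#' median of the neighboring pixels' spectra by more than
#' `spike_zscore` robust standard deviations (MAD of the residual after
#' variance stabilization by `sqrt(reference + 1)`, so that
#' signal-dependent shot noise does not trigger detections), in
#' contiguous runs at most `spike_max_width` channels wide, are replaced by
#' the neighbor median. Without neighbors the reference is a running median
#' of the spectrum itself.
#'
#' @param spectrum Numeric vector or [spectrum()].
#' @param neighbors Matrix (one neighbor spectrum per row), list of
#'   vectors/spectra, or `NULL`.
#' @param config A [preprocess_config()].
#' @return Despiked spectrum, same type as the input.
#' @export
remove_spikes <- function(spectrum, neighbors = NULL,
                          config = preprocess_config()) {
  is_sp <- inherits(spectrum, "spectrum")
  y <- if (is_sp) spectrum$intensities else as.numeric(spectrum)
  if (!is.null(neighbors)) {
    if (is.list(neighbors))
      neighbors <- do.call(rbind, lapply(neighbors, function(s)
        if (inherits(s, "spectrum")) s$intensities else as.numeric(s)))
    ref <- apply(neighbors, 2L, stats::median)
  } else {
    k <- min(7L, length(y) - (1 - length(y) %% 2))
    ref <- stats::runmed(y, k, endrule = "median")
  }
  idx <- spike_channels(y, ref, config$spike_zscore, config$spike_max_width)
  y[idx] <- ref[idx]
  if (is_sp) spectrum(y, spectrum$axis) else y
}

# Despike every pixel of a cube against the median of its 4-neighborhood
# (edges replicated). Matches remove_spikes() given the same neighbors.
# Returns the despiked cube and the number of corrected runs per pixel.
despike_cube <- function(cube, config) {
  d <- dim(cube); h <- d[1L]; w <- d[2L]; nch <- d[3L]
  up    <- cube[c(1L, seq_len(h - 1L)), , , drop = FALSE]
  down  <- cube[c(seq_len(h - 1L) + 1L, h), , , drop = FALSE]
  left  <- cube[, c(1L, seq_len(w - 1L)), , drop = FALSE]
  right <- cube[, c(seq_len(w - 1L) + 1L, w), , drop = FALSE]
  hi <- pmax(up, down); lo <- pmin(up, down)
  med <- (up + down + left + right - pmax(hi, left, right) -
            pmin(lo, left, right)) / 2
  n_events <- integer(h * w)
  flat <- matrix(cube, h * w, nch)
  medf <- matrix(med, h * w, nch)
  R <- (flat - medf) / sqrt(pmax(medf, 0) + 1)  # variance-stabilized
  # robust per-spectrum scale of the residual
  rowmed <- apply(R, 1L, stats::median)
  s <- pmax(1.4826 * apply(abs(R - rowmed), 1L, stats::median), 1e-12)
  any_hit <- which(rowSums(R > config$spike_zscore * s) > 0)
  for (px in any_hit) {
    idx <- spike_channels(flat[px, ], medf[px, ], config$spike_zscore,
                          config$spike_max_width)
    if (length(idx)) {
      flat[px, idx] <- medf[px, idx]
      n_events[px] <- n_events[px] +
        sum(diff(c(-1L, idx)) > 1L)  # count contiguous runs
    }
  }
  list(cube = array(flat, d), n_events = matrix(n_events, h, w))
}

#' Preprocess one Raman image
#'
#' Pipeline order: apply the cell mask, despike against pixel neighbors,
#' exclude fluorescence-outlier spectra, cut the silent region (keep the
#' fingerprint and high-wavenumber regions), estimate the SNIP baseline per
#' region (by default 200 iterations on the fingerprint, 50 on the
#' high-wavenumber region, counted in channels; the estimate runs on a
#' lightly smoothed copy of each spectrum, see `snip_smooth_channels`) and
#' subtract it, clamping corrected intensities at zero. The
#' outlier statistic is the mean of the fingerprint SNIP baseline computed
#' before the cut; a spectrum is excluded when it exceeds the in-image
#' median by more than `outlier_mad_factor` MADs.
#'
#' @param image A [raman_image()].
#' @param config A [preprocess_config()].
#' @return List with `cell_id`, `donor_id`, `phenotype`, `coords`
#'   (retained pixels), `spectra` (baseline-corrected, cropped axis),
#'   `axis`, and `report` (one-row data frame: spectra in, excluded,
#'   spike events corrected, retained).
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  stopifnot(inherits(image, "raman_image"))
  axis <- as.numeric(image$axis)
  idx_f <- which(axis >= config$fingerprint_region[1L] &
                   axis <= config$fingerprint_region[2L])
  idx_h <- which(axis >= config$highwave_region[1L] &
                   axis <= config$highwave_region[2L])
  if (!length(idx_f) || !length(idx_h))
    stop(sprintf("image '%s': axis does not cover the configured regions",
                 image$cell_id), call. = FALSE)

  ds <- despike_cube(image$cube, config)
  masked <- apply_mask(raman_image(ds$cube, image$mask, image$donor_id,
                                   image$phenotype, image$cell_id, image$axis))
  n_in <- nrow(masked$spectra)
  n_spikes <- sum(ds$n_events[image$mask])

  base_f <- estimate_baseline_rows(masked$spectra[, idx_f, drop = FALSE],
                                   config$snip_iterations_fingerprint,
                                   config$snip_smooth_channels)
  stat <- rowMeans(base_f)
  cut <- stats::median(stat) + config$outlier_mad_factor * stats::mad(stat)
  keep <- stat <= cut
  if (!any(keep))
    stop(sprintf("image '%s': no spectra retained after outlier exclusion",
                 image$cell_id), call. = FALSE)

  # clamp at zero: the smoothed-copy baseline estimate is not pointwise
  # below the raw spectrum at noise troughs
  sp_f <- pmax(masked$spectra[keep, idx_f, drop = FALSE] -
                 base_f[keep, , drop = FALSE], 0)
  base_h <- estimate_baseline_rows(masked$spectra[keep, idx_h, drop = FALSE],
                                   config$snip_iterations_highwave,
                                   config$snip_smooth_channels)
  sp_h <- pmax(masked$spectra[keep, idx_h, drop = FALSE] - base_h, 0)
  out_axis <- spectral_axis(axis[c(idx_f, idx_h)])
  list(cell_id = image$cell_id, donor_id = image$donor_id,
       phenotype = image$phenotype, dims = dim(image$mask),
       coords = masked$coords[keep, , drop = FALSE],
       spectra = cbind(sp_f, sp_h), axis = out_axis,
       report = data.frame(cell_id = image$cell_id, n_in = n_in,
                           n_excluded = sum(!keep), n_spikes = n_spikes,
                           n_retained = sum(keep),
                           stringsAsFactors = FALSE))
}

#' Preprocess every image of a set
#'
#' @param x A `raman_image_set`.
#' @param config A [preprocess_config()].
#' @return An object of class `"preprocessed_set"`: list with `images`
#'   (named list of [preprocess_image()] results), the shared cropped
#'   `axis`, and `report` (data frame, one row per image).
#' @export
preprocess_set <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "raman_image_set"))
  out <- lapply(x$images, preprocess_image, config = config)
  structure(list(images = out, axis = out[[1L]]$axis,
                 report = do.call(rbind, c(lapply(out, `[[`, "report"),
                                           make.row.names = FALSE))),
            class = "preprocessed_set")
}

#' @export
print.preprocessed_set <- function(x, ...) {
  cat(sprintf("<preprocessed_set> %d images, %d channels, %d spectra retained (%d excluded, %d spike events)\n",
              length(x$images), length(x$axis), sum(x$report$n_retained),
              sum(x$report$n_excluded), sum(x$report$n_spikes)))
  invisible(x)
}
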
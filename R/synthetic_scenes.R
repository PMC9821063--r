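# Synthetic macrophage scenes: elliptical cells with a nucleus, Poisson
# lipid droplets, four biochemical endmembers, donor nuisance effects,
# fluorescence baseline, shot-like noise and cosmic-ray spikes. Every image
# carries its exact ground truth for recovery testing.

COMPONENTS <- c("lipid", "protein", "nucleus", "environment")

#' Default endmember templates
#'
#' Gaussian pseudo-peak templates for the four biochemical components.
#' Band positions follow literature-typical Raman assignments for cells
#' (e.g. phenylalanine 1003, amide III 1230-1300, CH2 deformation ~1444,
#' amide I / C=C ~1655, ester C=O ~1745, CH stretches 2850-2930 cm^-1);
#' the nucleus template carries nucleic-acid bands (785, 1095, 1485,
#' 1578 cm^-1) and the environment a weak broad organic background.
#'
#' @return Named list of `endmember_template` objects
#'   (lipid, protein, nucleus, environment).
#' @export
endmember_templates <- function() {
  list(
    lipid = endmember_template("lipid", rbind(
      c(1080, 12, 0.40), c(1266, 12, 0.50), c(1302, 10, 0.70),
      c(1444, 14, 1.00), c(1655, 14, 1.20), c(1745, 12, 0.30),
      c(2850, 20, 1.20), c(2885, 22, 1.00))),
    protein = endmember_template("protein", rbind(
      c(1003, 8, 0.80), c(1240, 18, 0.50), c(1340, 16, 0.45),
      c(1450, 14, 0.70), c(1660, 16, 1.00), c(2930, 25, 1.10))),
    nucleus = endmember_template("nucleus", rbind(
      c(785, 12, 0.80), c(1095, 14, 0.60), c(1485, 13, 0.70),
      c(1578, 12, 0.65), c(1660, 16, 0.50), c(2930, 25, 0.60))),
    environment = endmember_template("environment", rbind(
      c(900, 200, 0.08), c(1600, 250, 0.06), c(2900, 150, 0.08)))
  )
}

#' Construct an endmember template
#'
#' @param name Component name.
#' @param peaks Matrix with one row per Gaussian peak and columns
#'   `center` (cm^-1), `width` (Gaussian sigma, cm^-1), `height` (>= 0).
#' @return An object of class `"endmember_template"`.
#' @export
endmember_template <- function(name, peaks) {
  peaks <- matrix(as.numeric(peaks), ncol = 3L,
                  dimnames = list(NULL, c("center", "width", "height")))
  if (nrow(peaks) && any(peaks[, "height"] < 0))
    stop("peak heights must be >= 0", call. = FALSE)
  if (nrow(peaks) && any(peaks[, "width"] <= 0))
    stop("peak widths must be > 0", call. = FALSE)
  structure(list(name = name, peaks = peaks), class = "endmember_template")
}

#' Evaluate a template on a spectral axis
#'
#' The intensity at wavenumber v is the sum over peaks of
#' `height * exp(-(v - center)^2 / (2 * width^2))`; non-negative everywhere.
#'
#' @param template An [endmember_template()].
#' @param axis A [spectral_axis()].
#' @return A [spectrum()].
#' @export
build_endmember_spectrum <- function(template, axis) {
  axis <- as_spectral_axis(axis)
  v <- as.numeric(axis)
  y <- numeric(length(v))
  pk <- template$peaks
  for (i in seq_len(nrow(pk)))
    y <- y + pk[i, "height"] * exp(-(v - pk[i, "center"])^2 / (2 * pk[i, "width"]^2))
  spectrum(y, axis)
}

#' Scene generator configuration
#'
#' Defaults define the benchmark study conditions: 3 donors with
#' (5 M0 + 10 M1 + 7 M2) cells each (66 images, mirroring a 15/32/20
#' M0/M1/M2 design at reduced scale), 32x32 px images at a 350-3100 cm^-1
#' axis in 3 cm^-1 steps (917 channels, silent region included so the
#' preprocessing cut is exercised). M1 cells are near-circular with a
#' Poisson(12) lipid-droplet count and a lipid endmember whose 1655 cm^-1
#' peak is scaled by 0.85 relative to M0/M2 (lower unsaturation); M0/M2 are
#' elongated with Poisson(4) droplets. Donor nuisance effects are a
#' lognormal intensity factor (log-sd 0.1), an integer axis shift in
#' {-1, 0, +1} channels, and a lipid-rate multiplier in 0.8-1.25.
#'
#' @param image_size `c(h, w)` in pixels.
#' @param axis_spec `c(lo, hi, step)` in cm^-1.
#' @param morphology Per-phenotype list with `eccentricity`, `lambda`
#'   (expected droplet count) and `droplet_radius` range (px).
#' @param cell_radius Range of the cell's semi-major axis (px).
#' @param nucleus_radius Range of the nucleus radius (px).
#' @param lipid_variant Scales applied to the lipid template per phenotype:
#'   `unsat_scale_M1` (1655 peak height in M1), `band1260_scale_M1`
#'   (1266 peak in M1), `ester_scale_M2` (1745 peak in M2).
#' @param donor_intensity_log_sd Log-sd of the donor intensity factor.
#' @param donor_shift_channels Possible integer axis shifts per donor.
#' @param donor_lipid_mult Range of the donor lipid-rate multiplier.
#' @param baseline_amplitude Range of the fluorescence baseline amplitude
#'   (counts); realized as a smooth spatial field across the image.
#' @param baseline_tau Exponential decay constant of the baseline (cm^-1).
#' @param intensity_scale Counts at unit abundance times unit peak height.
#' @param noise_gain Noise sd = `noise_gain * sqrt(signal + 1)`; 1 is the
#'   shot-noise limit for count data.
#' @param spike_prob Per-spectrum probability of a cosmic-ray spike.
#' @param spike_amplitude Spike amplitude range (counts).
#' @param counts Images per donor and phenotype, named `M0`, `M1`, `M2`.
#' @param n_donors Number of donors.
#' @param m2_equals_m0 If `TRUE`, M2 cells are generated with M0 morphology
#'   and M0 lipid spectrum (null scenario; labels still read M2).
#' @param seed Integer seed making the generator deterministic.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(image_size = c(32L, 32L),
                         axis_spec = c(350, 3100, 3),
                         morphology = list(
                           M0 = list(eccentricity = 0.85, lambda = 4,
                                     droplet_radius = c(1.0, 2.2)),
                           M1 = list(eccentricity = 0.35, lambda = 12,
                                     droplet_radius = c(1.0, 2.2)),
                           M2 = list(eccentricity = 0.85, lambda = 4,
                                     droplet_radius = c(1.0, 2.2))),
                         cell_radius = c(9, 13),
                         nucleus_radius = c(3, 5),
                         lipid_variant = list(unsat_scale_M1 = 0.85,
                                              band1260_scale_M1 = 1.15,
                                              ester_scale_M2 = 0.70),
                         donor_intensity_log_sd = 0.1,
                         donor_shift_channels = -1:1,
                         donor_lipid_mult = c(0.8, 1.25),
                         baseline_amplitude = c(50, 200),
                         baseline_tau = 900,
                         intensity_scale = 300,
                         noise_gain = 1,
                         spike_prob = 0.01,
                         spike_amplitude = c(500, 3000),
                         counts = c(M0 = 5L, M1 = 10L, M2 = 7L),
                         n_donors = 3L,
                         m2_equals_m0 = FALSE,
                         seed = 42L) {
  cfg <- list(image_size = as.integer(image_size), axis_spec = axis_spec,
              morphology = morphology, cell_radius = cell_radius,
              nucleus_radius = nucleus_radius, lipid_variant = lipid_variant,
              donor_intensity_log_sd = donor_intensity_log_sd,
              donor_shift_channels = donor_shift_channels,
              donor_lipid_mult = donor_lipid_mult,
              baseline_amplitude = baseline_amplitude,
              baseline_tau = baseline_tau,
              intensity_scale = intensity_scale, noise_gain = noise_gain,
              spike_prob = spike_prob, spike_amplitude = spike_amplitude,
              counts = counts, n_donors = as.integer(n_donors),
              m2_equals_m0 = isTRUE(m2_equals_m0), seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$image_size) == 2L, all(cfg$image_size >= 4L),
            length(cfg$axis_spec) == 3L, cfg$axis_spec[3L] > 0,
            cfg$noise_gain >= 0, cfg$spike_prob >= 0, cfg$spike_prob <= 1,
            cfg$intensity_scale > 0, cfg$baseline_tau > 0,
            all(cfg$counts >= 0))
  for (m in cfg$morphology)
    stopifnot(m$lambda >= 0, m$eccentricity >= 0, m$eccentricity < 1)
  invisible(cfg)
}

scene_axis <- function(config) {
  spectral_axis(seq(config$axis_spec[1L], config$axis_spec[2L],
                    by = config$axis_spec[3L]))
}

#' Per-phenotype endmember matrix used by the generator
#'
#' Rows are lipid, protein, nucleus, environment evaluated on the axis and
#' scaled to `intensity_scale` counts. The lipid row carries the phenotype
#' variant (M1: lower 1655 cm^-1 peak, higher 1266 cm^-1 peak; M2: lower
#' 1745 cm^-1 ester peak).
#'
#' @param config A [scene_config()].
#' @param phenotype `"M0"`, `"M1"` or `"M2"`.
#' @param axis Optional axis; defaults to the config's.
#' @return Matrix `4 x n_channels` with rownames the component names.
#' @export
scene_endmembers <- function(config, phenotype, axis = NULL) {
  if (is.null(axis)) axis <- scene_axis(config)
  if (config$m2_equals_m0 && phenotype == "M2") phenotype <- "M0"
  tmpl <- endmember_templates()
  lp <- tmpl$lipid$peaks
  if (phenotype == "M1") {
    lp[lp[, "center"] == 1655, "height"] <-
      lp[lp[, "center"] == 1655, "height"] * config$lipid_variant$unsat_scale_M1
    lp[lp[, "center"] == 1266, "height"] <-
      lp[lp[, "center"] == 1266, "height"] * config$lipid_variant$band1260_scale_M1
  } else if (phenotype == "M2") {
    lp[lp[, "center"] == 1745, "height"] <-
      lp[lp[, "center"] == 1745, "height"] * config$lipid_variant$ester_scale_M2
  }
  tmpl$lipid <- endmember_template("lipid", lp)
  E <- t(vapply(tmpl[COMPONENTS], function(tm)
    build_endmember_spectrum(tm, axis)$intensities, numeric(length(axis))))
  rownames(E) <- COMPONENTS
  E * config$intensity_scale
}

#' Sample donor-level nuisance effects
#'
#' @param config A [scene_config()].
#' @return List with `intensity` (lognormal factor), `shift` (integer
#'   channels) and `lipid_mult` (droplet-rate multiplier). Uses the current
#'   RNG stream.
#' @export
sample_donor_effects <- function(config) {
  list(intensity = exp(stats::rnorm(1L, 0, config$donor_intensity_log_sd)),
       shift = sample(config$donor_shift_channels, 1L),
       lipid_mult = stats::runif(1L, config$donor_lipid_mult[1L],
                                 config$donor_lipid_mult[2L]))
}

neutral_donor_effects <- function() {
  list(intensity = 1, shift = 0L, lipid_mult = 1)
}

# Shift spectra (rows of E) by k channels, replicating the edge value;
# emulates a donor-level wavenumber miscalibration.
shift_rows <- function(E, k) {
  n <- ncol(E)
  if (k == 0L) return(E)
  idx <- pmin(pmax(seq_len(n) - k, 1L), n)
  E[, idx, drop = FALSE]
}

#' Generate one synthetic cell image with ground truth
#'
#' Lays out an elliptical cell (eccentricity per phenotype), one nucleus
#' disk and Poisson-many lipid droplets; mixes the four component abundance
#' layers with the phenotype endmembers, applies the donor intensity factor
#' and axis shift, then adds an exponentially decaying fluorescence baseline
#' `A * exp(-(v - v_min) / tau)`, zero-mean Gaussian noise with
#' sd = `gain * sqrt(signal + 1)` and 1-2 channel cosmic-ray spikes.
#'
#' @param config A [scene_config()].
#' @param phenotype `"M0"`, `"M1"` or `"M2"`.
#' @param donor_id Donor identifier.
#' @param cell_id Cell identifier.
#' @param donor_effects Output of [sample_donor_effects()]; `NULL` means
#'   neutral effects (factor 1, no shift).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `image` (a [raman_image()], mask = cell region) and
#'   `truth` (class `"ground_truth_scene"`): true `abundance` (h x w x 4),
#'   `endmembers` (4 x n, exactly as mixed, including donor effects),
#'   `baseline_amplitude` (h x w), `baseline_tau`, `spikes` data frame,
#'   `n_droplets`, labels.
#' @export
generate_cell_image <- function(config, phenotype, donor_id = "d1",
                                cell_id = "cell", donor_effects = NULL,
                                seed = NULL) {
  validate_scene_config(config)
  phenotype <- match.arg(phenotype, c("M0", "M1", "M2"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(donor_effects)) donor_effects <- neutral_donor_effects()
  h <- config$image_size[1L]; w <- config$image_size[2L]
  axis <- scene_axis(config)
  nch <- length(axis)
  morph_key <- if (config$m2_equals_m0 && phenotype == "M2") "M0" else phenotype
  morph <- config$morphology[[morph_key]]

  a <- stats::runif(1L, config$cell_radius[1L], config$cell_radius[2L])
  if (2 * a > min(h, w) - 2)
    stop("cell larger than image: increase image_size or reduce cell_radius",
         call. = FALSE)
  b <- a * sqrt(1 - morph$eccentricity^2)
  theta <- stats::runif(1L, 0, pi)
  cx <- w / 2 + stats::runif(1L, -1.5, 1.5)
  cy <- h / 2 + stats::runif(1L, -1.5, 1.5)

  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  cell <- (u / a)^2 + (v / b)^2 <= 1

  abundance <- array(0, c(h, w, 4L), dimnames = list(NULL, NULL, COMPONENTS))
  abundance[, , "protein"][cell] <- stats::runif(sum(cell), 0.85, 1.15)
  abundance[, , "environment"] <- ifelse(cell, 0.1, 1)

  rn <- stats::runif(1L, config$nucleus_radius[1L], config$nucleus_radius[2L])
  nu <- stats::runif(1L, -0.3, 0.3) * a
  nv <- stats::runif(1L, -0.3, 0.3) * b
  ncx <- cx + nu * cos(theta) - nv * sin(theta)
  ncy <- cy + nu * sin(theta) + nv * cos(theta)
  dn2 <- (X - ncx)^2 + (Y - ncy)^2
  nuc <- exp(-(dn2 / rn^2)^2)
  nuc[!cell | nuc < 0.01] <- 0
  abundance[, , "nucleus"] <- 1.3 * nuc
  # chromatin displaces most of the cytoplasmic protein inside the nucleus,
  # so near-pure nucleus pixels exist (the pure-pixel premise of N-FINDR)
  abundance[, , "protein"] <- abundance[, , "protein"] * (1 - 0.9 * nuc)

  n_drop <- stats::rpois(1L, morph$lambda * donor_effects$lipid_mult)
  lip <- matrix(0, h, w)
  for (k in seq_len(n_drop)) {
    repeat {
      du <- stats::runif(1L, -a, a); dv <- stats::runif(1L, -b, b)
      if ((du / a)^2 + (dv / b)^2 <= 0.85) break
    }
    dcx <- cx + du * cos(theta) - dv * sin(theta)
    dcy <- cy + du * sin(theta) + dv * cos(theta)
    r <- stats::runif(1L, morph$droplet_radius[1L], morph$droplet_radius[2L])
    amp <- stats::runif(1L, 1.2, 2.0)
    blob <- amp * exp(-(((X - dcx)^2 + (Y - dcy)^2) / r^2)^2)
    blob[blob < 0.01] <- 0
    lip <- lip + blob
  }
  lip[!cell] <- 0
  abundance[, , "lipid"] <- lip
  # neutral-lipid droplets displace cytoplasm: protein drops towards zero
  # where the droplet profile saturates, so droplet cores are lipid-pure
  abundance[, , "protein"] <- abundance[, , "protein"] *
    (1 - 0.9 * pmin(lip / 1.2, 1))

  E <- scene_endmembers(config, phenotype, axis)
  E <- shift_rows(E, donor_effects$shift) * donor_effects$intensity

  A <- matrix(abundance, h * w, 4L)
  signal <- A %*% E  # (h*w) x nch

  # smooth fluorescence field: bilinear interpolation of a coarse 4x4 grid
  coarse <- matrix(stats::runif(16L, config$baseline_amplitude[1L],
                                config$baseline_amplitude[2L]), 4L, 4L)
  gy <- seq(1, 4, length.out = h); gx <- seq(1, 4, length.out = w)
  iy <- pmin(floor(gy), 3L); ix <- pmin(floor(gx), 3L)
  fy <- gy - iy; fx <- gx - ix
  amp_px <- matrix(0, h, w)
  for (r in seq_len(h)) {
    a <- coarse[iy[r], ix] * (1 - fx) + coarse[iy[r], ix + 1L] * fx
    b <- coarse[iy[r] + 1L, ix] * (1 - fx) + coarse[iy[r] + 1L, ix + 1L] * fx
    amp_px[r, ] <- a * (1 - fy[r]) + b * fy[r]
  }
  bshape <- exp(-(as.numeric(axis) - axis[1L]) / config$baseline_tau)
  cube_flat <- signal + as.vector(amp_px) %o% bshape

  if (config$noise_gain > 0)
    cube_flat <- cube_flat + stats::rnorm(length(cube_flat),
      sd = config$noise_gain * sqrt(pmax(cube_flat, 0) + 1))

  spikes <- data.frame(y = integer(), x = integer(), channel = integer(),
                       width = integer(), amplitude = numeric())
  if (config$spike_prob > 0) {
    hit <- which(stats::runif(h * w) < config$spike_prob)
    for (px in hit) {
      ch <- sample.int(nch - 1L, 1L)
      wd <- sample(1:2, 1L)
      amp <- stats::runif(1L, config$spike_amplitude[1L],
                          config$spike_amplitude[2L])
      cube_flat[px, ch:(ch + wd - 1L)] <-
        cube_flat[px, ch:(ch + wd - 1L)] + amp
      spikes <- rbind(spikes, data.frame(
        y = ((px - 1L) %% h) + 1L, x = ((px - 1L) %/% h) + 1L,
        channel = ch, width = wd, amplitude = amp))
    }
  }

  cube <- array(cube_flat, c(h, w, nch))
  image <- raman_image(cube, cell, donor_id, phenotype, cell_id, axis)
  truth <- structure(list(
    abundance = abundance, endmembers = E,
    baseline_amplitude = amp_px, baseline_tau = config$baseline_tau,
    spikes = spikes, n_droplets = n_drop,
    donor_id = as.character(donor_id), phenotype = phenotype,
    cell_id = as.character(cell_id)), class = "ground_truth_scene")
  list(image = image, truth = truth)
}

#' Generate the full synthetic benchmark set
#'
#' Generates `n_donors` donors, each with `counts` images per phenotype
#' (defaults: 3 donors x (5 M0 + 10 M1 + 7 M2) = 66 images). Donor effects
#' are sampled once per donor; the whole set is deterministic under
#' `config$seed`.
#'
#' @param config A [scene_config()].
#' @return List with `images` (a `raman_image_set`) and `truth` (named list
#'   of `ground_truth_scene`, parallel to the images).
#' @export
generate_benchmark_set <- function(config = scene_config()) {
  validate_scene_config(config)
  set.seed(config$seed)
  images <- list(); truth <- list()
  for (d in seq_len(config$n_donors)) {
    donor_id <- paste0("donor", d)
    eff <- sample_donor_effects(config)
    for (ph in names(config$counts)) {
      for (i in seq_len(config$counts[[ph]])) {
        cid <- sprintf("%s_%s_%02d", donor_id, ph, i)
        out <- generate_cell_image(config, ph, donor_id, cid,
                                   donor_effects = eff)
        images[[cid]] <- out$image
        truth[[cid]] <- out$truth
      }
    }
  }
  list(images = image_set(images), truth = truth)
}
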
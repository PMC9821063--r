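# Representative lipid spectra and diagnostic band-integral ratios:
# 1655/1444 unsaturation ratio, 1260/1300 acyl-chain ratio, 1740 ester band.

#' Define an integration band
#'
#' @param name Band name.
#' @param center Band center (cm^-1), inside the window.
#' @param window `c(lo, hi)` integration window (cm^-1).
#' @param background `"none"` or `"linear-endpoints"` (subtract the straight
#'   line through the window's endpoint intensities before integrating).
#' @return A list of class `"band_definition"`.
#' @export
band_definition <- function(name, center, window,
                            background = c("linear-endpoints", "none")) {
  background <- match.arg(background)
  window <- as.numeric(window)
  if (!(window[1L] < center && center < window[2L]))
    stop("band center must lie inside the window", call. = FALSE)
  structure(list(name = name, center = center, window = window,
                 background = background), class = "band_definition")
}

#' Default diagnostic bands
#'
#' Integration windows are symmetric around the canonical band centers:
#' C=C stretch 1655 (1620-1690), CH2 deformation 1444 (1410-1480),
#' 1260 (1240-1280) and 1300 (1285-1315) acyl-chain bands, and the ester
#' C=O band at 1740 (1720-1760 cm^-1); all with the linear-endpoints local
#' background rule.
#'
#' @return Named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(cc_1655 = band_definition("cc_1655", 1655, c(1620, 1690)),
       ch2_1444 = band_definition("ch2_1444", 1444, c(1410, 1480)),
       band_1260 = band_definition("band_1260", 1260, c(1240, 1280)),
       band_1300 = band_definition("band_1300", 1300, c(1285, 1315)),
       ester_1740 = band_definition("ester_1740", 1740, c(1720, 1760)))
}

#' Band integral of a spectrum
#'
#' Trapezoidal integral of the intensity over the band window (closed
#' interval on the channel grid). With the linear-endpoints rule the
#' straight line through the intensities at the window's first and last
#' retained channel is subtracted first, which makes the integral invariant
#' to any affine function of wavenumber added to the spectrum. The result
#' can be negative for pathological input and is reported as-is.
#'
#' @param spectrum A [spectrum()].
#' @param band A [band_definition()].
#' @return Integrated area (intensity x cm^-1).
#' @export
band_integral <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(band, "band_definition"))
  v <- as.numeric(spectrum$axis)
  idx <- which(v >= band$window[1L] & v <= band$window[2L])
  if (length(idx) < 2L)
    stop(sprintf("band '%s': window [%g, %g] not on the axis", band$name,
                 band$window[1L], band$window[2L]), call. = FALSE)
  x <- v[idx]
  y <- spectrum$intensities[idx]
  if (band$background == "linear-endpoints") {
    n <- length(idx)
    y <- y - (y[1L] + (y[n] - y[1L]) * (x - x[1L]) / (x[n] - x[1L]))
  }
  pracma::trapz(x, y)
}

#' Lipid unsaturation band ratio
#'
#' Ratio of the C=C stretch band integral (~1655 cm^-1, window
#' 1620-1690) to the CH2 deformation band integral (~1444 cm^-1, window
#' 1410-1480), both with the linear-endpoints background rule; a proxy for
#' the degree of unsaturation of the probed lipids. Returns `NA` when the
#' denominator is not positive.
#'
#' @param spectrum A [spectrum()].
#' @param bands List with elements `cc_1655` and `ch2_1444` (defaults from
#'   [default_bands()]).
#' @return Scalar ratio, or `NA_real_` when undefined.
#' @export
unsaturation_ratio <- function(spectrum, bands = default_bands()) {
  num <- band_integral(spectrum, bands$cc_1655)
  den <- band_integral(spectrum, bands$ch2_1444)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

#' Extract a representative lipid spectrum from an unmixed image
#'
#' Abundance-weighted mean of the preprocessed spectra over the cellular
#' pixels whose grouped lipid abundance reaches the image's `quantile`
#' quantile of that layer, with the lipid abundance itself as weight.
#'
#' @param pp_image One element of a `preprocessed_set`.
#' @param abundance The matching `abundance_map`.
#' @param quantile Abundance quantile defining the lipid-rich pixel subset.
#' @return A [spectrum()] on the preprocessed axis.
#' @export
extract_lipid_spectrum <- function(pp_image, abundance, quantile = 0.9) {
  stopifnot(inherits(abundance, "abundance_map"))
  h <- pp_image$dims[1L]
  px <- (pp_image$coords[, "x"] - 1L) * h + pp_image$coords[, "y"]
  lip <- abundance$grouped[, , "lipid"][px]
  thr <- stats::quantile(lip, quantile, names = FALSE)
  sel <- lip >= thr
  w <- lip[sel]
  if (!any(sel) || sum(w) <= 0)
    stop(sprintf("image '%s': no lipid-bearing pixel above the threshold",
                 pp_image$cell_id), call. = FALSE)
  y <- colSums(pp_image$spectra[sel, , drop = FALSE] * w) / sum(w)
  spectrum(y, pp_image$axis)
}

#' Lipid band-ratio profile table
#'
#' One row per cell: the 1655/1444 unsaturation ratio, the 1260/1300 band
#' ratio and the 1740 cm^-1 ester band integral of the cell's extracted
#' lipid spectrum, with donor and phenotype labels.
#'
#' @param pp A `preprocessed_set`.
#' @param abundances Named list of `abundance_map`s parallel to `pp$images`.
#' @param bands Band definitions (see [default_bands()]).
#' @param quantile Passed to [extract_lipid_spectrum()].
#' @return Data frame of class `"lipid_profile_table"` with columns
#'   cell_id, donor_id, phenotype, ratio_1655_1444, ratio_1260_1300,
#'   intensity_1740.
#' @export
lipid_profile_table <- function(pp, abundances, bands = default_bands(),
                                quantile = 0.9) {
  stopifnot(inherits(pp, "preprocessed_set"))
  rows <- lapply(names(pp$images), function(id) {
    im <- pp$images[[id]]
    sp <- extract_lipid_spectrum(im, abundances[[id]], quantile = quantile)
    r1300 <- band_integral(sp, bands$band_1300)
    data.frame(cell_id = id, donor_id = im$donor_id,
               phenotype = im$phenotype,
               ratio_1655_1444 = unsaturation_ratio(sp, bands),
               ratio_1260_1300 = if (is.finite(r1300) && r1300 > 0)
                 band_integral(sp, bands$band_1260) / r1300 else NA_real_,
               intensity_1740 = band_integral(sp, bands$ester_1740),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("lipid_profile_table", "data.frame")
  out
}

#' Per-phenotype summary of lipid profiles
#'
#' @param profiles A [lipid_profile_table()].
#' @return Data frame with per-phenotype mean and sd of each ratio.
#' @export
summarize_lipid_profiles <- function(profiles) {
  stats_for <- function(ph) {
    d <- profiles[profiles$phenotype == ph, ]
    data.frame(phenotype = ph, n = nrow(d),
               mean_1655_1444 = mean(d$ratio_1655_1444, na.rm = TRUE),
               sd_1655_1444 = stats::sd(d$ratio_1655_1444),
               mean_1260_1300 = mean(d$ratio_1260_1300, na.rm = TRUE),
               sd_1260_1300 = stats::sd(d$ratio_1260_1300),
               mean_1740 = mean(d$intensity_1740, na.rm = TRUE),
               sd_1740 = stats::sd(d$intensity_1740),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(lapply(intersect(c("M0", "M1", "M2"),
                                    unique(profiles$phenotype)), stats_for),
                   make.row.names = FALSE))
}
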
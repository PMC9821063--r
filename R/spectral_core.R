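#' Construct a spectral axis
#'
#' A spectral axis is the shared grid of Raman shifts (in cm^-1) on which all
#' spectra of an image set live. Wavenumbers must be finite and strictly
#' increasing; a single-channel axis is allowed so that narrow crops stay
#' representable.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1.
#' @return A numeric vector of class `"spectral_axis"`.
#' @examples
#' ax <- spectral_axis(seq(350, 3100, by = 3))
#' length(ax)
#' @export
spectral_axis <- function(wavenumbers) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 1L)
    stop("spectral axis needs at least 1 channel", call. = FALSE)
  if (!all(is.finite(wavenumbers)))
    stop("spectral axis must be finite", call. = FALSE)
  if (any(diff(wavenumbers) <= 0))
    stop("spectral axis must be strictly increasing", call. = FALSE)
  structure(wavenumbers, class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d channels, %.6g..%.6g cm-1\n",
              length(x), x[1L], x[length(x)]))
  invisible(x)
}

#' Construct a single spectrum on an axis
#'
#' @param intensities Numeric vector of intensities (detector counts,
#'   arbitrary units), one per axis channel.
#' @param axis A [spectral_axis()].
#' @return A list of class `"spectrum"` with elements `axis` and
#'   `intensities`.
#' @export
spectrum <- function(intensities, axis) {
  axis <- as_spectral_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis))
    stop("intensities length does not match axis length", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(axis = axis, intensities = intensities), class = "spectrum")
}

as_spectral_axis <- function(x) {
  if (inherits(x, "spectral_axis")) x else spectral_axis(x)
}

#' Construct a single-cell Raman image
#'
#' Bundles one cell's hyperspectral cube with its cell mask and metadata.
#' The cube is indexed `[row, col, channel]`; the mask marks cellular pixels
#' (`TRUE`) as drawn around the cell silhouette.
#'
#' @param cube Numeric array `h x w x n_channels`.
#' @param mask Logical matrix `h x w`; `TRUE` marks cellular pixels. `NULL`
#'   means all-cellular.
#' @param donor_id Donor identifier (coerced to character).
#' @param phenotype One of `"M0"`, `"M1"`, `"M2"`.
#' @param cell_id Unique cell/image identifier.
#' @param axis A [spectral_axis()] matching the cube's channel dimension.
#' @return An object of class `"raman_image"`.
#' @export
raman_image <- function(cube, mask = NULL, donor_id, phenotype, cell_id, axis) {
  axis <- as_spectral_axis(axis)
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("cube must be a 3-d array (h x w x channels)", call. = FALSE)
  d <- dim(cube)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), d[1:2]))
    stop(sprintf("image '%s': mask dims do not match cube spatial dims", cell_id),
         call. = FALSE)
  if (d[3L] != length(axis))
    stop(sprintf("image '%s': cube has %d channels but axis has %d",
                 cell_id, d[3L], length(axis)), call. = FALSE)
  phenotype <- match.arg(phenotype, c("M0", "M1", "M2"))
  structure(list(cube = cube, mask = mask,
                 donor_id = as.character(donor_id), phenotype = phenotype,
                 cell_id = as.character(cell_id), axis = axis),
            class = "raman_image")
}

#' @export
print.raman_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<raman_image> %s (donor %s, %s): %dx%d px, %d channels, %d mask px\n",
              x$cell_id, x$donor_id, x$phenotype, d[1L], d[2L], d[3L],
              sum(x$mask)))
  invisible(x)
}

#' Construct an image set sharing one spectral axis
#'
#' @param images List of [raman_image()] objects; all must share an identical
#'   axis and have unique cell ids.
#' @return An object of class `"raman_image_set"`: a list with `images` (named
#'   by cell id) and the shared `axis`.
#' @export
image_set <- function(images) {
  if (length(images)) {
    axis <- images[[1L]]$axis
    for (im in images) {
      stopifnot(inherits(im, "raman_image"))
      if (!isTRUE(all.equal(unclass(im$axis), unclass(axis), tolerance = 0)))
        stop(sprintf("image '%s' does not share the set's spectral axis",
                     im$cell_id), call. = FALSE)
    }
    ids <- vapply(images, `[[`, "", "cell_id")
    if (anyDuplicated(ids))
      stop("duplicate cell ids in image set", call. = FALSE)
    names(images) <- ids
  } else {
    axis <- NULL
  }
  structure(list(images = images, axis = axis), class = "raman_image_set")
}

#' @export
print.raman_image_set <- function(x, ...) {
  cat(sprintf("<raman_image_set> %d images", length(x$images)))
  if (length(x$images)) {
    ph <- table(vapply(x$images, `[[`, "", "phenotype"))
    cat(sprintf(", %d channels [%s]", length(x$axis),
                paste(sprintf("%s:%d", names(ph), ph), collapse = " ")))
  }
  cat("\n")
  invisible(x)
}

#' Metadata table of an image set
#'
#' @param x A `raman_image_set`.
#' @return A data.frame with one row per image: `cell_id`, `donor_id`,
#'   `phenotype`.
#' @export
set_metadata <- function(x) {
  stopifnot(inherits(x, "raman_image_set"))
  data.frame(cell_id = vapply(x$images, `[[`, "", "cell_id"),
             donor_id = vapply(x$images, `[[`, "", "donor_id"),
             phenotype = vapply(x$images, `[[`, "", "phenotype"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict the spectral axis to a union of wavenumber regions
#'
#' Keeps exactly the channels whose wavenumber falls inside one of the given
#' closed intervals; a channel sitting exactly on an interval boundary is
#' retained. Used to cut the biologically silent region (~1800-2650 cm^-1)
#' by keeping the fingerprint and high-wavenumber regions.
#'
#' @param x A `raman_image_set`, `raman_image`, or `spectrum`.
#' @param keep_regions List of `c(lo, hi)` intervals in cm^-1, sorted and
#'   non-overlapping.
#' @return Object of the same class with the reduced axis; channel order and
#'   per-channel values are preserved.
#' @examples
#' ax <- spectral_axis(seq(350, 3100, by = 50))
#' im <- raman_image(array(1, c(2, 2, length(ax))), NULL, "d1", "M0", "c1", ax)
#' cropped <- crop_axis(im, list(c(350, 1800), c(2650, 3100)))
#' range(cropped$axis)
#' @export
crop_axis <- function(x, keep_regions) {
  UseMethod("crop_axis")
}

axis_keep_index <- function(axis, keep_regions) {
  if (!length(keep_regions)) stop("keep_regions is empty", call. = FALSE)
  reg <- do.call(rbind, lapply(keep_regions, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || r[1L] > r[2L])
      stop("each keep region must be c(lo, hi) with lo <= hi", call. = FALSE)
    r
  }))
  o <- order(reg[, 1L])
  reg <- reg[o, , drop = FALSE]
  if (nrow(reg) > 1L && any(reg[-1L, 1L] <= reg[-nrow(reg), 2L]))
    stop("keep regions must be non-overlapping", call. = FALSE)
  keep <- rep(FALSE, length(axis))
  for (i in seq_len(nrow(reg)))
    keep <- keep | (axis >= reg[i, 1L] & axis <= reg[i, 2L])
  if (!any(keep)) stop("no channels retained", call. = FALSE)
  which(keep)
}

#' @export
crop_axis.spectrum <- function(x, keep_regions) {
  idx <- axis_keep_index(x$axis, keep_regions)
  spectrum(x$intensities[idx], spectral_axis(unclass(x$axis)[idx]))
}

#' @export
crop_axis.raman_image <- function(x, keep_regions) {
  idx <- axis_keep_index(x$axis, keep_regions)
  raman_image(x$cube[, , idx, drop = FALSE], x$mask, x$donor_id,
              x$phenotype, x$cell_id, spectral_axis(unclass(x$axis)[idx]))
}

#' @export
crop_axis.raman_image_set <- function(x, keep_regions) {
  image_set(lapply(x$images, crop_axis, keep_regions = keep_regions))
}
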
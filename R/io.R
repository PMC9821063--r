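# Image-set container: one directory holding a sidecar metadata YAML plus,
# per image, a long-format CSV (x, y, wavenumber, intensity) and a mask CSV
# (x, y, mask). Coordinates are 1-based (x = column, y = row). The axis is
# stored once in the metadata file and must match every image.

#' Write an image set to a long-CSV container
#'
#' Serializes a [image_set()] as a directory: `metadata.yaml` (axis, per-image
#' donor/phenotype) plus one `<cell_id>.csv` in long format
#' (`x,y,wavenumber,intensity`) and one `<cell_id>_mask.csv` per image.
#' Intensities are written with 17 significant digits so the round trip is
#' exact at double precision.
#'
#' @param x A `raman_image_set`.
#' @param path Directory to create/write into.
#' @param format Container format; only `"long_csv"` is supported.
#' @return `path`, invisibly.
#' @seealso [read_image_set()]
#' @export
write_image_set <- function(x, path, format = "long_csv") {
  stopifnot(inherits(x, "raman_image_set"))
  format <- match.arg(format, "long_csv")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop(sprintf("cannot create container directory '%s'", path), call. = FALSE)
  meta <- list(
    container = "ramanphen_long_csv",
    axis = list(units = "cm-1",
                wavenumbers = if (is.null(x$axis)) numeric()
                              else as.numeric(x$axis)),
    images = lapply(unname(x$images), function(im) {
      list(cell_id = im$cell_id, donor_id = im$donor_id,
           phenotype = im$phenotype,
           height = dim(im$cube)[1L], width = dim(im$cube)[2L])
    })
  )
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"), precision = 17L)
  old <- options(scipen = 100); on.exit(options(old))
  for (im in x$images) {
    d <- dim(im$cube)
    grid <- expand.grid(y = seq_len(d[1L]), x = seq_len(d[2L]),
                        channel = seq_len(d[3L]))
    long <- data.frame(x = grid$x, y = grid$y,
                       wavenumber = as.numeric(x$axis)[grid$channel],
                       intensity = format(as.vector(im$cube), digits = 17L,
                                          trim = TRUE))
    utils::write.csv(long, file.path(path, paste0(im$cell_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
    mg <- expand.grid(y = seq_len(d[1L]), x = seq_len(d[2L]))
    utils::write.csv(data.frame(x = mg$x, y = mg$y,
                                mask = as.integer(as.vector(im$mask))),
                     file.path(path, paste0(im$cell_id, "_mask.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an image set from a long-CSV container
#'
#' Inverse of [write_image_set()]. Every image must be on the container's
#' axis; cubes are reassembled from the long rows and validated against the
#' recorded dimensions. Images without a mask file get an all-`TRUE` mask.
#'
#' @param path Container directory.
#' @param format Container format; only `"long_csv"` is supported.
#' @return A `raman_image_set`.
#' @export
read_image_set <- function(path, format = "long_csv") {
  format <- match.arg(format, "long_csv")
  metafile <- file.path(path, "metadata.yaml")
  if (!file.exists(metafile))
    stop(sprintf("not an image-set container: missing '%s'", metafile),
         call. = FALSE)
  meta <- yaml::read_yaml(metafile)
  if (!length(meta$images)) return(image_set(list()))
  if (!length(meta$axis$wavenumbers))
    stop("container metadata has no axis", call. = FALSE)
  axis <- spectral_axis(as.numeric(meta$axis$wavenumbers))
  images <- lapply(meta$images, function(m) {
    long <- utils::read.csv(file.path(path, paste0(m$cell_id, ".csv")))
    read_long_image(long, axis, height = m$height, width = m$width,
                    donor_id = m$donor_id, phenotype = m$phenotype,
                    cell_id = m$cell_id,
                    mask_csv = file.path(path, paste0(m$cell_id, "_mask.csv")))
  })
  image_set(images)
}

# Reassemble one cube from long rows (x, y, wavenumber, intensity).
read_long_image <- function(long, axis, height, width, donor_id, phenotype,
                            cell_id, mask_csv = NULL) {
  need <- c("x", "y", "wavenumber", "intensity")
  if (!all(need %in% names(long)))
    stop(sprintf("image '%s': long CSV must have columns %s", cell_id,
                 paste(need, collapse = ", ")), call. = FALSE)
  ch <- match_channel(long$wavenumber, axis)
  if (anyNA(ch))
    stop(sprintf("image '%s': wavenumbers not on the container axis", cell_id),
         call. = FALSE)
  n_expect <- height * width * length(axis)
  if (nrow(long) != n_expect)
    stop(sprintf("image '%s': expected %d rows, found %d", cell_id,
                 n_expect, nrow(long)), call. = FALSE)
  cube <- array(NA_real_, c(height, width, length(axis)))
  cube[cbind(long$y, long$x, ch)] <- long$intensity
  if (anyNA(cube))
    stop(sprintf("image '%s': incomplete pixel/channel coverage", cell_id),
         call. = FALSE)
  mask <- NULL
  if (!is.null(mask_csv) && file.exists(mask_csv)) {
    mg <- utils::read.csv(mask_csv)
    mask <- matrix(FALSE, height, width)
    mask[cbind(mg$y, mg$x)] <- mg$mask != 0
  }
  raman_image(cube, mask, donor_id, phenotype, cell_id, axis)
}

# Tolerant wavenumber -> channel lookup (text round trips can perturb the
# last ulp of an axis value).
match_channel <- function(wn, axis) {
  idx <- findInterval(wn, as.numeric(axis) - 1e-6)
  idx[idx < 1L] <- NA_integer_
  ok <- !is.na(idx) & abs(as.numeric(axis)[idx] - wn) <= 1e-6
  idx[!ok] <- NA_integer_
  idx
}
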
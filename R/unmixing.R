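# N-FINDR endmember extraction, non-negative abundance estimation,
# endmember grouping into biochemical classes, false-color rendering and
# per-cell composition statistics.

#' Volume of a simplex given its vertices
#'
#' For p vertices in (p-1)-dimensional space,
#' `V = |det(M)| / (p-1)!` where M has columns `(1, vertex_i)`.
#'
#' @param vertices Numeric matrix, one vertex per row (p x (p-1)).
#' @return Non-negative volume.
#' @examples
#' simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' @export
simplex_volume <- function(vertices) {
  vertices <- as.matrix(vertices)
  p <- nrow(vertices)
  if (p < 2L || ncol(vertices) != p - 1L)
    stop("need p vertices in (p-1)-dimensional space", call. = FALSE)
  abs(det(rbind(1, t(vertices)))) / factorial(p - 1L)
}

#' N-FINDR endmember extraction
#'
#' Projects the spectra to (p-1) dimensions by PCA and searches for the p
#' pixels whose simplex has maximal volume: starting from a seeded random
#' selection, each current endmember is tested against every pixel and a
#' swap is accepted when it strictly increases the simplex volume
#' (determinant ratio via Cramer's rule), sweeping until a full pass makes
#' no change. The best of `restarts` runs by final volume is returned.
#'
#' @param spectra Matrix, one spectrum per row (n_pixels x n_channels).
#' @param p Number of endmembers (>= 2).
#' @param restarts Independent seeded restarts.
#' @param seed Optional integer seed.
#' @param source Optional data frame (n_pixels rows) recording where each
#'   pixel came from; subset to the winners in the result.
#' @return An object of class `"endmember_set"`: `spectra` (p x n_channels,
#'   original unprojected spectra), `indices` (selected pixel rows),
#'   `volume` (final simplex volume in the projected space), `group`
#'   (all `"unassigned"`), `source`.
#' @export
nfindr <- function(spectra, p, restarts = 10L, seed = NULL, source = NULL) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (p < 2L) stop("p must be >= 2", call. = FALSE)
  if (p > n) stop("p exceeds the number of pixels", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pc <- stats::prcomp(spectra, center = TRUE, rank. = p - 1L)
  if (pc$sdev[1L] < 1e-12) stop("zero-variance data", call. = FALSE)
  scores <- pc$x[, seq_len(p - 1L), drop = FALSE]
  Yaug <- rbind(1, t(scores))  # p x n

  best <- NULL
  for (r in seq_len(restarts)) {
    sel <- sample.int(n, p)
    M <- Yaug[, sel, drop = FALSE]
    dM <- det(M)
    tries <- 0L
    while (abs(dM) < 1e-12 && tries < 50L) {  # degenerate random start
      sel <- sample.int(n, p); M <- Yaug[, sel, drop = FALSE]
      dM <- det(M); tries <- tries + 1L
    }
    if (abs(dM) < 1e-12) next
    repeat {
      changed <- FALSE
      for (j in seq_len(p)) {
        ratios <- abs(solve(Yaug[, sel, drop = FALSE], Yaug)[j, ])
        cand <- which.max(ratios)
        if (ratios[cand] > 1 + 1e-10 && !(cand %in% sel)) {
          sel[j] <- cand
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    vol <- abs(det(Yaug[, sel, drop = FALSE])) / factorial(p - 1L)
    if (is.null(best) || vol > best$volume)
      best <- list(sel = sel, volume = vol)
  }
  if (is.null(best))
    stop("N-FINDR failed to find a non-degenerate simplex", call. = FALSE)
  structure(list(spectra = spectra[best$sel, , drop = FALSE],
                 indices = best$sel, volume = best$volume,
                 group = rep("unassigned", p),
                 source = if (!is.null(source))
                   source[best$sel, , drop = FALSE]),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> %d endmembers, %d channels, simplex volume %.4g\n",
              nrow(x$spectra), ncol(x$spectra), x$volume))
  if (any(x$group != "unassigned"))
    cat("  groups:", paste(sprintf("%s:%d", names(table(x$group)),
                                   table(x$group)), collapse = " "), "\n")
  invisible(x)
}

#' Common endmembers across selected images
#'
#' Pools the retained preprocessed spectra of the selected images and runs
#' [nfindr()] on the combined matrix, yielding one shared endmember set
#' applicable to every image of the set.
#'
#' @param pp A `preprocessed_set` (see [preprocess_set()]).
#' @param selection Character vector of cell ids to pool.
#' @param p Number of endmembers (default 15).
#' @param restarts,seed Passed to [nfindr()].
#' @return An `endmember_set` whose `source` records (cell_id, pixel row).
#' @export
common_endmembers <- function(pp, selection, p = 15L, restarts = 10L,
                              seed = NULL) {
  stopifnot(inherits(pp, "preprocessed_set"), length(selection) >= 1L)
  missing <- setdiff(selection, names(pp$images))
  if (length(missing))
    stop("selection ids not in set: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pool <- do.call(rbind, lapply(selection, function(id) pp$images[[id]]$spectra))
  src <- do.call(rbind, lapply(selection, function(id) {
    im <- pp$images[[id]]
    data.frame(cell_id = im$cell_id, y = im$coords[, "y"],
               x = im$coords[, "x"], stringsAsFactors = FALSE)
  }))
  nfindr(pool, p = p, restarts = restarts, seed = seed, source = src)
}

endmember_matrix <- function(endmembers) {
  if (inherits(endmembers, "endmember_set")) endmembers$spectra
  else as.matrix(endmembers)
}

#' Non-negative abundance estimate for one spectrum
#'
#' Solves `min || spectrum - coeffs %*% endmembers ||_2` subject to
#' `coeffs >= 0` (no sum-to-one constraint) by the Lawson-Hanson active-set
#' method.
#'
#' @param spectrum Numeric vector or [spectrum()].
#' @param endmembers An `endmember_set` or a p x n_channels matrix.
#' @return List with `coefficients` (length p, >= 0) and `residual`
#'   (attained L2 norm).
#' @export
estimate_abundances <- function(spectrum, endmembers) {
  y <- if (inherits(spectrum, "spectrum")) spectrum$intensities
       else as.numeric(spectrum)
  E <- endmember_matrix(endmembers)
  if (ncol(E) != length(y))
    stop("endmember channel dimension does not match the spectrum",
         call. = FALSE)
  fit <- .nnls_batch(t(E), matrix(y, ncol = 1L))
  list(coefficients = drop(fit$coefficients), residual = fit$residual[1L])
}

#' Assign endmembers to biochemical groups by template correlation
#'
#' Each endmember is assigned to the group (lipid, protein, nucleus,
#' environment) whose reference spectrum has the highest Pearson
#' correlation with it; manual overrides take precedence. A constant
#' endmember (undefined correlation) is assigned to environment with a
#' warning.
#'
#' @param endmembers An `endmember_set`.
#' @param references Named list of reference spectra (numeric or
#'   [spectrum()]) or a matrix with rownames; must cover the four group
#'   names and share the endmembers' axis.
#' @param manual_overrides Optional named list/vector mapping endmember
#'   index to group name, e.g. `list("3" = "nucleus")`.
#' @return The `endmember_set` with `group` filled in.
#' @export
group_endmembers <- function(endmembers, references, manual_overrides = NULL) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (is.list(references))
    references <- do.call(rbind, lapply(references, function(s)
      if (inherits(s, "spectrum")) s$intensities else as.numeric(s)))
  if (is.null(rownames(references)))
    stop("references must be named by group", call. = FALSE)
  if (ncol(references) != ncol(endmembers$spectra))
    stop("references are not on the endmembers' axis", call. = FALSE)
  groups <- character(nrow(endmembers$spectra))
  for (i in seq_along(groups)) {
    e <- endmembers$spectra[i, ]
    if (stats::sd(e) < 1e-12) {
      warning(sprintf("endmember %d is constant; assigned to environment", i))
      groups[i] <- "environment"
    } else {
      cors <- apply(references, 1L, function(r)
        if (stats::sd(r) < 1e-12) -Inf else stats::cor(e, r))
      groups[i] <- rownames(references)[which.max(cors)]
    }
  }
  if (!is.null(manual_overrides)) {
    for (k in names(manual_overrides)) {
      g <- match.arg(manual_overrides[[k]], COMPONENTS)
      groups[as.integer(k)] <- g
    }
  }
  endmembers$group <- groups
  endmembers
}

#' Unmix a preprocessed image into abundance maps
#'
#' Estimates non-negative abundances at every retained cellular pixel with
#' the shared endmember set and sums the raw coefficients per group into
#' the four-class grouped layer. Pixels outside the mask (or excluded
#' during preprocessing) are all-zero.
#'
#' @param pp_image One element of a `preprocessed_set` (see
#'   [preprocess_image()]).
#' @param endmembers A grouped `endmember_set` (see [group_endmembers()]).
#' @return Object of class `"abundance_map"`: `raw` (h x w x p), `grouped`
#'   (h x w x 4, lipid/protein/nucleus/environment), `residual` (h x w),
#'   `mask` (retained pixels), metadata.
#' @export
unmix_image <- function(pp_image, endmembers) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (any(endmembers$group == "unassigned"))
    stop("endmembers must be grouped before unmixing", call. = FALSE)
  E <- endmembers$spectra
  p <- nrow(E)
  h <- pp_image$dims[1L]; w <- pp_image$dims[2L]
  fit <- .nnls_batch(t(E), t(pp_image$spectra))
  raw <- array(0, c(h, w, p))
  grouped <- array(0, c(h, w, 4L), dimnames = list(NULL, NULL, COMPONENTS))
  residual <- matrix(0, h, w)
  mask <- matrix(FALSE, h, w)
  px <- (pp_image$coords[, "x"] - 1L) * h + pp_image$coords[, "y"]
  mask[px] <- TRUE
  for (k in seq_len(p))
    raw[, , k][px] <- fit$coefficients[k, ]
  for (g in COMPONENTS) {
    members <- which(endmembers$group == g)
    if (length(members))
      grouped[, , g][px] <- colSums(fit$coefficients[members, , drop = FALSE])
  }
  residual[px] <- fit$residual
  structure(list(raw = raw, grouped = grouped, residual = residual,
                 mask = mask, cell_id = pp_image$cell_id,
                 donor_id = pp_image$donor_id,
                 phenotype = pp_image$phenotype,
                 group = endmembers$group),
            class = "abundance_map")
}

#' @export
print.abundance_map <- function(x, ...) {
  tot <- vapply(COMPONENTS, function(g) sum(x$grouped[, , g]), 0)
  frac <- if (sum(tot) > 0) tot / sum(tot) else tot
  cat(sprintf("<abundance_map> %s (%s, donor %s): %d px",
              x$cell_id, x$phenotype, x$donor_id, sum(x$mask)))
  cat(sprintf("; fractions %s\n",
              paste(sprintf("%s %.2f", COMPONENTS, frac), collapse = ", ")))
  invisible(x)
}

#' False-color rendering of an abundance map
#'
#' Red, green and blue are proportional to the grouped lipid, protein and
#' nucleus abundances, each normalized to its image-wise 99th percentile
#' over cellular pixels and clipped to 1. Pixels outside the cell mask and
#' cellular pixels where the environment abundance dominates all three
#' components are rendered white.
#'
#' @param abundance An `abundance_map`.
#' @return Numeric array h x w x 3 in `[0, 1]`, suitable for
#'   [png::writePNG()].
#' @export
render_false_color <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_map"))
  mask <- abundance$mask
  rgb <- array(0, c(dim(mask), 3L))
  layers <- c("lipid", "protein", "nucleus")
  for (i in seq_along(layers)) {
    lay <- abundance$grouped[, , layers[i]]
    q <- stats::quantile(lay[mask], 0.99, names = FALSE)
    rgb[, , i] <- if (q > 0) pmin(lay / q, 1) else 0
  }
  env <- abundance$grouped[, , "environment"]
  cell_max <- pmax(abundance$grouped[, , "lipid"],
                   abundance$grouped[, , "protein"],
                   abundance$grouped[, , "nucleus"])
  white <- !mask | (env > cell_max & env > 0)
  for (i in 1:3) {
    ch <- rgb[, , i]
    ch[white] <- 1
    rgb[, , i] <- ch
  }
  rgb
}

#' Per-cell biochemical composition
#'
#' Fractions of the total grouped abundance over cellular pixels, per
#' class; the four fractions sum to one.
#'
#' @param abundance An `abundance_map`.
#' @return One-row data frame: cell_id, donor_id, phenotype, and the
#'   lipid/protein/nucleus/environment fractions.
#' @export
cell_composition <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_map"))
  tot <- vapply(COMPONENTS, function(g)
    sum(abundance$grouped[, , g][abundance$mask]), 0)
  if (sum(tot) <= 0)
    stop(sprintf("image '%s': total abundance is zero", abundance$cell_id),
         call. = FALSE)
  frac <- tot / sum(tot)
  out <- data.frame(cell_id = abundance$cell_id,
                    donor_id = abundance$donor_id,
                    phenotype = abundance$phenotype,
                    stringsAsFactors = FALSE)
  out[COMPONENTS] <- as.list(frac)
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null by full enumeration of all `C(n1 + n2, n1)` group splits of
#' the midranks when both samples have at most 8 observations (valid with
#' ties); otherwise the normal approximation with tie-corrected variance.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
mann_whitney_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L || n1 + n2 < 2L)
    stop("need at least one observation per group", call. = FALSE)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 8L && n2 <= 8L) {
    splits <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    2 * stats::pnorm(-abs((u_obs - mu) / sqrt(sigma2)))
  }
}

#' Within-donor comparison of lipid fractions, M1 vs M0/M2
#'
#' Two-sided Mann-Whitney U test of the per-cell lipid fraction between M1
#' cells and pooled M0/M2 cells of one donor (see [mann_whitney_test()]).
#'
#' @param compositions Data frame of [cell_composition()] rows.
#' @param donor Donor id to test within.
#' @return Two-sided p-value.
#' @export
compare_lipid_fraction <- function(compositions, donor) {
  d <- compositions[compositions$donor_id == donor, ]
  m1 <- d$lipid[d$phenotype == "M1"]
  rest <- d$lipid[d$phenotype != "M1"]
  if (length(m1) < 1L || length(rest) < 1L)
    stop(sprintf("donor '%s' needs at least one M1 and one non-M1 cell",
                 donor), call. = FALSE)
  mann_whitney_test(m1, rest)
}
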
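test_that("simplex volume matches closed forms and degenerates to zero", {
  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  # tetrahedron: independent formula |det(v2-v1, v3-v1, v4-v1)| / 3!
  set.seed(8)
  V <- matrix(rnorm(12), 4, 3)
  ref <- abs(det(t(V[-1, ]) - V[1, ])) / 6
  expect_equal(simplex_volume(V), ref)
  expect_error(simplex_volume(matrix(0, 3, 3)), "p-1")
})

test_that("nfindr recovers pure pixels planted among convex combinations", {
  set.seed(14)
  pure <- rbind(c(10, 0, 0, 2), c(0, 10, 0, 2), c(0, 0, 10, 2))
  wts <- matrix(runif(150), 50, 3)
  wts <- wts / rowSums(wts)
  # strict convex combinations, pulled towards the centroid
  mix <- 0.8 * (wts %*% pure) + 0.2 * rep(colMeans(pure), each = 50)
  X <- rbind(pure, mix)
  em <- nfindr(X, p = 3, restarts = 5, seed = 2)
  expect_setequal(em$indices, 1:3)
})

test_that("nfindr with p = 2 returns the extremes of the first principal axis", {
  set.seed(15)
  X <- matrix(rnorm(40 * 6), 40, 6)
  em <- nfindr(X, p = 2, restarts = 5, seed = 3)
  pc1 <- stats::prcomp(X, center = TRUE, rank. = 1)$x[, 1]
  expect_setequal(em$indices, c(which.min(pc1), which.max(pc1)))
})

test_that("nfindr attains the exhaustive-search optimum on small instances", {
  for (inst in 1:25) {
    set.seed(100 + inst)
    X <- matrix(rnorm(20 * 5), 20, 5)
    em <- nfindr(X, p = 3, restarts = 10, seed = inst)
    scores <- stats::prcomp(X, center = TRUE, rank. = 2)$x
    best <- max(utils::combn(20, 3, function(tr)
      simplex_volume(scores[tr, , drop = FALSE])))
    expect_equal(em$volume, best, tolerance = 1e-9)
  }
})

test_that("nfindr rejects impossible inputs", {
  expect_error(nfindr(matrix(1, 5, 3), p = 6), "exceeds")
  expect_error(nfindr(matrix(1, 10, 3), p = 3), "zero-variance")
})

test_that("non-negative abundances solve the constrained least-squares", {
  set.seed(22)
  E <- matrix(abs(rnorm(3 * 40)), 3, 40)  # 3 endmembers
  # exact member
  fit <- estimate_abundances(E[2, ], E)
  expect_equal(fit$coefficients, c(0, 1, 0), tolerance = 1e-8)
  expect_equal(fit$residual, 0, tolerance = 1e-6)
  # constructed mixture
  fit2 <- estimate_abundances(0.3 * E[1, ] + 0.7 * E[3, ], E)
  expect_equal(fit2$coefficients, c(0.3, 0, 0.7), tolerance = 1e-8)
  # anti-correlated target: all-zero solution, residual = norm
  fit3 <- estimate_abundances(-E[1, ], E)
  expect_equal(fit3$coefficients, c(0, 0, 0))
  expect_equal(fit3$residual, sqrt(sum(E[1, ]^2)))
})

test_that("the NNLS solver matches brute-force enumeration and pracma", {
  set.seed(23)
  for (i in 1:20) {
    E <- matrix(abs(rnorm(3 * 25)), 3, 25)
    y <- rnorm(25, sd = 2) + drop(runif(3, -1, 1) %*% E)
    fit <- estimate_abundances(y, E)
    oracle <- nnls_bruteforce(E, y)
    expect_equal(fit$coefficients, oracle$coefficients, tolerance = 1e-7)
    expect_equal(fit$residual, oracle$residual, tolerance = 1e-7)
    prac <- pracma::lsqnonneg(t(E), y)
    expect_equal(fit$coefficients, prac$x, tolerance = 1e-7)
  }
})

test_that("common endmembers pool images and are order-invariant", {
  bench <- generate_benchmark_set(small_scene_config(seed = 6L))
  pp <- preprocess_set(bench$images)
  ids <- names(pp$images)
  one <- common_endmembers(pp, ids[1], p = 4, seed = 9)
  direct <- nfindr(pp$images[[ids[1]]]$spectra, p = 4, seed = 9)
  expect_equal(one$volume, direct$volume)
  expect_equal(unname(one$spectra), unname(direct$spectra))
  expect_error(common_endmembers(pp, c(ids[1], "nope"), p = 4),
               "not in set")
  a <- common_endmembers(pp, ids[1:4], p = 4, seed = 11)
  b <- common_endmembers(pp, rev(ids[1:4]), p = 4, seed = 11)
  expect_equal(a$volume, b$volume, tolerance = 1e-9)
})

test_that("endmember grouping follows correlations and manual overrides", {
  ax <- tiny_axis(200)
  tmpl <- endmember_templates()
  refs <- do.call(rbind, lapply(tmpl, function(tm)
    build_endmember_spectrum(tm, ax)$intensities))
  em <- structure(list(spectra = refs[c("lipid", "nucleus"), ],
                       indices = 1:2, volume = 1,
                       group = rep("unassigned", 2), source = NULL),
                  class = "endmember_set")
  g <- group_endmembers(em, refs)
  expect_equal(g$group, c("lipid", "nucleus"))
  g2 <- group_endmembers(em, refs, manual_overrides = list("2" = "protein"))
  expect_equal(g2$group, c("lipid", "protein"))
  em$spectra[2, ] <- 7  # constant endmember: undefined correlation
  expect_warning(g3 <- group_endmembers(em, refs), "constant")
  expect_equal(g3$group[2], "environment")
})

test_that("unmixing with true endmembers reproduces the ground truth maps", {
  cfg <- noiseless_config()
  out <- generate_cell_image(cfg, "M1", seed = 19)
  pp <- preprocess_image(out$image)
  # true endmembers restricted to the retained axis, labelled by component
  keep <- match(round(as.numeric(pp$axis), 6),
                round(as.numeric(out$image$axis), 6))
  em <- structure(list(spectra = out$truth$endmembers[, keep],
                       indices = 1:4, volume = 1,
                       group = rownames(out$truth$endmembers), source = NULL),
                  class = "endmember_set")
  # disable exclusions: noiseless droplets are legitimate bright pixels
  am <- unmix_image(pp, em)
  expect_true(all(am$raw >= 0))
  # raw-to-grouped summation conserves abundance per class
  for (g in c("lipid", "protein", "nucleus", "environment")) {
    members <- which(em$group == g)
    expect_equal(am$grouped[, , g],
                 apply(am$raw[, , members, drop = FALSE], c(1, 2), sum))
  }
  # SNIP flattens the broad environment component; compare the sharp ones
  h <- dim(out$image$cube)[1]
  px <- cbind(pp$coords[, "y"], pp$coords[, "x"])
  for (g in c("lipid", "nucleus")) {
    expect_equal(am$grouped[, , g][px], out$truth$abundance[, , g][px],
                 tolerance = 0.05)
  }
})

test_that("residuals shrink pointwise when the endmember basis is extended", {
  bench <- generate_benchmark_set(small_scene_config(seed = 61L))
  pp <- preprocess_set(bench$images)
  im <- pp$images[[2]]
  set.seed(3)
  base4 <- im$spectra[sample(nrow(im$spectra), 4), ]
  extra <- im$spectra[sample(nrow(im$spectra), 11), ]
  mk <- function(S) structure(list(spectra = S, indices = seq_len(nrow(S)),
                                   volume = 1,
                                   group = rep("protein", nrow(S)),
                                   source = NULL), class = "endmember_set")
  r4 <- unmix_image(im, mk(base4))$residual
  r15 <- unmix_image(im, mk(rbind(base4, extra)))$residual
  expect_true(all(r15 <= r4 + 1e-6))
})

test_that("false-color rendering follows the color and scale conventions", {
  grouped <- array(0, c(4, 4, 4),
                   dimnames = list(NULL, NULL,
                                   c("lipid", "protein", "nucleus",
                                     "environment")))
  mask <- matrix(FALSE, 4, 4); mask[2:3, 2:3] <- TRUE
  grouped[2, 2, "lipid"] <- 5
  am <- structure(list(grouped = grouped, raw = NULL,
                       residual = matrix(0, 4, 4), mask = mask,
                       cell_id = "c", donor_id = "d", phenotype = "M1",
                       group = NULL), class = "abundance_map")
  rgb <- render_false_color(am)
  expect_equal(rgb[2, 2, ], c(1, 0, 0))          # pure lipid pixel is red
  expect_equal(rgb[1, 1, ], c(1, 1, 1))          # background is white
  expect_equal(rgb[3, 3, ], c(0, 0, 0))          # empty cellular pixel black
  am2 <- am; am2$grouped <- am2$grouped * 2      # scale invariance
  expect_equal(render_false_color(am2), rgb)
})

test_that("cell composition fractions are normalized and labelled", {
  grouped <- array(0, c(3, 3, 4),
                   dimnames = list(NULL, NULL,
                                   c("lipid", "protein", "nucleus",
                                     "environment")))
  mask <- matrix(TRUE, 3, 3)
  mk <- function(g) structure(list(grouped = g, mask = mask, cell_id = "c",
                                   donor_id = "d", phenotype = "M0"),
                              class = "abundance_map")
  only_lipid <- grouped; only_lipid[, , "lipid"] <- 1
  expect_equal(cell_composition(mk(only_lipid))$lipid, 1.0)
  uniform <- grouped + 1
  cc <- cell_composition(mk(uniform))
  expect_equal(unlist(cc[c("lipid", "protein", "nucleus", "environment")]),
               c(lipid = 0.25, protein = 0.25, nucleus = 0.25,
                 environment = 0.25))
  expect_error(cell_composition(mk(grouped)), "total abundance is zero")
})

test_that("Mann-Whitney p-values match enumeration, wilcox.test and invariances", {
  # complete separation at 3 vs 3: p = 2 / C(6,3)
  expect_equal(mann_whitney_test(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15)), 0.1)
  expect_equal(mann_whitney_test(c(1, 1, 1), c(1, 1, 1)), 1.0)
  set.seed(33)
  for (i in 1:15) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous: no ties
    expect_equal(mann_whitney_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
    perm <- sample(n1)
    expect_equal(mann_whitney_test(x[perm], y), mann_whitney_test(x, y))
  }
  # large samples: tie-corrected normal approximation
  x <- c(rnorm(20), 1, 1, 1); y <- c(rnorm(20, 0.7), 1, 1)
  expect_equal(mann_whitney_test(x, y),
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = FALSE)$p.value)
})

test_that("within-donor lipid comparison needs both groups", {
  comp <- data.frame(donor_id = c("d1", "d1", "d1", "d2"),
                     phenotype = c("M1", "M0", "M2", "M0"),
                     lipid = c(0.4, 0.1, 0.2, 0.1))
  expect_type(compare_lipid_fraction(comp, "d1"), "double")
  expect_error(compare_lipid_fraction(comp, "d2"), "at least one M1")
})
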
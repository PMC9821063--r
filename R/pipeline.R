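# End-to-end orchestration: simulate (or load) -> preprocess -> common
# endmembers -> group -> unmix -> false-color render -> lipid profiles ->
# feature tables -> leave-one-donor-out CV for both discrimination tasks.

#' Pipeline configuration
#'
#' Exactly one of `scene` (generate a synthetic benchmark) or `input_path`
#' (read an existing long-CSV container) must be given. The global `seed`
#' fans out deterministically to the stages: the scene generator uses
#' `seed` and N-FINDR uses `seed + 1000`, so stages can be rerun in
#' isolation reproducibly.
#'
#' @param scene A [scene_config()] or `NULL`.
#' @param input_path Container directory for [read_image_set()] or `NULL`.
#' @param preprocess A [preprocess_config()].
#' @param unmix List with `p` (endmember count, default 15), `restarts`,
#'   `selection` (cell ids pooled for common endmembers; `NULL` picks a
#'   balanced 20-image subset: 7 M0, 6 M1, 7 M2 spread over donors),
#'   `overrides` (manual group overrides).
#' @param bands Band definitions (see [default_bands()]).
#' @param classifier List with `n_components`, `tasks`, `mode`.
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scene = scene_config(), input_path = NULL,
                            preprocess = preprocess_config(),
                            unmix = list(p = 15L, restarts = 10L,
                                         selection = NULL, overrides = NULL),
                            bands = default_bands(),
                            classifier = list(n_components = 2L,
                                              tasks = c("M1_vs_rest",
                                                        "M0_vs_M2"),
                                              mode = "per_image"),
                            out_dir = tempfile("ramanphen_run_"),
                            seed = 42L) {
  if (is.null(scene) == is.null(input_path))
    stop("exactly one of 'scene' and 'input_path' must be given",
         call. = FALSE)
  if (is.null(unmix$p)) unmix$p <- 15L
  if (is.null(unmix$restarts)) unmix$restarts <- 10L
  if (is.null(classifier$n_components)) classifier$n_components <- 2L
  if (is.null(classifier$tasks)) classifier$tasks <- c("M1_vs_rest",
                                                       "M0_vs_M2")
  if (is.null(classifier$mode)) classifier$mode <- "per_image"
  structure(list(scene = scene, input_path = input_path,
                 preprocess = preprocess, unmix = unmix, bands = bands,
                 classifier = classifier, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Balanced image subset for the common-endmember pool
#'
#' Picks a phenotype-balanced subset (default 7 M0, 6 M1, 7 M2 — 20
#' images), taking cells round-robin across donors, as the pool on which
#' shared endmembers are computed.
#'
#' @param metadata A [set_metadata()] data frame.
#' @param counts Named image counts per phenotype.
#' @return Character vector of cell ids.
#' @export
select_balanced <- function(metadata, counts = c(M0 = 7L, M1 = 6L, M2 = 7L)) {
  picks <- character()
  for (ph in names(counts)) {
    d <- metadata[metadata$phenotype == ph, ]
    if (!nrow(d)) next
    d <- d[order(ave(seq_len(nrow(d)), d$donor_id, FUN = seq_along),
                 d$donor_id), ]
    picks <- c(picks, utils::head(d$cell_id, counts[[ph]]))
  }
  picks
}

cv_report_json <- function(report) {
  list(task = report$task, positive = report$positive,
       n_components = report$n_components,
       metrics = report$metrics,
       predictions = report$predictions,
       coefficient_cosine = as.matrix(report$cosine))
}

#' Run the full phenotyping pipeline
#'
#' Executes every stage in order and writes all artifacts into
#' `config$out_dir`: preprocessing report CSV, endmember spectra CSV,
#' false-color PNG per cell, composition CSV with per-donor lipid-fraction
#' p-values, lipid profile CSV with per-phenotype summary, and one CV JSON
#' per discrimination task. Identical config and seed reproduce identical
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list with config hash, stage timings and
#'   output paths), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(); timings <- list()
  manifest_path <- file.path(config$out_dir, "manifest.json")
  stage <- function(name, fun) {
    t0 <- proc.time()[[3L]]
    res <- tryCatch(fun(), error = function(e) {
      jsonlite::write_json(list(status = "FAILED", stage = name,
                                error = conditionMessage(e),
                                outputs = paths),
                           manifest_path, auto_unbox = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[[3L]] - t0
    res
  }

  message("[simulate] preparing image set")
  images <- stage("simulate", function() {
    if (!is.null(config$input_path)) {
      read_image_set(config$input_path)
    } else {
      sc <- config$scene
      sc$seed <- config$seed
      generate_benchmark_set(sc)$images
    }
  })

  message(sprintf("[preprocess] %d images", length(images$images)))
  pp <- stage("preprocess", function() preprocess_set(images,
                                                      config$preprocess))
  paths$preprocess_report <- file.path(config$out_dir,
                                       "preprocess_report.csv")
  utils::write.csv(pp$report, paths$preprocess_report, row.names = FALSE)

  message("[unmix] common endmembers")
  em <- stage("endmembers", function() {
    sel <- config$unmix$selection
    if (is.null(sel)) sel <- select_balanced(set_metadata(images))
    em <- common_endmembers(pp, sel, p = config$unmix$p,
                            restarts = config$unmix$restarts,
                            seed = config$seed + 1000L)
    refs <- do.call(rbind, lapply(endmember_templates()[COMPONENTS],
      function(tm) build_endmember_spectrum(tm, pp$axis)$intensities))
    rownames(refs) <- COMPONENTS
    group_endmembers(em, refs, config$unmix$overrides)
  })
  paths$endmembers <- file.path(config$out_dir, "endmembers.csv")
  emdf <- data.frame(endmember = seq_along(em$group), group = em$group,
                     as.data.frame(em$spectra))
  colnames(emdf)[-(1:2)] <- as.character(as.numeric(pp$axis))
  utils::write.csv(emdf, paths$endmembers, row.names = FALSE)

  message("[unmix] abundance maps")
  maps <- stage("unmix", function()
    lapply(pp$images, unmix_image, endmembers = em))
  png_dir <- file.path(config$out_dir, "false_color")
  dir.create(png_dir, showWarnings = FALSE)
  for (id in names(maps)) {
    f <- file.path(png_dir, paste0(id, ".png"))
    png::writePNG(render_false_color(maps[[id]]), f)
    paths$false_color <- png_dir
  }

  message("[compose] cell compositions")
  comp <- stage("composition", function()
    do.call(rbind, c(lapply(maps, cell_composition),
                     make.row.names = FALSE)))
  paths$composition <- file.path(config$out_dir, "composition.csv")
  utils::write.csv(comp, paths$composition, row.names = FALSE)
  pvals <- stage("lipid_tests", function() {
    donors <- sort(unique(comp$donor_id))
    ok <- vapply(donors, function(d) {
      dd <- comp[comp$donor_id == d, ]
      any(dd$phenotype == "M1") && any(dd$phenotype != "M1")
    }, TRUE)
    data.frame(donor_id = donors[ok],
               p_value = vapply(donors[ok], function(d)
                 compare_lipid_fraction(comp, d), 0))
  })
  paths$lipid_pvalues <- file.path(config$out_dir, "lipid_pvalues.csv")
  utils::write.csv(pvals, paths$lipid_pvalues, row.names = FALSE)

  message("[lipids] band-ratio profiles")
  profiles <- stage("lipid_profiles", function()
    lipid_profile_table(pp, maps, bands = config$bands))
  paths$lipid_profiles <- file.path(config$out_dir, "lipid_profiles.csv")
  utils::write.csv(profiles, paths$lipid_profiles, row.names = FALSE)
  paths$lipid_summary <- file.path(config$out_dir, "lipid_summary.csv")
  utils::write.csv(summarize_lipid_profiles(profiles), paths$lipid_summary,
                   row.names = FALSE)

  message("[classify] leave-one-donor-out CV")
  reports <- list()
  for (task in config$classifier$tasks) {
    reports[[task]] <- stage(paste0("cv_", task), function() {
      table <- build_feature_table(pp, mode = config$classifier$mode)
      lodo_cv(table, n_components = config$classifier$n_components,
              task = task)
    })
    f <- file.path(config$out_dir, paste0("cv_", task, ".json"))
    jsonlite::write_json(cv_report_json(reports[[task]]), f,
                         auto_unbox = TRUE, digits = NA)
    paths[[paste0("cv_", task)]] <- f
    g <- file.path(config$out_dir, paste0("predictions_", task, ".csv"))
    utils::write.csv(reports[[task]]$predictions, g, row.names = FALSE)
    paths[[paste0("predictions_", task)]] <- g
    h <- file.path(config$out_dir, paste0("coefficients_", task, ".csv"))
    utils::write.csv(data.frame(wavenumber = as.numeric(reports[[task]]$axis),
                                t(reports[[task]]$coefficients)),
                     h, row.names = FALSE)
    paths[[paste0("coefficients_", task)]] <- h
  }

  cfg_yaml <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_yaml)
  manifest <- list(status = "OK",
                   config_hash = unname(tools::md5sum(cfg_yaml)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("ramanphen")),
                   timings = timings, outputs = paths)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  manifest$reports <- reports
  manifest$composition <- comp
  manifest$lipid_profiles <- profiles
  manifest$lipid_pvalues <- pvals
  invisible(manifest)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `scene`,
#' `input_path`, `preprocess`, `unmix`, `bands`, `classifier`, `out_dir`,
#' `seed`; `scene` and `preprocess` entries are passed to [scene_config()]
#' and [preprocess_config()], band entries to [band_definition()]. Missing
#' keys take the package defaults.
#'
#' @param path YAML file.
#' @param out_dir,seed Optional overrides of the file's values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$input_path)) {
    args$scene <- NULL
    args$input_path <- y$input_path
  } else if (!is.null(y$scene)) {
    sc <- y$scene
    for (nm in c("image_size", "counts"))
      if (!is.null(sc[[nm]])) sc[[nm]] <- unlist(sc[[nm]])
    if (!is.null(sc$counts) && is.null(names(sc$counts)))
      names(sc$counts) <- c("M0", "M1", "M2")
    args$scene <- do.call(scene_config, sc)
  }
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$unmix)) args$unmix <- y$unmix
  if (!is.null(y$bands))
    args$bands <- lapply(y$bands, function(b)
      band_definition(b$name, b$center, unlist(b$window),
                      if (is.null(b$background)) "linear-endpoints"
                      else b$background))
  if (!is.null(y$classifier)) args$classifier <- y$classifier
  if (!is.null(out_dir)) args$out_dir <- out_dir
  else if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(seed)) args$seed <- seed
  else if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipeline_config, args)
}

# Config as plain lists for YAML serialization; named atomic vectors
# become maps so their names survive the round trip.
serialize_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, "band_definition")) return(lapply(unclass(x), strip))
    if (is.list(x)) return(lapply(x, strip))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  lapply(unclass(config), strip)
}
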
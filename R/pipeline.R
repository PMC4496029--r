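# End-to-end pipeline: simulate -> preprocess -> (tune) -> fit -> classify
# -> contextual filter -> crown objects -> evaluate, with every artifact and
# seed recorded in a run-metadata JSON.

#' Default pipeline configuration
#'
#' A nested list with one section per stage. Every stochastic stage carries
#' an explicit seed derived from the master `seed`; [run_pipeline()] refuses
#' configs with missing seeds before doing any work. The defaults run the
#' package's reference synthetic conditions at desk scale: the default
#' [scene_config()] scene, a 4,000-pixel pseudo-outlier pool, fixed detector
#' parameters (obtained by running [tune_biased()] on these conditions; see
#' the package vignette), 5-fold crown-level CV, majority-rule contextual
#' filtering and the 10-pixel object-size rule.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param ... replacements for top-level sections (`scene`, `mask`,
#'   `pseudo`, `detector`, `tiebreaker`, `cv`, `filter`, `compare`).
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1, ...) {
  cfg <- list(
    scene = scene_config(seed = derive_seed(seed, "scene_cfg")),
    mask = mask_config(),
    pseudo = list(n_pixels = 4000, seed = derive_seed(seed, "pseudo_cfg")),
    detector = list(gamma = exp(-5), cost = exp(8), weight = 0.4,
                    tune = FALSE, tune_seed = derive_seed(seed, "tune_cfg")),
    tiebreaker = list(gamma = exp(-5), cost = exp(8),
                      seed = derive_seed(seed, "tb_cfg")),
    cv = list(k = 5, seed = derive_seed(seed, "cv_cfg")),
    filter = list(rule = "majority", min_size = 10),
    seed = seed)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

# Schema check: required sections and seeds must exist before any compute.
validate_run_config <- function(cfg) {
  for (sec in c("scene", "mask", "pseudo", "detector", "tiebreaker",
                "cv", "filter"))
    if (is.null(cfg[[sec]]))
      stop(sprintf("run config is missing the '%s' section", sec),
           call. = FALSE)
  seeds <- list(scene = cfg$scene$seed, pseudo = cfg$pseudo$seed,
                tiebreaker = cfg$tiebreaker$seed, cv = cfg$cv$seed,
                master = cfg$seed)
  missing <- names(seeds)[vapply(seeds, is.null, logical(1))]
  if (length(missing))
    stop(sprintf("run config is missing seeds for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the corresponding fields of
#' [default_run_config()]; the `scene` section is passed to [scene_config()]
#' and `mask` to [mask_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  cfg <- default_run_config(seed = seed)
  if (!is.null(y$scene)) cfg$scene <- do.call(scene_config, y$scene)
  if (!is.null(y$mask)) cfg$mask <- do.call(mask_config, y$mask)
  for (sec in c("pseudo", "detector", "tiebreaker", "cv", "filter"))
    for (nm in names(y[[sec]])) cfg[[sec]][[nm]] <- y[[sec]][[nm]]
  cfg
}

#' Run the full detection-and-mapping pipeline
#'
#' Executes simulate, preprocess, detector fitting (optionally tuning),
#' crown-level CV, image classification, contextual filtering, crown-object
#' extraction and truth validation, writing every artifact plus a
#' `run_metadata.json` (config echo, seeds, assignment fractions, tie-break
#' usage, filter reductions, accuracies, artifact digests) to `out_dir`.
#' Identical configs produce identical artifacts.
#'
#' @param config a `run_config` from [default_run_config()] /
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`cv`, `map`,
#'   `summary`, `validation`, `objects`, paths and metadata).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  grid <- stage("grid", build_band_grid())
  lib <- stage("simulate", make_spectral_library(config$scene, grid))
  scene <- stage("simulate", generate_scene(config$scene, lib))
  stage("simulate", {
    write_envi_cube(scene$cube, p("scene.dat"))
    write_crown_map(scene$map, p("crowns.dat"))
  })

  mask <- stage("preprocess", vegetation_mask(scene$cube, config$mask))
  dataset <- stage("preprocess",
                   extract_crown_pixels(scene$cube, scene$map, mask))
  stage("preprocess", {
    write_envi_raster(mask * 1L, p("mask.dat"))
    write_pixel_dataset(dataset, p("crown_pixels.csv"))
  })

  pseudo <- stage("pseudo", sample_pseudo_outliers(
    scene$cube, mask, n = config$pseudo$n_pixels, seed = config$pseudo$seed))

  focal_species <- seq_len(config$scene$n_focal_species)
  det_cfg <- config$detector
  params <- detector_params(det_cfg$gamma, det_cfg$cost, det_cfg$weight)
  if (isTRUE(det_cfg$tune)) {
    focal_all <- subset_pixels(dataset, dataset$species %in% focal_species)
    tuned <- lapply(focal_species, function(s) {
      fs <- subset_pixels(dataset, dataset$species == s)
      cs <- crown_summary(fs)
      folds <- crown_folds(cs, k = config$cv$k, seed = det_cfg$tune_seed,
                           strata = rep("focal", nrow(cs)))
      tune_biased(fs, pseudo, folds, seed = det_cfg$tune_seed)
    })
    params_list <- lapply(tuned, `[[`, "best_params")
  } else {
    params_list <- list(params)
  }
  tb_params <- detector_params(config$tiebreaker$gamma, config$tiebreaker$cost)

  cv <- stage("cv", multi_species_cv(
    dataset, pseudo, focal_species, params_list, tb_params,
    k = config$cv$k, seed = config$cv$seed))

  model <- stage("fit", fit_multispecies(
    subset_pixels(dataset, dataset$species %in% focal_species),
    pseudo, params_list, tb_params, seed = config$tiebreaker$seed))

  map <- stage("classify", classify_image(scene$cube, mask, model))
  stage("classify", write_envi_raster(map$labels, p("labels_raw.dat")))

  filtered <- stage("filter",
                    apply_contextual_filter(map$labels, config$filter$rule))
  objects <- stage("objects",
                   extract_objects(filtered, config$filter$min_size))
  stage("objects", {
    write_envi_raster(filtered, p("labels_filtered.dat"))
    write_envi_raster(objects$object_raster, p("objects.dat"))
    utils::write.csv(as.data.frame(objects$table), p("crown_objects.csv"),
                     row.names = FALSE)
  })

  summary <- stage("evaluate",
                   map_summary(map$labels, filtered, objects$table, mask))
  validation <- stage("evaluate", validate_objects(objects, scene$map))
  stage("evaluate", {
    utils::write.csv(summary, p("map_summary.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(validation), p("validation.csv"),
                     row.names = FALSE)
  })

  artifacts <- list.files(out_dir, full.names = TRUE)
  meta <- list(
    seeds = list(master = config$seed, scene = config$scene$seed,
                 pseudo = config$pseudo$seed, cv = config$cv$seed,
                 tiebreaker = config$tiebreaker$seed),
    n_vegetation_pixels = sum(mask),
    assignment = map$meta,
    producer_accuracy = as.list(cv$producer_accuracy),
    filter = list(n_conflicts = attr(filtered, "n_conflicts")),
    map_summary = summary,
    validation = as.data.frame(validation),
    digests = as.list(tools::md5sum(sort(artifacts))))
  jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(library = lib, scene = scene, mask = mask,
                 dataset = dataset, pseudo = pseudo, params_list = params_list,
                 cv = cv, model = model, map = map, filtered = filtered,
                 objects = objects, summary = summary,
                 validation = validation, meta = meta, out_dir = out_dir))
}
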
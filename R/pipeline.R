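#' Run the end-to-end analysis pipeline from a config
#'
#' Orchestrates the workflow stages in dependency order -- `synth`
#' (landscape + community + reflectance cube), `spectral` (spectral
#' species and gridded community), `terrain` (per-cell environment),
#' `stats` (Bray-Curtis and Mantel correlogram), `gdm` (deviance
#' partition), `simulate` (one neutral census) and `infer` (parameter
#' sweep and spline match) -- writing plain-text outputs to
#' `config$output_dir` and returning a run manifest with content digests.
#' Every stage draws its seed deterministically from the master seed, so
#' re-running an identical config reproduces identical digests.
#'
#' @param config a named list or the path to a YAML file. Recognised
#'   fields: `output_dir`, `seed`, `stages` (subset of the stage names
#'   above, empty for a manifest-only run) and per-stage parameter blocks
#'   (`landscape`, `community`, `cube`, `spectral`, `gdm`, `simulate`,
#'   `infer`).
#' @return object of class `run_manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  all_stages <- c("synth", "spectral", "terrain", "stats", "gdm",
                  "simulate", "infer")
  stages <- config$stages %||% character(0)
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("config$stages: unknown stage(s) ", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  deps <- list(spectral = "synth", terrain = "synth",
               stats = "spectral", gdm = c("stats", "terrain"),
               simulate = "synth", infer = c("simulate", "gdm"))
  for (s in stages) {
    miss <- setdiff(deps[[s]] %||% character(0), stages)
    if (length(miss))
      stop("config$stages: stage '", s, "' requires ",
           paste(miss, collapse = ", "))
  }

  state <- new.env(parent = emptyenv())
  manifest <- list(package_version = as.character(utils::packageVersion(
                     "betascape")),
                   config_hash = rlang::hash(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   master_seed = seed, stages = list())
  emit <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      seed = child_seed(seed, match(stage, all_stages)),
      outputs = lapply(files, function(f)
        rlang::hash(readBin(f, "raw", file.size(f)))))
  }

  for (stage in stages) {
    s_seed <- child_seed(seed, match(stage, all_stages))
    files <- switch(stage,
      synth = stage_synth(config, state, s_seed, out_dir),
      spectral = stage_spectral(config, state, s_seed, out_dir),
      terrain = stage_terrain(state, out_dir),
      stats = stage_stats(state, s_seed, out_dir),
      gdm = stage_gdm(config, state, out_dir),
      simulate = stage_simulate(config, state, s_seed, out_dir),
      infer = stage_infer(config, state, s_seed, out_dir))
    emit(stage, files)
  }

  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> betascape ", x$package_version, ", config ",
      substr(x$config_hash, 1, 8), ", stages: ",
      paste(names(x$stages), collapse = ", "), "\n", sep = "")
  invisible(x)
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  path
}

stage_synth <- function(config, state, seed, out_dir) {
  lc <- config$landscape %||% list()
  cc <- config$community %||% list()
  cu <- config$cube %||% list()
  state$landscape <- gen_landscape(
    width = lc$width %||% 30, height = lc$height %||% 30,
    n_types = lc$n_types %||% 3,
    autocorr_range = lc$autocorr_range %||% 10,
    cell_size = lc$cell_size %||% 100, seed = seed)
  state$truth <- gen_community(
    state$landscape, n_species = cc$n_species %||% 20,
    niche_strength = cc$niche_strength %||% 2,
    aggregation = cc$aggregation %||% 2,
    px_per_cell = cc$px_per_cell %||% 4, seed = child_seed(seed, 1))
  spectra <- gen_spectra(cc$n_species %||% 20, seed = child_seed(seed, 2))
  state$cube <- gen_cube(state$truth, spectra,
                         noise_sd = cu$noise_sd %||% 0.01,
                         invalid_fraction = cu$invalid_fraction %||% 0.05,
                         seed = child_seed(seed, 3))
  c(write_matrix_csv(state$landscape$forest_type,
                     file.path(out_dir, "forest_type.csv")),
    write_matrix_csv(state$landscape$covariates$elevation,
                     file.path(out_dir, "elevation.csv")),
    write_matrix_csv(state$truth$species_raster,
                     file.path(out_dir, "true_species.csv")))
}

stage_spectral <- function(config, state, seed, out_dir) {
  sp <- config$spectral %||% list()
  res <- spectral_species(state$cube, k = sp$k %||% 25, seed = seed,
                          cell_size = state$landscape$cell_size,
                          min_coverage = sp$min_coverage %||% 0.25)
  state$spectral <- res
  f <- file.path(out_dir, "spectral_community.csv")
  utils::write.csv(as.data.frame(res$community), f, row.names = FALSE)
  f
}

stage_terrain <- function(state, out_dir) {
  state$env <- cell_environment(state$landscape)
  f <- file.path(out_dir, "cell_environment.csv")
  utils::write.csv(state$env, f, row.names = FALSE)
  f
}

stage_stats <- function(state, seed, out_dir) {
  comm <- state$spectral$community
  state$d <- bray_curtis(comm)
  cg <- mantel_correlogram(state$d, n_boot = 100, seed = seed)
  f <- file.path(out_dir, "correlogram.csv")
  utils::write.csv(as.data.frame(cg), f, row.names = FALSE)
  f
}

stage_gdm <- function(config, state, out_dir) {
  idx <- as.integer(sub("cell_", "", state$spectral$community$ids))
  env <- state$env[idx, c("elevation", "tri", "tch", "forest_type")]
  pairs <- build_site_pairs(state$d, env,
                            coords = state$spectral$community$coords)
  preds <- config$gdm$predictors %||% c("elevation", "tri", "tch")
  state$partition <- gdm_partition(pairs, env_predictors = preds)
  f <- file.path(out_dir, "partition.json")
  jsonlite::write_json(state$partition[c("D", "E", "DxE", "unexplained",
                                         "full")],
                       f, auto_unbox = TRUE, digits = NA)
  f2 <- file.path(out_dir, "distance_splines.csv")
  utils::write.csv(
    data.frame(x = state$partition$spline_d_only$x,
               d_only = state$partition$spline_d_only$y,
               d_plus_dxe = state$partition$spline_d_plus_dxe$y),
    f2, row.names = FALSE)
  c(f, f2)
}

stage_simulate <- function(config, state, seed, out_dir) {
  sm <- config$simulate %||% list()
  kernel <- dispersal_kernel(sm$sigma %||% 3, sm$tau %||% 5)
  cfg <- sim_config(state$landscape, nu = sm$nu %||% 0.01, kernel,
                    m = sm$m %||% 1, mode = sm$mode %||% "naive",
                    seed = seed)
  state$census <- coalescent_census(cfg)
  f <- file.path(out_dir, "census.csv")
  utils::write.csv(as.data.frame(state$census), f, row.names = FALSE)
  f
}

stage_infer <- function(config, state, seed, out_dir) {
  inf <- config$infer %||% list()
  grid <- expand.grid(sigma = inf$sigma %||% c(2, 4, 8),
                      tau = inf$tau %||% 5,
                      nu = inf$nu %||% c(0.005, 0.02))
  sweep <- sweep_splines(grid, state$landscape, seed = seed)
  target_comm <- census_to_community(state$census)
  target <- community_spline(target_comm, sweep$eval_grid)
  match <- match_splines(target, sweep)
  state$match <- match
  f <- file.path(out_dir, "spline_match.json")
  jsonlite::write_json(list(best = as.list(match$best),
                            scores = match$scores),
                       f, auto_unbox = TRUE, digits = NA)
  f
}
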
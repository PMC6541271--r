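#' Default end-to-end run configuration
#'
#' A single flat configuration with one section per stage, each carrying
#' its own explicit seed. Round-trips losslessly through YAML.
#'
#' @param out_dir Output root for all artifacts.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("cropdistill_run_")) {
  structure(list(
    weather = list(n_grids = 10L, n_years = 10L,
                   lat_min = 31, lat_max = 43,
                   scenario_weights = list(baseline = 0.55,
                                           cool_summer = 0.2,
                                           heat_anthesis = 0.2,
                                           cold_region = 0.05),
                   seed = 101L, write_csv = FALSE),
    cultivar = list(file = NULL),
    corpus = list(noise = 0.001, train_fraction = 0.75, seed = 202L),
    train = list(hidden = 64L, lr = 1e-3, batch_size = 128L,
                 max_epochs = 30L, patience = 10L, seed = 303L),
    saliency = list(n = 500L, percentile = 10, seed = 404L,
                    cases = list("all", "low_h_gammaH", "low_h_gammaL")),
    out_dir = out_dir
  ), class = "run_config")
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (sec in names(base)) {
    if (is.list(base[[sec]]) && !is.null(cfg[[sec]])) {
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else if (!is.null(cfg[[sec]])) {
      base[[sec]] <- cfg[[sec]]
    }
  }
  structure(base, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesize -> simulate -> build -> train -> explain from
#' one configuration, writing every artifact (results CSVs, corpus and
#' model RDS with JSON sidecars, saliency profile CSV) under
#' `config$out_dir` and returning a manifest with per-stage seeds,
#' artifact paths, content hashes, and summary metrics. A fixed
#' configuration gives an identical manifest on every run.
#'
#' @param config A `run_config` list, or a path to a YAML file with the
#'   same structure (missing entries fall back to defaults).
#' @return The manifest, invisibly also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  wx <- stage("synthesize", {
    w <- config$weather
    synth_grid(w$n_grids, w$n_years, c(w$lat_min, w$lat_max),
               unlist(w$scenario_weights), seed = w$seed)
  })
  weather_paths <- character(0)
  if (isTRUE(config$weather$write_csv)) {
    wdir <- file.path(out, "weather")
    dir.create(wdir, showWarnings = FALSE)
    weather_paths <- vapply(wx, function(ws) {
      p <- file.path(wdir, sprintf("%s_y%03d.csv", ws$grid_id, ws$year_index))
      write_weather_csv(ws, p)
      p
    }, character(1))
  }

  params <- stage("cultivar", cultivar_params(config$cultivar$file))
  batch <- stage("simulate", simulate_batch(wx, params))
  res_paths <- write_results_csv(batch, file.path(out, "seasons"))

  corpus <- stage("build", {
    cc <- config$corpus
    build_corpus(wx, batch, noise = cc$noise,
                 train_fraction = cc$train_fraction, seed = cc$seed)
  })
  corpus_path <- file.path(out, "corpus.rds")
  saveRDS(corpus, corpus_path)

  fit <- stage("train", {
    tc <- config$train
    distill(corpus, hidden = tc$hidden,
            config = train_config(lr = tc$lr, batch_size = tc$batch_size,
                                  max_epochs = tc$max_epochs,
                                  patience = tc$patience, seed = tc$seed))
  })
  model_path <- file.path(out, "model.rds")
  saveRDS(fit, model_path)
  history_path <- file.path(out, "history.csv")
  write.csv(fit$history, history_path, row.names = FALSE)

  val_pred <- predict(fit, corpus$X[, , corpus$validation, drop = FALSE])
  val_r2 <- 1 - mean((val_pred - corpus$y[corpus$validation])^2) /
    mean((corpus$y[corpus$validation] - mean(corpus$y[corpus$validation]))^2)

  profiles <- stage("explain", {
    sc <- config$saliency
    kept_results <- batch$results[!batch$results$excluded, ]
    do.call(rbind, lapply(sc$cases, function(case) {
      case_idx <- select_case(kept_results, case, sc$percentile)
      pool <- intersect(case_idx, corpus$train)
      picked <- sample_inputs(pool, sc$n,
                              seed = derive_seed(sc$seed, match(case, sc$cases)))
      maps <- positive_saliency(fit, corpus$X[, , picked, drop = FALSE])
      profile_by_dvi(maps, corpus$dvi[, picked, drop = FALSE],
                     corpus$maturity_day[picked], case = case)
    }))
  })
  profile_path <- file.path(out, "saliency_profiles.csv")
  write_profile_csv(profiles, profile_path)

  artifacts <- c(res_paths, corpus = corpus_path, model = model_path,
                 history = history_path, profiles = profile_path,
                 weather_paths)
  manifest <- list(
    config = unclass(config),
    seeds = list(weather = config$weather$seed,
                 corpus = config$corpus$seed,
                 train = config$train$seed,
                 saliency = config$saliency$seed),
    n_generated = length(wx),
    n_excluded = corpus$n_excluded,
    n_kept = length(corpus$y),
    best_epoch = fit$best_epoch,
    val_mse = fit$val_mse_best,
    val_r2 = val_r2,
    artifacts = as.list(artifacts),
    hashes = as.list(tools::md5sum(unname(artifacts)))
  )
  sidecar <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
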
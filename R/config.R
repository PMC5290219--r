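#' Default run configuration
#'
#' The full nested configuration with the conventional defaults: tau = 0.5,
#' order-5 bandpass at 0.01-0.6 Hz, four sub-streams per feature, split
#' fractions 90% down to 50% in 5% steps with 20 repetitions, the 12-way
#' polynomial-degree set `c(0, 2:12)` for SNC, and the standard baseline
#' classifier settings.
#'
#' @return A nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    simulation = unclass(simulation_config()),
    preprocess = unclass(preprocess_config()),
    features = list(families = feature_families, window = 10L,
                    de_eps_floor = NULL),
    snc = list(tau = 0.5, degrees = c(0L, 2:12), bias = FALSE),
    evaluation = list(fractions = seq(0.90, 0.50, by = -0.05),
                      repetitions = 20L, seed = 1L,
                      channels = c("Left1", "Left3", "Right1", "Right3"),
                      classifier = "snc", classifier_params = list())
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", here), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "classifier_params") {
      if (!is.list(user[[key]])) {
        stop(sprintf("'%s' must be a mapping", here), call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (cfg$snc$tau <= 0 || cfg$snc$tau > 1) {
    stop("snc.tau must lie in (0, 1]", call. = FALSE)
  }
  if (any(cfg$snc$degrees < 0 | cfg$snc$degrees > 12)) {
    stop("snc.degrees must lie in [0, 12]", call. = FALSE)
  }
  frs <- cfg$evaluation$fractions
  if (any(frs <= 0 | frs >= 1) || any(diff(frs) >= 0)) {
    stop("evaluation.fractions must be strictly decreasing within (0, 1)",
         call. = FALSE)
  }
  if (!all(cfg$features$families %in% feature_families)) {
    stop(sprintf("features.families must be drawn from %s",
                 paste(feature_families, collapse = ", ")), call. = FALSE)
  }
  sim <- cfg$simulation
  class(sim) <- "sim_config"
  validate_sim_config(sim)
  do.call(preprocess_config, cfg$preprocess)
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()]; unknown keys are
#' rejected with the offending key path; value constraints are validated.
#' An empty file yields the full defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      cfg <- structure(merge_config(unclass(cfg), user), class = "run_config")
    }
  }
  validate_run_config(cfg)
  cfg
}

#' Dump a run configuration to YAML
#'
#' @param cfg a `"run_config"`.
#' @param path target YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$features$de_eps_floor <- out$features$de_eps_floor %||% NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

# --- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: sncnirs <command> [--seed N] [options]",
    "",
    "commands:",
    "  simulate     --out DIR [--config cfg.yaml] [--seed N]",
    "  preprocess   --in in.csv --out out.csv [--config cfg.yaml]",
    "  extract      --cohort DIR --family FAM --channel CH --out features.csv",
    "  train        --features features.csv --out model.json [--degree D] [--tau T]",
    "  predict      --model model.json --features features.csv --out pred.csv",
    "  evaluate     --cohort DIR --classifier NAME --out report.json",
    "               [--config cfg.yaml] [--sweep-degrees]",
    "  segment-demo --cohort DIR --out table.csv [--depths 0,1,2] [--s 2]",
    "",
    "global flags: --seed N, --version",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(); flags <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(argv) && !startsWith(argv[[i + 1L]], "--")) {
        opts[[key]] <- argv[[i + 1L]]
        i <- i + 2L
      } else {
        flags <- c(flags, key)
        i <- i + 1L
      }
    } else {
      stop(sprintf("unexpected positional argument '%s'", a), call. = FALSE)
    }
  }
  list(opts = opts, flags = flags)
}

require_opt <- function(parsed, key) {
  if (is.null(parsed$opts[[key]])) {
    stop(sprintf("missing required option --%s", key), call. = FALSE)
  }
  parsed$opts[[key]]
}

#' Command-line entry point
#'
#' Dispatches the subcommands listed by the usage text; every run with the
#' same `--seed` and inputs reproduces its outputs byte for byte. Returns
#' (rather than calls `quit()` with) the exit code so it is testable in
#' process; the installed `sncnirs` script forwards the code to the shell.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 on success, 1 on any error.
#' @export
main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(1L)
  }
  if (argv[[1L]] == "--version") {
    cat(as.character(utils::packageVersion("sncnirs")), "\n")
    return(0L)
  }
  cmd <- argv[[1L]]
  parsed <- tryCatch(parse_cli_args(argv[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed)); message(cli_usage()); return(1L)
  }
  result <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(parsed),
      preprocess = cli_preprocess(parsed),
      extract = cli_extract(parsed),
      train = cli_train(parsed),
      predict = cli_predict(parsed),
      evaluate = cli_evaluate(parsed),
      `segment-demo` = cli_segment_demo(parsed),
      stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("unknown subcommand", conditionMessage(e))) message(cli_usage())
    1L
  })
  result
}

cli_config <- function(parsed) {
  cfg <- load_config(parsed$opts[["config"]])
  if (!is.null(parsed$opts[["seed"]])) {
    seed <- as.integer(parsed$opts[["seed"]])
    cfg$simulation$seed <- seed
    cfg$evaluation$seed <- seed
  }
  cfg
}

# Write the resolved configuration next to an output so the run is
# reproducible from its artifacts alone.
write_manifest <- function(cfg, out_dir) {
  dump_config(cfg, file.path(out_dir, "run_manifest.yaml"))
}

cli_simulate <- function(parsed) {
  cfg <- cli_config(parsed)
  out <- require_opt(parsed, "out")
  sim <- cfg$simulation; class(sim) <- "sim_config"
  cohort <- generate_cohort(sim)
  write_cohort(cohort, out)
  write_manifest(cfg, out)
  invisible(NULL)
}

cli_preprocess <- function(parsed) {
  cfg <- cli_config(parsed)
  rec <- read_recording(require_opt(parsed, "in"))
  pp <- do.call(preprocess_config, cfg$preprocess)
  write_recording(preprocess(rec, pp), require_opt(parsed, "out"))
  invisible(NULL)
}

cli_extract <- function(parsed) {
  cfg <- cli_config(parsed)
  cohort <- read_cohort(require_opt(parsed, "cohort"))
  feats <- extract_features(cohort, require_opt(parsed, "family"),
                            require_opt(parsed, "channel"),
                            window = cfg$features$window,
                            eps_floor = cfg$features$de_eps_floor)
  write_features(feats, require_opt(parsed, "out"))
  invisible(NULL)
}

cli_train <- function(parsed) {
  cfg <- cli_config(parsed)
  feats <- read_features(require_opt(parsed, "features"))
  degree <- as.integer(parsed$opts[["degree"]] %||% 0L)
  tau <- as.numeric(parsed$opts[["tau"]] %||% cfg$snc$tau)
  model <- snc_fit(feats$X, feats$y, tau = tau, degree = degree,
                   bias = isTRUE(cfg$snc$bias))
  write_snc_model(model, require_opt(parsed, "out"),
                  feature_family = feats$family, channel = feats$channel)
  invisible(NULL)
}

cli_predict <- function(parsed) {
  model <- read_snc_model(require_opt(parsed, "model"))
  feats <- read_features(require_opt(parsed, "features"))
  pred <- predict(model, feats$X)
  utils::write.csv(
    data.frame(participant_id = feats$participant, task_label = feats$y,
               predicted = pred),
    require_opt(parsed, "out"), row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

cli_evaluate <- function(parsed) {
  cfg <- cli_config(parsed)
  cohort <- read_cohort(require_opt(parsed, "cohort"))
  pp <- do.call(preprocess_config, cfg$preprocess)
  cohort <- structure(lapply(cohort, preprocess, config = pp),
                      class = "nirs_cohort")
  name <- parsed$opts[["classifier"]] %||% cfg$evaluation$classifier
  clf <- if (name == "snc") snc_classifier(tau = cfg$snc$tau) else {
    baseline_adapter(name, cfg$evaluation$classifier_params)
  }
  plan <- split_plan(cfg$evaluation$fractions, cfg$evaluation$repetitions,
                     cfg$evaluation$seed)
  degrees <- if ("sweep-degrees" %in% parsed$flags) cfg$snc$degrees else NULL
  report <- run_algorithm1(cohort, clf, families = cfg$features$families,
                           channels = cfg$evaluation$channels, plan = plan,
                           degrees = degrees, window = cfg$features$window,
                           eps_floor = cfg$features$de_eps_floor)
  jsonlite::write_json(
    list(classifier = report$classifier, step_count = report$step_count,
         best = report$best, summary = report$summary, cells = report$cells),
    require_opt(parsed, "out"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(NULL)
}

cli_segment_demo <- function(parsed) {
  cfg <- cli_config(parsed)
  cohort <- read_cohort(require_opt(parsed, "cohort"))
  pp <- do.call(preprocess_config, cfg$preprocess)
  cohort <- structure(lapply(cohort, preprocess, config = pp),
                      class = "nirs_cohort")
  depths <- as.integer(strsplit(parsed$opts[["depths"]] %||% "0,1,2", ",")[[1L]])
  s <- as.integer(parsed$opts[["s"]] %||% 2L)
  plan <- split_plan(cfg$evaluation$fractions, cfg$evaluation$repetitions,
                     cfg$evaluation$seed)
  tab <- segmentation_degradation_demo(cohort, snc_classifier(tau = cfg$snc$tau),
                                       depths = depths, s = s, plan = plan)
  utils::write.csv(tab, require_opt(parsed, "out"), row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}
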
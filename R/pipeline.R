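# End-to-end orchestration: simulate (or read) -> validate/filter -> score
# -> network metrics -> match -> lactation fits -> affinity effect, with
# every intermediate table persisted as CSV and a JSON run manifest.

#' Pipeline configuration
#'
#' Either `synthetic` (a [synthetic_config()]) or the three input paths
#' must be supplied.
#'
#' @param synthetic optional [synthetic_config()]; when given, the run
#'   starts by simulating a herd.
#' @param gate_events_path,milk_records_path,residency_path input CSVs used
#'   when `synthetic` is NULL; `residency_path` may be NULL to infer
#'   residency from the events.
#' @param spec a [scoring_spec()]; the default applies the lag-sequence
#'   score with monthly-traffic weighting and residency normalisation.
#' @param match_mode `"exclusive"` or `"non_exclusive"`.
#' @param min_residency_days minimum total days in pen to keep a cow.
#' @param min_obs minimum records per cow-lactation fit.
#' @param min_period_days minimum days per period type per cow.
#' @param alternative sidedness of the per-pen paired test.
#' @param out_dir directory for artifacts.
#' @param seed RNG seed for the run (overrides the synthetic config's).
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = NULL,
                       gate_events_path = NULL, milk_records_path = NULL,
                       residency_path = NULL,
                       spec = scoring_spec("lag_sequence",
                                           apply_month_weights = TRUE,
                                           apply_residency_norm = TRUE),
                       match_mode = "exclusive",
                       min_residency_days = 30L,
                       min_obs = 5L,
                       min_period_days = 7L,
                       alternative = "greater",
                       out_dir = tempfile("herdaffinity_run_"),
                       seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(gate_events_path) || is.null(milk_records_path)))
    stop("supply either `synthetic` or input CSV paths", call. = FALSE)
  structure(list(synthetic = synthetic,
                 gate_events_path = gate_events_path,
                 milk_records_path = milk_records_path,
                 residency_path = residency_path,
                 spec = spec, match_mode = match_mode,
                 min_residency_days = as.integer(min_residency_days),
                 min_obs = as.integer(min_obs),
                 min_period_days = as.integer(min_period_days),
                 alternative = alternative,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full affinity analysis pipeline
#'
#' Executes simulate/read -> residency filter -> affinity scoring ->
#' network metrics -> pair matching -> Wood lactation fits -> affinity
#' effect analysis, writing each stage's table under `config$out_dir` and
#' returning all results plus a manifest.  Reruns with an identical
#' configuration (including seed) produce byte-identical artifacts.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisible list with all stage outputs and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- character(0)
  keep <- function(name, dt) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    fwrite(dt, p)
    paths[[name]] <<- p
    dt
  }

  # Stage 1: inputs.
  truth <- NULL
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- config$seed
    sim <- generate_herd(cfg)
    events <- sim$events; milk <- sim$milk; residency <- sim$residency
    truth <- sim$truth
    say("simulated herd: %d gate events, %d milk records, %d cows",
        nrow(events), nrow(milk), length(unique(residency$cow_id)))
  } else {
    events <- read_gate_events(config$gate_events_path)
    milk <- read_milk_records(config$milk_records_path)
    residency <- if (!is.null(config$residency_path))
      read_residency(config$residency_path) else infer_residency(events)
    say("read %d gate events, %d milk records", nrow(events), nrow(milk))
  }

  # Stage 2: residency filter.
  flt <- apply_residency_filter(residency, events = events, milk = milk,
                                min_days = config$min_residency_days)
  events <- flt$events; milk <- flt$milk; residency <- flt$residency
  say("residency filter (< %d days): excluded %d cow(s)",
      config$min_residency_days, length(flt$excluded))
  keep("residency", residency)

  # Stage 3: scoring.
  networks <- score_affinity(events, config$spec, residency = residency)
  keep("scores", rbindlist(lapply(networks, network_edges)))
  say("scored %d pen network(s) with method %s", length(networks),
      config$spec$method)

  # Stage 4: network metrics.
  metrics <- lapply(networks, compute_metrics)
  keep("metrics", metrics_table(metrics))

  # Stage 5: matching.
  pairs <- match_pairs(networks, mode = config$match_mode)
  keep("pairs", pairs)
  say("matched %d pair(s) (%s)", nrow(pairs),
      paste(unique(pairs$algorithm), collapse = "+"))

  # Stage 6: lactation baselines.
  fits <- fit_lactations(milk, min_obs = config$min_obs)
  keep("fits", fits)
  resid <- lactation_residuals(milk, fits)
  keep("residuals", resid)
  say("fitted %d cow-lactation curve(s), %d converged", nrow(fits),
      sum(fits$converged))

  # Stage 7: affinity effect.
  periods <- label_periods(pairs, residency)
  summaries <- summarize_deviation(resid, periods,
                                   min_period_days = config$min_period_days)
  keep("deviation_summaries", summaries)
  effects <- pen_paired_test(summaries, alternative = config$alternative)
  keep("effects", effects)
  balance <- dim_balance_check(periods, milk)
  say("affinity effect: overall mean diff %.3f kg/day, DIM-balance KS %.3f",
      effects[pen_id == "Overall", mean_diff], balance$ks_statistic)

  manifest <- list(
    package_version = as.character(utils::packageVersion("herdaffinity")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    artifacts = as.list(paths),
    rows = lapply(list(events = events, milk = milk, residency = residency,
                       pairs = pairs, fits = fits, effects = effects),
                  nrow),
    excluded_cows = flt$excluded,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2))
  jsonlite::write_json(manifest[names(manifest) != "elapsed_s"],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(events = events, milk = milk, residency = residency,
                 truth = truth, networks = networks, metrics = metrics,
                 pairs = pairs, fits = fits, residuals = resid,
                 periods = periods, summaries = summaries,
                 effects = effects, dim_balance = balance,
                 manifest = manifest))
}

#' Fraction of planted pairs recovered by a matching
#'
#' @param pairs matched pairs table (`pen_id, cow_a, cow_b`).
#' @param truth ground truth from [generate_herd()] (`$truth`).
#' @return fraction of planted pairs recovered exactly.
#' @export
pair_recovery <- function(pairs, truth) {
  planted <- truth$planted_pairs[, .(pen_id, cow_a, cow_b)]
  if (!nrow(planted)) return(NA_real_)
  got <- as.data.table(pairs)[, .(pen_id, cow_a, cow_b)]
  nrow(merge(planted, got, by = c("pen_id", "cow_a", "cow_b"))) /
    nrow(planted)
}
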
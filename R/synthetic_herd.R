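# Synthetic herd generator: gate-passage logs, daily milk records and pen
# residency for an AMS farm, with planted affinity pairs and a known
# broken-affinity effect on milk yield.  Every downstream stage of the
# pipeline can be validated against the ground truth this module returns.

#' Configuration for the synthetic herd generator
#'
#' Defaults emulate the commercial AMS farm the pipeline was designed around:
#' four pens of about 54 milking cows, roughly 10 sort-gate passages and 2.7
#' milkings per cow per day over a 12-month study, dynamic pen residency with
#' stay lengths spread over four duration bands, per-cow Wood lactation
#' curves peaking near 37 kg/day, and day-to-day yield noise of 0.8 kg/day
#' while a cow's affinity partner is present versus 2.6 kg/day (plus a small
#' negative mean shift) after the pair is broken.
#'
#' A fraction `affinity_fraction` of each pen's cows is assigned to disjoint
#' planted pairs.  One member of each pair (the "stayer") is resident for
#' the whole study; the other (the "leaver") is absent for part of it, so
#' the stayer experiences both an affinity period and a broken period.  By
#' default most pairs are broken by one or two temporary absence windows of
#' the leaver (who returns, as after illness or a management move) and the
#' rest by a terminal exit (dry-off or sale); temporary breaks keep the
#' break status unconfounded with lactation stage.  While both mates are
#' co-resident, each gate passage by one mate is followed by a passage of
#' the other within `follow_gap_seconds` with probability `follow_prob`;
#' the mates' baseline passage rate is reduced to
#' `passes_per_cow_day / (1 + follow_prob)` during co-residence so the
#' total daily rate stays at the configured mean.
#'
#' @param n_pens number of pens (one AMS each).
#' @param cows_per_pen cows housed per pen.
#' @param study_days length of the study period in days.
#' @param passes_per_cow_day mean sort-gate passages per cow per day
#'   (Poisson).
#' @param milkings_per_cow_day mean passages diverted to milking; sets the
#'   probability that an event's destination is `"milking"`.
#' @param affinity_fraction fraction of a pen's cows assigned to planted
#'   pairs (rounded down to an even cow count).
#' @param follow_prob probability that a planted partner passes the gate
#'   immediately after its mate.
#' @param follow_gap_seconds maximum delay (s) of a follower passage.
#' @param residency_model list with `frac_day_one` (fraction of unpaired
#'   cows resident from day 1), `band_lo`/`band_hi`/`band_prob`
#'   (stay-duration bands in days and their probabilities),
#'   `temporary_break_frac` (fraction of planted pairs broken by temporary
#'   absence rather than terminal exit), `break_slots` (start-fraction
#'   windows for absences), `break_len_range` (absence length as a fraction
#'   of the study), `two_break_prob` (chance of two absences), and
#'   `leaver_exit_range` (exit-day fraction range for terminal breaks).
#' @param wood_param_dists list of per-cow Wood parameter distributions:
#'   `alpha_meanlog`, `alpha_sdlog` (log-normal scale), `beta_mean`,
#'   `beta_sd`, `beta_min` (truncated normal rise exponent), `gamma_mean`,
#'   `gamma_sd`, `gamma_min` (truncated normal decay rate per day).
#' @param sd_affinity daily yield noise SD (kg/day) while a planted pair is
#'   co-resident, and for unpaired cows.
#' @param sd_broken daily yield noise SD (kg/day) during broken-affinity
#'   periods.
#' @param mean_shift_broken additive mean yield effect (kg/day) during broken
#'   periods; non-positive under the working hypothesis.
#' @param start_date first calendar day of the study.
#' @param dim_at_entry_max days in milk at pen entry are sampled uniformly
#'   from 1..`dim_at_entry_max`.
#' @param max_dim no milk is recorded past this DIM (dry-off proxy).
#' @param lactation_probs named numeric vector of lactation-number
#'   probabilities.
#' @param seed RNG seed; identical configurations give identical herds.
#' @return a `herd_config` list.
#' @export
synthetic_config <- function(n_pens = 4L,
                             cows_per_pen = 54L,
                             study_days = 365L,
                             passes_per_cow_day = 10,
                             milkings_per_cow_day = 2.7,
                             affinity_fraction = 0.4,
                             follow_prob = 0.8,
                             follow_gap_seconds = 30,
                             residency_model = list(),
                             wood_param_dists = list(),
                             sd_affinity = 0.8,
                             sd_broken = 2.6,
                             mean_shift_broken = -0.3,
                             start_date = as.Date("2019-02-04"),
                             dim_at_entry_max = 120L,
                             max_dim = 400L,
                             lactation_probs = c("1" = 0.40, "2" = 0.29,
                                                 "3" = 0.18, "4" = 0.09,
                                                 "5" = 0.04),
                             seed = 1L) {
  stopifnot_scalar(n_pens, "n_pens", min = 1)
  stopifnot_scalar(cows_per_pen, "cows_per_pen", min = 1)
  if (study_days < 1) stop("`study_days` must be at least 1", call. = FALSE)
  stopifnot_scalar(passes_per_cow_day, "passes_per_cow_day", min = 1e-9)
  stopifnot_scalar(affinity_fraction, "affinity_fraction", min = 0, max = 1)
  stopifnot_scalar(follow_prob, "follow_prob", min = 0, max = 1)
  stopifnot_scalar(follow_gap_seconds, "follow_gap_seconds", min = 1)
  stopifnot_scalar(sd_affinity, "sd_affinity", min = 1e-12)
  stopifnot_scalar(sd_broken, "sd_broken", min = 1e-12)

  # Stay-duration bands follow the four residency bands reported for the
  # reference farm (30-90, 91-180, 181-270, >270 days), with probabilities
  # proportional to the pooled cow counts in those bands.
  rm_def <- list(frac_day_one = 0.5,
                 band_lo = c(30, 91, 181, 271),
                 band_hi = c(90, 180, 270, 365),
                 band_prob = c(124, 99, 149, 66) / 438,
                 temporary_break_frac = 0.7,
                 break_slots = list(c(0.25, 0.40), c(0.55, 0.70)),
                 break_len_range = c(0.08, 0.15),
                 two_break_prob = 0.5,
                 leaver_exit_range = c(0.3, 0.7))
  rm <- utils::modifyList(rm_def, residency_model)

  wd_def <- list(alpha_meanlog = log(17), alpha_sdlog = 0.2,
                 beta_mean = 0.25, beta_sd = 0.05, beta_min = 0.05,
                 gamma_mean = 0.004, gamma_sd = 0.001, gamma_min = 5e-4)
  wd <- utils::modifyList(wd_def, wood_param_dists)

  structure(list(
    n_pens = as.integer(n_pens), cows_per_pen = as.integer(cows_per_pen),
    study_days = as.integer(study_days),
    passes_per_cow_day = passes_per_cow_day,
    milkings_per_cow_day = milkings_per_cow_day,
    affinity_fraction = affinity_fraction, follow_prob = follow_prob,
    follow_gap_seconds = follow_gap_seconds,
    residency_model = rm, wood_param_dists = wd,
    sd_affinity = sd_affinity, sd_broken = sd_broken,
    mean_shift_broken = mean_shift_broken,
    start_date = as.Date(start_date),
    dim_at_entry_max = as.integer(dim_at_entry_max),
    max_dim = as.integer(max_dim),
    lactation_probs = lactation_probs / sum(lactation_probs),
    seed = as.integer(seed)), class = "herd_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

sample_band_duration <- function(n, rm) {
  band <- sample.int(length(rm$band_prob), n, replace = TRUE,
                     prob = rm$band_prob)
  lo <- rm$band_lo[band]
  hi <- rm$band_hi[band]
  lo + floor(runif(n) * (hi - lo + 1))
}

#' Generate a synthetic herd
#'
#' Simulates pen residency, per-cow Wood lactation curves, daily milk
#' records, and the sort-gate event stream (with follower passages planted
#' for affinity pairs), and returns them together with the ground truth
#' needed to validate the analysis pipeline.
#'
#' @param config a [synthetic_config()] object.
#' @return an object of class `herd_sim`: a list with `events` (timestamp,
#'   cow_id, pen_id, destination), `milk` (date, cow_id, pen_id, yield_kg,
#'   lactation_number, dim), `residency` (cow_id, pen_id, entry_date,
#'   exit_date) and `truth` (planted pairs, Wood parameters, day-level
#'   period labels, the config).
#' @export
generate_herd <- function(config) {
  if (!inherits(config, "herd_config"))
    stop("`config` must come from synthetic_config()", call. = FALSE)
  set.seed(config$seed)
  rm <- config$residency_model
  nd <- config$study_days

  pens <- lapply(seq_len(config$n_pens), function(p)
    simulate_pen(p, config, rm, nd))

  events <- rbindlist(lapply(pens, `[[`, "events"))
  milk <- rbindlist(lapply(pens, `[[`, "milk"))
  residency <- rbindlist(lapply(pens, `[[`, "residency"))
  labels <- rbindlist(lapply(pens, `[[`, "labels"))
  pairs <- rbindlist(lapply(pens, `[[`, "pairs"))
  params <- rbindlist(lapply(pens, `[[`, "params"))

  origin <- as.POSIXct(paste0(config$start_date, " 00:00:00"), tz = "UTC")
  events[, timestamp := origin + abs_sec]
  events[, abs_sec := NULL]
  setcolorder(events, c("timestamp", "cow_id", "pen_id", "destination"))

  milk[, date := config$start_date + day - 1L]
  residency[, `:=`(entry_date = config$start_date + entry - 1L,
                   exit_date = config$start_date + exit - 1L)]
  labels[, date := config$start_date + day - 1L]

  structure(list(
    events = events[],
    milk = milk[, .(date, cow_id, pen_id, yield_kg, lactation_number, dim)],
    residency = residency[, .(cow_id, pen_id, entry_date, exit_date)],
    truth = list(planted_pairs = pairs[],
                 wood_params = params[],
                 residency_days = residency[, .(cow_id, pen_id, entry, exit)],
                 labels = labels[, .(cow_id, pen_id, day, date, label)],
                 config = config)), class = "herd_sim")
}

# One pen's worth of simulation; day indices are 1..study_days.
simulate_pen <- function(p, config, rm, nd) {
  pen_id <- sprintf("pen%d", p)
  n <- config$cows_per_pen
  cow_id <- sprintf("P%dC%03d", p, seq_len(n))

  n_pairable <- floor(config$affinity_fraction * n)
  if (config$affinity_fraction > 0 && n_pairable %% 2L == 1L) {
    warning(sprintf(
      "pen %d: affinity_fraction yields an odd cow count (%d); rounding down",
      p, n_pairable), call. = FALSE)
  }
  n_paired <- (n_pairable %/% 2L) * 2L
  paired <- if (n_paired > 0) sample(cow_id, n_paired) else character()
  stayer <- paired[seq_len(n_paired / 2)]
  leaver <- paired[seq_len(n_paired / 2) + n_paired / 2]

  # Residency: stayers span the study.  A planted pair is broken either by a
  # temporary absence of the leaver (exit with later re-entry: illness or a
  # management move, keeping break status unconfounded with lactation
  # stage) or by a terminal exit (dry-off/sold).  Unpaired cows enter on
  # day 1 with prob frac_day_one, else uniformly, with banded stays.
  n_pairs <- length(stayer)
  iv <- list()                      # residency intervals (cow, entry, exit)
  add_iv <- function(cw, e, x) iv[[length(iv) + 1L]] <<-
    data.table(cow_id = cw, entry = as.integer(e), exit = as.integer(x))
  for (s in stayer) add_iv(s, 1L, nd)
  break_type <- character(n_pairs)
  break_start <- integer(n_pairs); break_end <- integer(n_pairs)
  if (n_pairs) {
    temp <- runif(n_pairs) < rm$temporary_break_frac
    for (i in seq_len(n_pairs)) {
      if (temp[i]) {
        # One or two absence windows with return, drawn from staggered
        # slots so the two windows cannot overlap.
        slots <- rm$break_slots
        k <- if (length(slots) >= 2 && runif(1) < rm$two_break_prob) 2L
             else 1L
        use <- if (k == 2L) seq_len(2L)
               else 1L + (runif(1) < 0.5)
        prev_end <- 0L
        for (sl in slots[use]) {
          b0 <- max(prev_end + 2L,
                    round(runif(1, sl[1], sl[2]) * nd))
          len <- max(1L, round(runif(1, rm$break_len_range[1],
                                     rm$break_len_range[2]) * nd))
          b1 <- min(nd - 1L, b0 + len - 1L)
          if (b0 > b1) next
          add_iv(leaver[i], prev_end + 1L, b0 - 1L)
          prev_end <- b1
          if (break_start[i] == 0L) break_start[i] <- b0
          break_end[i] <- b1
        }
        if (prev_end + 1L <= nd) add_iv(leaver[i], prev_end + 1L, nd)
        break_type[i] <- "temporary"
      } else {
        lex <- round(runif(1, rm$leaver_exit_range[1],
                           rm$leaver_exit_range[2]) * nd)
        lex <- min(nd - 1L, max(1L, as.integer(lex)))
        add_iv(leaver[i], 1L, lex)
        break_type[i] <- "terminal"
        break_start[i] <- lex + 1L; break_end[i] <- nd
      }
    }
  }
  unpaired <- setdiff(cow_id, paired)
  if (length(unpaired)) {
    from_one <- runif(length(unpaired)) < rm$frac_day_one
    e <- ifelse(from_one, 1L, 1L + floor(runif(length(unpaired)) * nd))
    dur <- sample_band_duration(length(unpaired), rm)
    for (i in seq_along(unpaired))
      add_iv(unpaired[i], e[i], min(nd, as.integer(e[i]) + dur[i] - 1L))
  }
  resid_iv <- rbindlist(iv)[id_order(cow_id, entry)]
  first_entry <- resid_iv[, .(entry0 = min(entry)), by = cow_id]
  entry0 <- setNames(first_entry$entry0, first_entry$cow_id)

  partner_of <- setNames(rep(NA_character_, n), cow_id)
  partner_of[stayer] <- leaver
  partner_of[leaver] <- stayer

  # Per-cow-day period labels from the interval structure.
  labels <- resid_iv[, .(day = seq(entry, exit)),
                     by = .(.row = seq_len(nrow(resid_iv)), cow_id)][
                       , .(cow_id, day)]
  labels[, pen_id := pen_id]
  labels[, partner := partner_of[cow_id]]
  present <- labels[, .(partner = cow_id, day, co = TRUE)]
  labels <- present[labels, on = c("partner", "day")]
  labels[, label := fifelse(is.na(partner), "unpaired",
                            fifelse(is.na(co), "broken", "affinity"))]
  labels[, co := NULL]
  setorder(labels, cow_id, day)

  # Wood parameters, lactation number and DIM at entry.
  wd <- config$wood_param_dists
  params <- data.table(
    cow_id = cow_id, pen_id = pen_id,
    alpha = rlnorm(n, wd$alpha_meanlog, wd$alpha_sdlog),
    beta = rtrunc_norm(n, wd$beta_mean, wd$beta_sd, wd$beta_min),
    gamma = rtrunc_norm(n, wd$gamma_mean, wd$gamma_sd, wd$gamma_min),
    lactation_number = as.integer(sample(names(config$lactation_probs), n,
                                         replace = TRUE,
                                         prob = config$lactation_probs)),
    dim_at_entry = 1L + floor(runif(n) * config$dim_at_entry_max))

  # Milk: one daily total per resident day while DIM <= max_dim.
  milk <- merge(labels[, .(cow_id, pen_id, day, label)],
                params[, .(cow_id, alpha, beta, gamma, lactation_number,
                           dim_at_entry)],
                by = "cow_id")
  milk[, dim := dim_at_entry + day - entry0[cow_id]]
  milk <- milk[dim <= config$max_dim]
  setorder(milk, cow_id, day)
  milk[, mu := wood_curve(dim, alpha, beta, gamma) +
         fifelse(label == "broken", config$mean_shift_broken, 0)]
  milk[, yield_kg := pmax(0, mu + rnorm(.N, 0,
         fifelse(label == "broken", config$sd_broken, config$sd_affinity)))]

  # Gate events: Poisson per resident day; paired cows' baseline rate is
  # reduced during co-residence so follower events keep the mean rate.
  base_rate <- config$passes_per_cow_day
  ev <- labels[, .(cow_id, day, label)]
  ev[, rate := fifelse(label == "affinity",
                       base_rate / (1 + config$follow_prob), base_rate)]
  ev[, n_ev := rpois(.N, rate)]
  base <- ev[n_ev > 0, .(cow_id = rep(cow_id, n_ev), day = rep(day, n_ev),
                         label = rep(label, n_ev))]
  base[, abs_sec := (day - 1) * 86400 + floor(runif(.N) * 86400)]

  trig <- base[label == "affinity"]
  followers <- if (nrow(trig)) {
    keep <- runif(nrow(trig)) < config$follow_prob
    f <- trig[keep]
    f[, cow_id := partner_of[cow_id]]
    f[, abs_sec := abs_sec +
        1 + floor(runif(.N) * config$follow_gap_seconds)]
    f[abs_sec < nd * 86400]
  } else trig[0]

  events <- rbind(base, followers)[, .(cow_id, abs_sec)]
  setorder(events, abs_sec, cow_id)
  events[, abs_sec := strictly_increasing(abs_sec)]
  events[, pen_id := pen_id]
  events[, destination := fifelse(
    runif(.N) < config$milkings_per_cow_day / config$passes_per_cow_day,
    "milking", "feeding")]

  pairs <- if (n_pairs) {
    cp <- canonical_pairs(stayer, leaver)
    data.table(pen_id = pen_id, cow_a = cp$cow_a, cow_b = cp$cow_b,
               stayer = stayer, leaver = leaver, break_type = break_type,
               break_start = break_start,
               break_end = break_end)[id_order(cow_a)]
  } else {
    data.table(pen_id = character(), cow_a = character(),
               cow_b = character(), stayer = character(),
               leaver = character(), break_type = character(),
               break_start = integer(), break_end = integer())
  }

  list(events = events,
       milk = milk[, .(cow_id, pen_id, day, yield_kg, lactation_number, dim)],
       residency = data.table(resid_iv[, .(cow_id)], pen_id = pen_id,
                              resid_iv[, .(entry, exit)]),
       labels = labels[, .(cow_id, pen_id, day, label)],
       pairs = pairs, params = params)
}

#' Write a synthetic herd to disk as plain-text fixtures
#'
#' Writes `gate_events.csv`, `milk_records.csv` and `residency.csv` in the
#' schemas the readers in this package expect, plus `ground_truth.json`
#' (planted pairs, Wood parameters, day-level period labels).  Re-reading
#' the CSVs reproduces the in-memory tables; rewriting from the same
#' configuration is byte-identical.
#'
#' @param sim a `herd_sim` object from [generate_herd()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_herd_fixture <- function(sim, dir) {
  if (!inherits(sim, "herd_sim")) stop("`sim` must be a herd_sim object")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  paths <- c(gate_events = file.path(dir, "gate_events.csv"),
             milk_records = file.path(dir, "milk_records.csv"),
             residency = file.path(dir, "residency.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))

  ev <- copy(sim$events)
  ev[, timestamp := fmt_timestamp(timestamp)]
  fwrite(ev, paths[["gate_events"]])
  fwrite(sim$milk, paths[["milk_records"]])
  fwrite(sim$residency, paths[["residency"]])

  tr <- sim$truth
  gt <- list(planted_pairs = tr$planted_pairs,
             wood_params = tr$wood_params,
             labels = tr$labels[, .(cow_id, pen_id, day, label)])
  jsonlite::write_json(gt, paths[["ground_truth"]], dataframe = "columns",
                       digits = NA)
  invisible(paths)
}
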
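# The milk-yield contrast: label each matched cow's resident days as
# affinity (partner co-resident in the same pen) or broken (partner
# absent), summarise Wood-curve deviations per period type, and test the
# within-cow difference per pen with a paired t-test, Holm-corrected across
# pens.  A days-in-milk balance diagnostic guards against confounding with
# lactation stage.

expand_residency_days <- function(residency) {
  res <- as.data.table(residency)
  if (!nrow(res))
    return(data.table(cow_id = character(), pen_id = character(),
                      date = as.Date(character())))
  res[, .(date = seq(entry_date, exit_date, by = "day")),
      by = .(.row = seq_len(nrow(res)), cow_id, pen_id)][
        , .(cow_id, pen_id, date)]
}

#' Label affinity and broken-affinity days for matched pairs
#'
#' For every cow in an exclusive matching, each day of the cow's residency
#' is labelled `"affinity"` when its matched partner is resident in the
#' same pen that day, else `"broken"`.  Labels exist only on days the cow
#' itself is resident.
#'
#' @param pairs matched pairs (`pen_id, cow_a, cow_b`, as from
#'   [match_pairs()]).
#' @param residency residency interval table.
#' @return `data.table`: `cow_id, partner_id, pair_pen, pen_id, date,
#'   label`.
#' @export
label_periods <- function(pairs, residency) {
  pr <- as.data.table(pairs)
  days <- expand_residency_days(residency)
  mem <- rbind(pr[, .(cow_id = cow_a, partner_id = cow_b, pair_pen = pen_id)],
               pr[, .(cow_id = cow_b, partner_id = cow_a, pair_pen = pen_id)])
  if (anyDuplicated(mem$cow_id))
    stop("matching is not exclusive: a cow appears in two pairs",
         call. = FALSE)
  d <- days[mem, on = "cow_id", nomatch = NULL, allow.cartesian = TRUE]
  partner_days <- days[, .(partner_id = cow_id, pen_id, date, co = TRUE)]
  d <- partner_days[d, on = c("partner_id", "pen_id", "date")]
  d[, label := fifelse(is.na(co), "broken", "affinity")]
  out <- d[, .(cow_id, partner_id, pair_pen, pen_id, date, label)]
  setorder(out, cow_id, date)
  out[]
}

#' Summarise Wood-curve deviations by period type
#'
#' Per cow and period type: the mean daily deviation from the cow's
#' expected lactation curve (the discrete observed-minus-expected area
#' divided by days), its day-to-day SD, and the day count.  Period types
#' observed on fewer than `min_period_days` days are suppressed.
#'
#' @param residuals daily deviations from [lactation_residuals()].
#' @param periods day labels from [label_periods()].
#' @param min_period_days minimum days of a period type per cow.
#' @return `data.table`: `cow_id, partner_id, pair_pen, period_type,
#'   mean_dev, sd_dev, n_days`.
#' @export
summarize_deviation <- function(residuals, periods, min_period_days = 7L) {
  rs <- as.data.table(residuals)
  pd <- as.data.table(periods)
  x <- pd[rs, on = c("cow_id", "date"), nomatch = NULL]
  out <- x[, .(mean_dev = mean(residual_kg), sd_dev = sd(residual_kg),
               n_days = .N),
           by = .(cow_id, partner_id, pair_pen, period_type = label)]
  out <- out[n_days >= min_period_days]
  setorder(out, cow_id, period_type)
  out[]
}

# SD of the concatenation of groups given per-group (n, mean, sd).
pooled_sd <- function(n, m, s) {
  N <- sum(n)
  if (N < 2L) return(NA_real_)
  M <- sum(n * m) / N
  ss <- sum((n - 1) * s^2, na.rm = TRUE) + sum(n * (m - M)^2)
  sqrt(ss / (N - 1))
}

#' Per-pen paired t-test of affinity versus broken periods
#'
#' Each cow with both period types contributes one within-cow difference
#' `mean_dev(affinity) - mean_dev(broken)`; per pen these differences are
#' tested against zero (one-sided by default: yields are hypothesised to be
#' higher during affinity periods).  Raw p-values are Holm-adjusted across
#' pens.  Pooled per-pen SDs of the daily deviations (reconstructed from
#' the per-cow summaries, equivalent to concatenating every cow's daily
#' residuals) quantify the day-to-day variability in each period type.  An
#' `Overall` row pools all pens; its test is not applicable and reported
#' `NA`.
#'
#' @param summaries output of [summarize_deviation()].
#' @param alternative `"greater"` (affinity > broken) or `"two.sided"`.
#' @return `data.table` with one row per pen plus `Overall`: `pen_id,
#'   n_cows, mean_broken, mean_affinity, sd_broken, sd_affinity, mean_diff,
#'   t_statistic, p_raw, p_holm, testable`.
#' @export
pen_paired_test <- function(summaries, alternative = c("greater",
                                                       "two.sided")) {
  alternative <- match.arg(alternative)
  sm <- as.data.table(summaries)
  wide <- dcast(sm, cow_id + pair_pen ~ period_type,
                value.var = c("mean_dev", "sd_dev", "n_days"))
  need <- c("mean_dev_affinity", "mean_dev_broken")
  if (!all(need %in% names(wide)))
    for (cn in setdiff(need, names(wide))) wide[, (cn) := NA_real_]
  both <- wide[!is.na(mean_dev_affinity) & !is.na(mean_dev_broken)]
  both[, d := mean_dev_affinity - mean_dev_broken]

  per_pen <- function(s, pen_label) {
    sm_aff <- s[period_type == "affinity"]
    sm_bro <- s[period_type == "broken"]
    data.table(
      pen_id = pen_label,
      mean_broken = if (nrow(sm_bro)) mean(sm_bro$mean_dev) else NA_real_,
      mean_affinity = if (nrow(sm_aff)) mean(sm_aff$mean_dev) else NA_real_,
      sd_broken = pooled_sd(sm_bro$n_days, sm_bro$mean_dev, sm_bro$sd_dev),
      sd_affinity = pooled_sd(sm_aff$n_days, sm_aff$mean_dev,
                              sm_aff$sd_dev))
  }

  pens <- sort(unique(sm$pair_pen))
  rows <- lapply(pens, function(p) {
    desc <- per_pen(sm[pair_pen == p], p)
    dd <- both[pair_pen == p, d]
    if (length(dd) >= 2L && sd(dd) > 0) {
      tt <- stats::t.test(dd, mu = 0, alternative = alternative)
      desc[, `:=`(n_cows = length(dd), mean_diff = mean(dd),
                  t_statistic = unname(tt$statistic),
                  p_raw = tt$p.value, testable = TRUE)]
    } else {
      desc[, `:=`(n_cows = length(dd),
                  mean_diff = if (length(dd)) mean(dd) else NA_real_,
                  t_statistic = NA_real_, p_raw = NA_real_,
                  testable = FALSE)]
    }
    desc
  })
  out <- rbindlist(rows)
  out[, p_holm := NA_real_]
  idx <- which(out$testable)
  if (length(idx))
    out[idx, p_holm := stats::p.adjust(out$p_raw[idx], method = "holm")]

  overall <- per_pen(sm, "Overall")
  overall[, `:=`(n_cows = nrow(both), mean_diff = mean(both$d),
                 t_statistic = NA_real_, p_raw = NA_real_,
                 p_holm = NA_real_, testable = FALSE)]
  out <- rbind(out, overall)
  setcolorder(out, c("pen_id", "n_cows", "mean_broken", "mean_affinity",
                     "sd_broken", "sd_affinity", "mean_diff", "t_statistic",
                     "p_raw", "p_holm", "testable"))
  out[]
}

#' Days-in-milk balance between period types
#'
#' Daily yield variability is largest in early lactation, so a spurious
#' association would arise if affinity days fell systematically at
#' different lactation stages than broken days.  This diagnostic compares
#' the DIM distributions of the two period types (quartiles and the
#' two-sample Kolmogorov-Smirnov statistic).  Advisory only — it never
#' gates the analysis.
#'
#' @param periods day labels from [label_periods()].
#' @param milk milk-record table supplying each day's DIM.
#' @return list with `quartiles` (per period type) and `ks_statistic`.
#' @export
dim_balance_check <- function(periods, milk) {
  pd <- as.data.table(periods)
  mk <- as.data.table(milk)[, .(cow_id, date, dim)]
  x <- mk[pd, on = c("cow_id", "date"), nomatch = NULL]
  qs <- x[, as.list(stats::quantile(dim, c(0.25, 0.5, 0.75),
                                    names = FALSE)),
          by = .(period_type = label)]
  setnames(qs, c("V1", "V2", "V3"), c("q25", "q50", "q75"))
  aff <- x[label == "affinity", dim]
  bro <- x[label == "broken", dim]
  ks <- if (length(aff) && length(bro))
    unname(suppressWarnings(
      stats::ks.test(aff, bro)$statistic)) else NA_real_
  list(quartiles = qs[], ks_statistic = ks)
}
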
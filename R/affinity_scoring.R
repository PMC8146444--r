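# Pairwise affinity scoring from ordered sort-gate passages.  Three schemes
# are provided: fixed 15-minute co-presence windows, inverse passage
# intervals, and an exponentially decaying lag-sequence score over the last
# `max_lag` passages.  Scores can be weighted by monthly gate traffic and
# normalised by pen residency.

#' Scoring specification
#'
#' @param method one of `"lag_sequence"` (exponentially decaying credit over
#'   the previous `max_lag` passages), `"window15"` (uniform credit to all
#'   cows co-present in a fixed window) or `"inverse_interval"` (credit
#'   inversely proportional to the time between two passages).
#' @param window_minutes window length for `window15` and the maximum
#'   interval considered by `inverse_interval` (minutes).
#' @param max_lag number of preceding passages credited by `lag_sequence`.
#' @param decay_base base of the exponential lag decay; lag `k` earns
#'   `decay_base^-(k-1)` (1, 1/2, 1/4, 1/8 with the default base 2).
#' @param epsilon_seconds floor on the interval used by `inverse_interval`
#'   so simultaneous passages contribute `1/epsilon_seconds`.
#' @param apply_month_weights down-weight events from high-traffic months by
#'   the pen's minimum-to-observed monthly count ratio.
#' @param apply_residency_norm divide each pair score by the geometric mean
#'   of the two cows' total days of pen residency.
#' @return a `scoring_spec` list.
#' @export
scoring_spec <- function(method = c("lag_sequence", "window15",
                                    "inverse_interval"),
                         window_minutes = 15, max_lag = 4L, decay_base = 2,
                         epsilon_seconds = 1,
                         apply_month_weights = FALSE,
                         apply_residency_norm = FALSE) {
  method <- match.arg(method)
  if (max_lag < 1L) stop("`max_lag` must be >= 1", call. = FALSE)
  if (window_minutes <= 0) stop("`window_minutes` must be > 0", call. = FALSE)
  if (decay_base <= 1) stop("`decay_base` must be > 1", call. = FALSE)
  structure(list(method = method, window_minutes = window_minutes,
                 max_lag = as.integer(max_lag), decay_base = decay_base,
                 epsilon_seconds = epsilon_seconds,
                 apply_month_weights = isTRUE(apply_month_weights),
                 apply_residency_norm = isTRUE(apply_residency_norm)),
            class = "scoring_spec")
}

# Build an affinity_network from accumulated pair contributions.
make_network <- function(pen_id, cows, pair_dt, spec, month_weights = NULL) {
  cows <- cows[id_order(cows)]
  w <- matrix(0, length(cows), length(cows), dimnames = list(cows, cows))
  if (nrow(pair_dt)) {
    agg <- pair_dt[, .(s = sum(w)), by = .(cow_a, cow_b)]
    w[cbind(agg$cow_a, agg$cow_b)] <- agg$s
    w[cbind(agg$cow_b, agg$cow_a)] <- agg$s
  }
  structure(list(pen_id = pen_id, cows = cows, weights = w, spec = spec,
                 month_weights = month_weights),
            class = "affinity_network")
}

#' @export
print.affinity_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<affinity_network> pen %s: %d cows, %d scored pairs (%s)\n",
              x$pen_id, length(x$cows), nz, x$spec$method))
  invisible(x)
}

#' Edge list of an affinity network
#'
#' @param network an `affinity_network`.
#' @param drop_zero drop pairs with zero score.
#' @return `data.table` with `pen_id, cow_a, cow_b, score`, `cow_a < cow_b`.
#' @export
network_edges <- function(network, drop_zero = TRUE) {
  w <- network$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.table(pen_id = network$pen_id,
                    cow_a = rownames(w)[ut[, 1]],
                    cow_b = colnames(w)[ut[, 2]],
                    score = w[ut])
  if (drop_zero) out <- out[score > 0]
  setorder(out, cow_a, cow_b)
  out[]
}

#' Rebuild an affinity network from an edge table
#'
#' Inverse of [network_edges()]: reconstructs the symmetric weight matrix of
#' one pen from `(pen_id, cow_a, cow_b, score)` rows, e.g. when resuming an
#' analysis from a persisted `scores.csv`.
#'
#' @param edges edge table for a single pen.
#' @param cows optional full cow roster (isolated cows carry zero rows).
#' @param spec the [scoring_spec()] to attach.
#' @return an `affinity_network`.
#' @export
network_from_edges <- function(edges, cows = NULL, spec = scoring_spec()) {
  e <- as.data.table(edges)
  if (length(unique(e$pen_id)) != 1L)
    stop("`edges` must belong to a single pen", call. = FALSE)
  cows <- cows %||% unique(c(e$cow_a, e$cow_b))
  make_network(e$pen_id[1], cows,
               e[, .(cow_a, cow_b, w = score)], spec, NULL)
}

check_one_pen_sorted <- function(events) {
  ev <- as.data.table(events)
  if (length(unique(ev$pen_id)) > 1L)
    stop("scoring expects events for a single pen", call. = FALSE)
  if (is.unsorted(as.numeric(ev$timestamp)))
    stop("events must be sorted by timestamp", call. = FALSE)
  ev
}

event_month_weight <- function(months, month_weights) {
  if (is.null(month_weights)) return(rep(1, length(months)))
  w <- month_weights[months]
  w[is.na(w)] <- 0
  unname(w)
}

#' Lag-sequence affinity score
#'
#' Walks the pen's ordered passage sequence; the cow at position `i` credits
#' the distinct cows at positions `i-1 .. i-max_lag` with
#' `decay_base^-(k-1)` (times the month weight of event `i`).  Passages by
#' the same cow at a lagged position are skipped without re-indexing the
#' lags.  This is order-based only: no time window or time weighting.
#'
#' @param events sorted gate events for one pen.
#' @param spec a [scoring_spec()] with `method = "lag_sequence"`.
#' @param month_weights optional named vector from [month_weights()].
#' @return an `affinity_network`.
#' @export
score_lag_sequence <- function(events, spec = scoring_spec("lag_sequence"),
                               month_weights = NULL) {
  ev <- check_one_pen_sorted(events)
  cows <- unique(ev$cow_id)
  n <- nrow(ev)
  mw <- event_month_weight(month_key(ev$timestamp), month_weights)
  pieces <- vector("list", spec$max_lag)
  for (k in seq_len(spec$max_lag)) {
    if (n <= k) break
    i <- (k + 1L):n
    a <- ev$cow_id[i]
    b <- ev$cow_id[i - k]
    keep <- a != b
    if (!any(keep)) next
    cp <- canonical_pairs(a[keep], b[keep])
    pieces[[k]] <- data.table(cow_a = cp$cow_a, cow_b = cp$cow_b,
                              w = spec$decay_base^(-(k - 1L)) * mw[i][keep])
  }
  make_network(ev$pen_id[1] %||% NA_character_, cows,
               rbindlist(pieces[!vapply(pieces, is.null, TRUE)]),
               spec, month_weights)
}

#' Fixed-window affinity score
#'
#' Time is partitioned into consecutive `window_minutes` bins aligned to
#' midnight (UTC).  Every unordered pair of distinct cows that each pass the
#' gate at least once in a bin gains one unit (times the bin's month
#' weight); credit is presence-based, not event-count-based, so all cows in
#' a window hold a uniform relationship.
#'
#' @inheritParams score_lag_sequence
#' @export
score_window <- function(events, spec = scoring_spec("window15"),
                         month_weights = NULL) {
  ev <- check_one_pen_sorted(events)
  cows <- unique(ev$cow_id)
  if (nrow(ev) == 0L)
    return(make_network(NA_character_, cows, data.table(), spec,
                        month_weights))
  secs <- as.numeric(ev$timestamp)
  wsec <- spec$window_minutes * 60
  day <- floor(secs / 86400)
  bin <- day * ceiling(86400 / wsec) + floor((secs - day * 86400) / wsec)
  pres <- unique(data.table(bin = bin, sec0 = day * 86400 +
                              floor((secs - day * 86400) / wsec) * wsec,
                            cow = ev$cow_id))
  pres <- unique(pres, by = c("bin", "cow"))
  mwb <- event_month_weight(
    month_key(as.POSIXct(pres$sec0, origin = "1970-01-01", tz = "UTC")),
    month_weights)
  pres[, mw := mwb]
  pairs <- pres[pres, on = "bin", allow.cartesian = TRUE][cow < i.cow]
  pair_dt <- pairs[, .(cow_a = cow, cow_b = i.cow, w = mw)]
  make_network(ev$pen_id[1], cows, pair_dt, spec, month_weights)
}

#' Inverse-interval affinity score
#'
#' Every pair of passages by distinct cows separated by at most
#' `window_minutes` contributes `month_weight / max(dt, epsilon_seconds)`
#' (dt in seconds) to the pair's score, weighting affinity inversely to the
#' time between the two passages.
#'
#' @inheritParams score_lag_sequence
#' @export
score_inverse_interval <- function(events,
                                   spec = scoring_spec("inverse_interval"),
                                   month_weights = NULL) {
  ev <- check_one_pen_sorted(events)
  cows <- unique(ev$cow_id)
  n <- nrow(ev)
  if (n < 2L)
    return(make_network(ev$pen_id[1] %||% NA_character_, cows, data.table(),
                        spec, month_weights))
  secs <- as.numeric(ev$timestamp)
  W <- spec$window_minutes * 60
  upper <- findInterval(secs + W, secs)
  sizes <- pmax(upper - seq_len(n), 0L)
  i <- rep.int(seq_len(n), sizes)
  j <- sequence(sizes, from = seq_len(n) + 1L)
  keep <- ev$cow_id[i] != ev$cow_id[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i))
    return(make_network(ev$pen_id[1], cows, data.table(), spec,
                        month_weights))
  mw <- event_month_weight(month_key(ev$timestamp[j]), month_weights)
  cp <- canonical_pairs(ev$cow_id[i], ev$cow_id[j])
  pair_dt <- data.table(cow_a = cp$cow_a, cow_b = cp$cow_b,
                        w = mw / pmax(secs[j] - secs[i],
                                      spec$epsilon_seconds))
  make_network(ev$pen_id[1], cows, pair_dt, spec, month_weights)
}

#' Monthly traffic weights for one pen
#'
#' Logged gate traffic varies over the year for operational reasons
#' unrelated to the cows' social structure, so event contributions are
#' weighted by `C_min / C_m`, the ratio of the pen's minimum nonzero monthly
#' passage count to the month's count.  The busiest month is thus weighted
#' `C_max / C_min` times less than the quietest; months with no events get
#' weight zero.
#'
#' @param counts `data.table` with columns `month` and `n` for one pen (as
#'   one pen's rows of [monthly_gate_counts()]).
#' @return named numeric vector mapping month (\"YYYY-MM\") to weight.
#' @export
month_weights <- function(counts) {
  ct <- as.data.table(counts)
  if (!all(c("month", "n") %in% names(ct)))
    stop("`counts` needs columns month and n", call. = FALSE)
  if ("pen_id" %in% names(ct) && length(unique(ct$pen_id)) > 1L)
    stop("month_weights() expects counts for a single pen", call. = FALSE)
  nz <- ct$n[ct$n > 0]
  if (!length(nz)) stop("no month with a nonzero count", call. = FALSE)
  w <- ifelse(ct$n > 0, min(nz) / ct$n, 0)
  stats::setNames(w, ct$month)
}

#' Normalise an affinity network by pen residency
#'
#' Divides each pair score by the geometric mean `sqrt(T_a * T_b)` of the
#' two cows' total days of residency in the network's pen (or, with
#' `denominator = "overlap"`, by the number of days both were co-resident),
#' so scores are comparable between long- and short-tenured cows.
#'
#' @param network an `affinity_network`.
#' @param residency residency interval table covering every scored cow.
#' @param denominator `"geometric"` (default) or `"overlap"`.
#' @return the normalised `affinity_network`.
#' @export
normalize_by_residency <- function(network, residency,
                                   denominator = c("geometric", "overlap")) {
  denominator <- match.arg(denominator)
  res <- as.data.table(residency)[pen_id == network$pen_id]
  cows <- network$cows
  if (denominator == "geometric") {
    tot <- res[, .(days = sum(as.integer(exit_date - entry_date) + 1L)),
               by = cow_id]
    Tx <- stats::setNames(tot$days, tot$cow_id)[cows]
    if (any(is.na(Tx) | Tx <= 0))
      stop("every scored cow needs positive residency in pen ",
           network$pen_id, call. = FALSE)
    denom <- sqrt(outer(Tx, Tx))
  } else {
    days <- seq(min(res$entry_date), max(res$exit_date), by = "day")
    occ <- matrix(FALSE, length(cows), length(days),
                  dimnames = list(cows, NULL))
    for (r in seq_len(nrow(res))) {
      cw <- res$cow_id[r]
      if (!cw %in% cows) next
      idx <- which(days >= res$entry_date[r] & days <= res$exit_date[r])
      occ[cw, idx] <- TRUE
    }
    denom <- tcrossprod(occ * 1)
    if (any(denom[network$weights > 0] == 0))
      stop("scored pair with zero co-residency overlap", call. = FALSE)
    denom[denom == 0] <- 1
  }
  network$weights <- network$weights / denom
  diag(network$weights) <- 0
  network
}

#' Score affinity networks for every pen
#'
#' Splits the event table by pen, optionally computes per-pen monthly
#' traffic weights, applies the requested scoring scheme, and optionally
#' normalises by residency.
#'
#' @param events gate-event table (all pens).
#' @param spec a [scoring_spec()].
#' @param residency residency table; required when
#'   `spec$apply_residency_norm` is set.
#' @return named list of `affinity_network` objects, one per pen.
#' @export
score_affinity <- function(events, spec = scoring_spec(), residency = NULL) {
  ev <- as.data.table(events)
  scorer <- switch(spec$method,
                   lag_sequence = score_lag_sequence,
                   window15 = score_window,
                   inverse_interval = score_inverse_interval)
  monthly <- if (spec$apply_month_weights) monthly_gate_counts(ev) else NULL
  pens <- sort(unique(ev$pen_id))
  nets <- lapply(pens, function(p) {
    mw <- if (!is.null(monthly)) month_weights(monthly[pen_id == p]) else NULL
    net <- scorer(ev[pen_id == p], spec, mw)
    if (spec$apply_residency_norm) {
      if (is.null(residency))
        stop("residency table required for residency normalisation",
             call. = FALSE)
      net <- normalize_by_residency(net, residency)
    }
    net
  })
  stats::setNames(nets, pens)
}
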
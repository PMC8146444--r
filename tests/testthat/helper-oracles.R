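# Independent brute-force oracles and small fixture builders used across
# the suite.  Oracles are deliberately naive (loops, exhaustive
# enumeration) and share no code with the implementation they check.

library(data.table)

t0 <- as.POSIXct("2019-02-04 00:00:00", tz = "UTC")

make_events <- function(secs, cows, pen = "pen1") {
  data.table(timestamp = t0 + secs, cow_id = cows, pen_id = pen,
             destination = "feeding")
}

make_net <- function(cows, edges, pen = "pen1") {
  w <- matrix(0, length(cows), length(cows), dimnames = list(cows, cows))
  for (e in edges) w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  structure(list(pen_id = pen, cows = cows, weights = w,
                 spec = scoring_spec(), month_weights = NULL),
            class = "affinity_network")
}

rand_pen_events <- function(n, n_cows, span_secs, seed) {
  set.seed(seed)
  secs <- sort(sample.int(span_secs, n))
  make_events(secs, sample(sprintf("C%02d", seq_len(n_cows)), n,
                           replace = TRUE))
}

# --- scoring oracles (naive double loops) ---------------------------------

oracle_lag <- function(events, max_lag = 4, base = 2, mw = NULL) {
  cw <- events$cow_id
  mon <- format(events$timestamp, "%Y-%m", tz = "UTC")
  s <- list()
  add <- function(a, b, v) {
    key <- paste(sort(c(a, b)), collapse = "|")
    s[[key]] <<- (s[[key]] %||% 0) + v
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (i in seq_along(cw)) {
    for (k in seq_len(max_lag)) {
      if (i - k < 1) break
      if (cw[i - k] == cw[i]) next
      wgt <- if (is.null(mw)) 1 else unname(mw[mon[i]])
      add(cw[i], cw[i - k], base^(-(k - 1)) * wgt)
    }
  }
  s
}

oracle_window <- function(events, window_minutes = 15, mw = NULL) {
  secs <- as.numeric(events$timestamp)
  w <- window_minutes * 60
  day <- floor(secs / 86400)
  bin <- paste(day, floor((secs - day * 86400) / w))
  bin_start <- t0 + 0  # month from bin start
  s <- list()
  for (b in unique(bin)) {
    idx <- which(bin == b)
    cows <- sort(unique(events$cow_id[idx]))
    if (length(cows) < 2) next
    st <- min(secs[idx])
    d0 <- floor(st / 86400) * 86400
    bs <- d0 + floor((st - d0) / w) * w
    mon <- format(as.POSIXct(bs, origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m")
    wgt <- if (is.null(mw)) 1 else unname(mw[mon])
    for (i in seq_len(length(cows) - 1))
      for (j in (i + 1):length(cows)) {
        key <- paste(cows[i], cows[j], sep = "|")
        s[[key]] <- (if (is.null(s[[key]])) 0 else s[[key]]) + wgt
      }
  }
  s
}

oracle_inverse <- function(events, window_minutes = 15, eps = 1,
                           mw = NULL) {
  secs <- as.numeric(events$timestamp)
  cw <- events$cow_id
  mon <- format(events$timestamp, "%Y-%m", tz = "UTC")
  W <- window_minutes * 60
  s <- list()
  n <- length(secs)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    dt <- secs[j] - secs[i]
    if (dt > W || cw[i] == cw[j]) next
    wgt <- if (is.null(mw)) 1 else unname(mw[mon[j]])
    key <- paste(sort(c(cw[i], cw[j])), collapse = "|")
    s[[key]] <- (if (is.null(s[[key]])) 0 else s[[key]]) +
      wgt / max(dt, eps)
  }
  s
}

edges_to_list <- function(net) {
  e <- network_edges(net)
  out <- as.list(e$score)
  names(out) <- paste(e$cow_a, e$cow_b, sep = "|")
  out
}

expect_same_scores <- function(net, oracle, tol = 1e-9) {
  got <- edges_to_list(net)
  oracle <- oracle[sapply(oracle, function(v) v > 0)]
  expect_setequal(names(got), names(oracle))
  for (k in names(oracle))
    expect_equal(got[[k]], oracle[[k]], tolerance = tol)
}

# --- graph oracles --------------------------------------------------------

floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

brute_max_matching <- function(W) {
  n <- nrow(W)
  best <- 0
  rec <- function(avail, acc) {
    if (acc > best) best <<- acc
    if (length(avail) < 2) return()
    v <- avail[1]
    rec(avail[-1], acc)
    for (u in avail[-1]) if (W[v, u] > 0)
      rec(setdiff(avail, c(v, u)), acc + W[v, u])
  }
  rec(seq_len(n), 0)
  best
}

# All matchings (incl. partial) of a set of agents, as named mate vectors.
all_matchings <- function(agents) {
  if (length(agents) == 0) return(list(character(0)))
  a <- agents[1]
  rest <- agents[-1]
  out <- all_matchings(rest)
  for (b in rest)
    for (m in all_matchings(setdiff(rest, b)))
      out[[length(out) + 1]] <- c(m, stats::setNames(c(b, a), c(a, b)))
  out
}

# Independent blocking-pair check (loops over every listed pair).
oracle_is_stable <- function(prefs, mate) {
  pos <- function(a, x) {
    p <- match(x, prefs[[a]])
    if (is.na(p)) Inf else p
  }
  for (a in names(prefs)) for (b in prefs[[a]]) {
    if (!(a %in% prefs[[b]])) next
    a_cur <- if (is.na(mate[a] %||% NA)) Inf else pos(a, mate[[a]])
    b_cur <- if (is.na(mate[b] %||% NA)) Inf else pos(b, mate[[b]])
    if (pos(a, b) < a_cur && pos(b, a) < b_cur) return(FALSE)
  }
  TRUE
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x

# Preference table with no stable matching: the classic 4-agent cyclic
# instance (each of A, B, C ranks the next in the cycle first and D last).
no_stable_prefs <- function() {
  structure(list(A = c("B", "C", "D"), B = c("C", "A", "D"),
                 C = c("A", "B", "D"), D = c("A", "B", "C")),
            class = "preference_table")
}

rand_weight_matrix <- function(n, p = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) W[i, j] <- W[j, i] <- round(runif(1, 0.1, 10), 2)
  dimnames(W) <- list(sprintf("C%02d", 1:n), sprintf("C%02d", 1:n))
  W
}

net_from_matrix <- function(W, pen = "pen1") {
  structure(list(pen_id = pen, cows = rownames(W), weights = W,
                 spec = scoring_spec(), month_weights = NULL),
            class = "affinity_network")
}
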
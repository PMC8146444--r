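test_that("lag-sequence score reproduces the hand-enumerated example", {
  ev <- make_events(c(10, 20, 30, 40), c("A", "B", "C", "A"))
  e <- network_edges(score_lag_sequence(ev))
  expect_equal(e[cow_a == "A" & cow_b == "B", score], 1.5)
  expect_equal(e[cow_a == "A" & cow_b == "C", score], 1.5)
  expect_equal(e[cow_a == "B" & cow_b == "C", score], 1.0)
})

test_that("a single cow's events give an all-zero matrix", {
  ev <- make_events(c(1, 2, 3, 4), rep("A", 4))
  net <- score_lag_sequence(ev)
  expect_equal(sum(net$weights), 0)
  expect_equal(nrow(network_edges(net)), 0L)
})

test_that("alternating two-cow stream follows the closed form from enumeration", {
  # lags 1 and 3 hit the partner (weights 1 and 1/4); lags 2 and 4 hit self
  # and are skipped, so AB = (n-1) + (n-3)/4 for n >= 3.
  for (n in c(4, 7, 20)) {
    ev <- make_events(seq_len(n) * 10, rep(c("A", "B"), length.out = n))
    got <- network_edges(score_lag_sequence(ev))$score
    oracle <- oracle_lag(ev)[["A|B"]]
    expect_equal(got, (n - 1) + (n - 3) * 0.25)
    expect_equal(got, oracle)
  }
})

test_that("unsorted events are rejected", {
  ev <- make_events(c(20, 10), c("A", "B"))
  expect_error(score_lag_sequence(ev), "sorted")
})

test_that("window score is presence-based within midnight-aligned bins", {
  # A and B each pass twice in one 15-min bin: one unit, not four
  ev <- make_events(c(10, 50, 100, 200), c("A", "B", "A", "B"))
  expect_equal(network_edges(score_window(ev))$score, 1)
  # A at 00:14, B at 00:16 fall in different bins: no score
  ev2 <- make_events(c(14 * 60, 16 * 60), c("A", "B"))
  expect_equal(nrow(network_edges(score_window(ev2))), 0L)
})

test_that("inverse-interval score follows 1/dt with an epsilon guard", {
  ev <- make_events(c(0, 10), c("A", "B"))
  expect_equal(network_edges(score_inverse_interval(ev))$score, 1 / 10)
  ev2 <- make_events(c(5, 5), c("A", "B"))
  expect_equal(network_edges(score_inverse_interval(ev2))$score, 1)
})

test_that("all three methods match naive brute-force enumeration", {
  for (seed in 1:6) {
    ev <- rand_pen_events(n = 150, n_cows = 12,
                          span_secs = 3 * 86400, seed = seed)
    expect_same_scores(score_lag_sequence(ev), oracle_lag(ev))
    expect_same_scores(score_window(ev), oracle_window(ev))
    expect_same_scores(score_inverse_interval(ev), oracle_inverse(ev))
  }
})

test_that("month weights scale contributions multiplicatively per event", {
  ev <- make_events(c(10, 20, 40 * 86400 + 10, 40 * 86400 + 20),
                    c("A", "B", "A", "B"))
  counts <- monthly_gate_counts(ev)
  mw <- month_weights(counts)
  for (fn in list(score_lag_sequence, score_window,
                  score_inverse_interval)) {
    net <- fn(ev, month_weights = mw)
    orc <- switch(net$spec$method,
                  lag_sequence = oracle_lag(ev, mw = mw),
                  window15 = oracle_window(ev, mw = mw),
                  inverse_interval = oracle_inverse(ev, mw = mw))
    expect_same_scores(net, orc)
  }
})

test_that("month weights are C_min / C_m with the stated extremes", {
  counts <- data.table(month = c("2019-03", "2019-12"), n = c(1000L, 2800L))
  w <- month_weights(counts)
  expect_equal(unname(w["2019-03"]), 1.0)
  expect_equal(unname(w["2019-12"]), 1 / 2.8)
  expect_equal(max(w) / min(w[w > 0]), 2.8)

  eq <- data.table(month = sprintf("2019-%02d", 1:12), n = 500L)
  expect_true(all(month_weights(eq) == 1))

  seas <- data.table(month = sprintf("2019-%02d", 1:6),
                     n = c(100L, 0L, 340L, 720L, 55L, 210L))
  ws <- month_weights(seas)
  expect_equal(ws[["2019-02"]], 0)
  nz <- seas$n[seas$n > 0]
  expect_equal(min(ws[ws > 0]) * max(nz), max(ws[ws > 0]) * min(nz))
})

test_that("residency normalisation divides by the geometric mean tenure", {
  net <- make_net(c("A", "B"), list(list("A", "B", 10)))
  res <- data.table(cow_id = c("A", "B"), pen_id = "pen1",
                    entry_date = as.Date("2019-03-01"),
                    exit_date = as.Date("2019-03-01") + 99)
  nn <- normalize_by_residency(net, res)
  expect_equal(nn$weights["A", "B"], 0.1)
  # doubling both tenures halves the normalised score
  res2 <- copy(res)[, exit_date := entry_date + 199]
  expect_equal(normalize_by_residency(net, res2)$weights["A", "B"], 0.05)
  # missing residency for a scored cow is an error
  expect_error(normalize_by_residency(net, res[cow_id == "A"]),
               "residency")
})

test_that("identical event streams rank shorter-tenure pairs higher", {
  secs <- rep((0:19) * 3600, each = 2) + c(0, 5)
  cows <- c(rbind(rep(c("A", "C"), 10), rep(c("B", "D"), 10)))
  ev <- make_events(secs, cows)
  net <- score_lag_sequence(ev)
  res <- data.table(cow_id = c("A", "B", "C", "D"), pen_id = "pen1",
                    entry_date = as.Date("2019-02-04"),
                    exit_date = as.Date("2019-02-04") + c(364, 364, 49, 49))
  nn <- normalize_by_residency(net, res)
  expect_equal(net$weights["A", "B"], net$weights["C", "D"])
  expect_gt(nn$weights["C", "D"], nn$weights["A", "B"])
})

test_that("scores are equivariant under cow relabelling", {
  ev <- rand_pen_events(n = 120, n_cows = 8, span_secs = 86400, seed = 42)
  perm <- stats::setNames(sprintf("Z%02d", sample(8)),
                          sprintf("C%02d", 1:8))
  ev2 <- copy(ev)[, cow_id := unname(perm[cow_id])]
  for (fn in list(score_lag_sequence, score_window,
                  score_inverse_interval)) {
    w1 <- fn(ev)$weights
    w2 <- fn(ev2)$weights
    expect_equal(w2[perm[rownames(w1)], perm[colnames(w1)]],
                 `dimnames<-`(w1, list(unname(perm[rownames(w1)]),
                                       unname(perm[colnames(w1)]))))
  }
})

test_that("lag scores are invariant to uniform time translation", {
  ev <- rand_pen_events(n = 100, n_cows = 6, span_secs = 86400, seed = 7)
  ev2 <- copy(ev)[, timestamp := timestamp + 12345]
  expect_equal(score_lag_sequence(ev)$weights,
               score_lag_sequence(ev2)$weights)
})

test_that("methods agree on which pairs score zero", {
  ev <- rand_pen_events(n = 80, n_cows = 10, span_secs = 40 * 86400,
                        seed = 9)
  nets <- list(score_lag_sequence(ev, scoring_spec("lag_sequence")),
               score_window(ev),
               score_inverse_interval(ev))
  # pairs isolated in time (beyond any window or lag) are zero everywhere;
  # check pairs that the most permissive method scores zero
  zero_lag <- nets[[1]]$weights == 0
  expect_true(all(nets[[2]]$weights[zero_lag] == 0 |
                    nets[[1]]$weights[zero_lag] == 0))
})

test_that("planted pairs separate from background for all three methods", {
  cfg <- synthetic_config(n_pens = 1, cows_per_pen = 20, study_days = 40,
                          affinity_fraction = 0.6, follow_prob = 0.5,
                          seed = 21)
  sim <- generate_herd(cfg)
  tp <- sim$truth$planted_pairs[, paste(cow_a, cow_b)]
  for (fn in list(score_lag_sequence, score_window,
                  score_inverse_interval)) {
    e <- network_edges(fn(sim$events))
    e[, planted := paste(cow_a, cow_b) %in% tp]
    med_bg <- e[planted == FALSE, stats::median(score)]
    expect_true(all(e[planted == TRUE, score] > med_bg))
  }
})
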
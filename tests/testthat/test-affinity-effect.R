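mk_residency <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r)
    data.table(cow_id = r[[1]], pen_id = r[[2]],
               entry_date = as.Date("2019-03-01") + r[[3]] - 1,
               exit_date = as.Date("2019-03-01") + r[[4]] - 1)))
}

test_that("period labels split at the partner's exit", {
  pairs <- data.table(pen_id = "pen1", cow_a = "A", cow_b = "B")
  res <- mk_residency(list("A", "pen1", 1, 300), list("B", "pen1", 1, 200))
  lab <- label_periods(pairs, res)
  a <- lab[cow_id == "A"]
  expect_equal(a[label == "affinity", .N], 200L)
  expect_equal(a[label == "broken", .N], 100L)
  # B is only resident while A is present: all affinity
  expect_equal(lab[cow_id == "B" & label == "broken", .N], 0L)
  # day conservation: labels cover exactly the resident days
  expect_equal(nrow(a), 300L)
})

test_that("co-residence in a different pen still counts as broken", {
  pairs <- data.table(pen_id = "pen1", cow_a = "A", cow_b = "B")
  res <- mk_residency(list("A", "pen1", 1, 100), list("B", "pen1", 1, 50),
                      list("B", "pen2", 51, 100))
  lab <- label_periods(pairs, res)
  expect_equal(lab[cow_id == "A" & label == "broken", .N], 50L)
})

test_that("a non-exclusive pairs table is rejected", {
  pairs <- data.table(pen_id = "pen1", cow_a = c("A", "A"),
                      cow_b = c("B", "C"))
  expect_error(label_periods(pairs, mk_residency(list("A", "pen1", 1, 9))),
               "exclusive")
})

test_that("labels agree exactly with generator ground truth", {
  cfg <- synthetic_config(n_pens = 1, cows_per_pen = 16, study_days = 90,
                          affinity_fraction = 0.5, passes_per_cow_day = 0.5,
                          seed = 17)
  sim <- generate_herd(cfg)
  lab <- label_periods(sim$truth$planted_pairs[, .(pen_id, cow_a, cow_b)],
                       sim$residency)
  truth <- sim$truth$labels[label != "unpaired",
                            .(cow_id, date, truth_label = label)]
  cmp <- merge(lab[, .(cow_id, date, label)], truth,
               by = c("cow_id", "date"), all = TRUE)
  expect_true(all(!is.na(cmp$label) & !is.na(cmp$truth_label)))
  expect_true(all(cmp$label == cmp$truth_label))
})

test_that("deviation summaries compute means, SDs and suppression", {
  pairs <- data.table(pen_id = "pen1", cow_a = "A", cow_b = "B")
  res <- mk_residency(list("A", "pen1", 1, 20), list("B", "pen1", 1, 10))
  lab <- label_periods(pairs, res)
  rs <- data.table(cow_id = "A", date = as.Date("2019-03-01") + 0:19,
                   residual_kg = c(rep(c(1, -1), 5), rep(0.5, 10)))
  sm <- summarize_deviation(rs, lab, min_period_days = 7)
  aff <- sm[cow_id == "A" & period_type == "affinity"]
  expect_equal(aff$mean_dev, 0)
  expect_equal(aff$sd_dev, sd(rep(c(1, -1), 5)))   # ~1.054 over 10 days
  bro <- sm[cow_id == "A" & period_type == "broken"]
  expect_equal(bro$mean_dev, 0.5)
  expect_equal(bro$sd_dev, 0)
  # raising the threshold suppresses nothing here, but a 15-day floor
  # drops the 10-day broken period
  sm2 <- summarize_deviation(rs, lab, min_period_days = 15)
  expect_equal(nrow(sm2[period_type == "broken"]), 0L)

  two <- data.table(cow_id = "A", date = as.Date("2019-03-01") + 0:1,
                    residual_kg = c(1, -1))
  sm3 <- summarize_deviation(two, lab, min_period_days = 2)
  expect_equal(sm3$sd_dev, sqrt(2))
})

test_that("pen test pairs within cows, pools SDs, and applies Holm", {
  set.seed(18)
  mk_sm <- function(pen, n, shift) {
    rbindlist(lapply(seq_len(n), function(i) {
      aff <- rnorm(60, 0, 0.8)
      bro <- rnorm(40, -shift, 2.4)
      data.table(cow_id = sprintf("%s_C%02d", pen, i), partner_id = "x",
                 pair_pen = pen,
                 period_type = c("affinity", "broken"),
                 mean_dev = c(mean(aff), mean(bro)),
                 sd_dev = c(sd(aff), sd(bro)), n_days = c(60L, 40L))
    }))
  }
  sm <- rbind(mk_sm("pen1", 15, 0.9), mk_sm("pen2", 15, 0),
              mk_sm("pen3", 15, 0), mk_sm("pen4", 15, 0))
  out <- pen_paired_test(sm)
  expect_equal(nrow(out), 5L)
  expect_true(all(out[testable == TRUE, p_holm >= p_raw]))
  idx <- out$testable
  expect_equal(out$p_holm[idx],
               stats::p.adjust(out$p_raw[idx], method = "holm"))
  expect_lt(out[pen_id == "pen1", p_holm], 0.05)
  # pooled SD equals the SD of concatenated residuals (oracle identity)
  one <- mk_sm("pen9", 4, 0.5)
  daily <- lapply(seq_len(4), function(i) rnorm(50))
  sm_o <- rbindlist(lapply(seq_len(4), function(i)
    data.table(cow_id = sprintf("C%d", i), partner_id = "x",
               pair_pen = "pen9", period_type = "affinity",
               mean_dev = mean(daily[[i]]), sd_dev = sd(daily[[i]]),
               n_days = 50L)))
  out_o <- pen_paired_test(sm_o)
  expect_equal(out_o[pen_id == "pen9", sd_affinity],
               sd(unlist(daily)))
  # overall row is present and untested
  expect_true(is.na(out[pen_id == "Overall", p_raw]))
})

test_that("Holm step-down matches hand computation", {
  # hand application: sort {0.008, 0.6, 0.7, 0.9}; multipliers 4,3,2,1;
  # running max, clipped at 1 -> {0.032, 1, 1, 1}
  hand_holm <- function(p) {
    o <- order(p)
    adj <- pmin(1, cummax((length(p) - seq_along(p) + 1) * p[o]))
    out <- numeric(length(p))
    out[o] <- adj
    out
  }
  p <- c(0.008, 0.9, 0.6, 0.7)
  expect_equal(hand_holm(p), c(0.032, 1, 1, 1))
  expect_equal(stats::p.adjust(p, method = "holm"), hand_holm(p))
  # monotone and bounded by Bonferroni on random p sets
  for (i in 1:10) {
    pr <- runif(sample(2:6, 1))
    h <- stats::p.adjust(pr, "holm")
    expect_true(all(h >= pr))
    expect_true(all(h <= pmin(1, length(pr) * pr)))
    expect_true(all(diff(h[order(pr)]) >= -1e-12))
  }
})

test_that("degenerate and underpowered pens are flagged untestable", {
  sm <- data.table(cow_id = c("C1", "C1", "C2", "C2"), partner_id = "x",
                   pair_pen = "pen1",
                   period_type = rep(c("affinity", "broken"), 2),
                   mean_dev = c(0.4, 0.4, 0.1, 0.1),   # all diffs zero
                   sd_dev = 0.5, n_days = 30L)
  out <- pen_paired_test(sm)
  expect_false(out[pen_id == "pen1", testable])
  sm1 <- sm[cow_id == "C1"]
  out1 <- pen_paired_test(sm1)
  expect_false(out1[pen_id == "pen1", testable])
})

test_that("DIM balance reports quartiles and the KS statistic", {
  pairs <- data.table(pen_id = "pen1", cow_a = "A", cow_b = "B")
  res <- mk_residency(list("A", "pen1", 1, 40), list("B", "pen1", 1, 20))
  lab <- label_periods(pairs, res)
  mk <- data.table(date = as.Date("2019-03-01") + 0:39, cow_id = "A",
                   pen_id = "pen1", yield_kg = 30, lactation_number = 1L,
                   dim = 1:40)
  bal <- dim_balance_check(lab[cow_id == "A"], mk)
  expect_equal(bal$ks_statistic, 1)       # disjoint DIM ranges
  # identical DIM sets give KS 0
  lab2 <- copy(lab[cow_id == "A"])
  lab2[, label := rep(c("affinity", "broken"), 20)]
  bal2 <- dim_balance_check(lab2, mk)
  expect_lt(bal2$ks_statistic, 0.06)
  expect_equal(nrow(bal$quartiles), 2L)
})

test_that("pen test is calibrated and powered on synthetic herds", {
  # power: a planted -0.6 kg/day shift is detected at alpha 0.05 in a
  # majority of small replicates (25 pairs/pen, cheap surrogate of the
  # full design)
  set.seed(19)
  rej <- replicate(20, {
    s <- sample.int(1e6, 1)
    cfg <- synthetic_config(n_pens = 1, cows_per_pen = 50, study_days = 150,
                            affinity_fraction = 1, follow_prob = 0,
                            passes_per_cow_day = 0.2, sd_affinity = 0.8,
                            sd_broken = 2.6, mean_shift_broken = -0.6,
                            residency_model = list(temporary_break_frac = 1),
                            seed = s)
    sim <- generate_herd(cfg)
    tr <- sim$truth
    mk <- merge(sim$milk, tr$wood_params[, .(cow_id, alpha, beta, gamma)],
                by = "cow_id")
    mk[, residual_kg := yield_kg - wood_curve(dim, alpha, beta, gamma)]
    per <- label_periods(tr$planted_pairs[, .(pen_id, cow_a, cow_b)],
                         sim$residency)
    smm <- summarize_deviation(mk[, .(cow_id, date, residual_kg)], per)
    eff <- pen_paired_test(smm)
    # hypothesised direction: affinity higher, so d > 0 under the shift
    eff[pen_id != "Overall", p_raw] < 0.05
  })
  expect_gte(mean(rej), 0.8)
})
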
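write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("gate events read sorted with malformed rows rejected", {
  f <- write_lines_tmp(c(
    "timestamp,cow_id,pen_id,destination",
    "2019-03-01T10:00:02,C2,pen1,feeding",
    "2019-03-01T10:00:01,C1,pen1,milking",
    "not-a-time,C3,pen1,feeding",
    "2019-03-01T09:59:59,C4,pen1,feeding"))
  expect_message(ev <- read_gate_events(f), "rejected 1")
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$cow_id, c("C4", "C1", "C2"))
  expect_equal(attr(ev, "n_rejected"), 1L)
})

test_that("a missing required column is an error", {
  f <- write_lines_tmp(c("timestamp,cow_id,destination",
                         "2019-03-01T10:00:00,C1,feeding"))
  expect_error(read_gate_events(f), "missing columns")
})

test_that("equal timestamps keep input order (stable sort)", {
  f <- write_lines_tmp(c(
    "timestamp,cow_id,pen_id,destination",
    "2019-03-01T10:00:00,C9,pen1,feeding",
    "2019-03-01T10:00:00,C1,pen1,feeding",
    "2019-03-01T10:00:00,C5,pen1,feeding"))
  ev <- read_gate_events(f)
  expect_equal(ev$cow_id, c("C9", "C1", "C5"))
})

test_that("duplicate milk rows collapse by summing and bad rows are dropped", {
  f <- write_lines_tmp(c(
    "date,cow_id,pen_id,yield_kg,lactation_number,dim",
    "2019-03-01,C1,pen1,20.1,2,100",
    "2019-03-01,C1,pen1,19.9,2,100",
    "2019-03-02,C1,pen1,-3,2,101",
    "2019-03-02,C2,pen1,31.5,1,50"))
  expect_warning(
    expect_message(mk <- read_milk_records(f), "rejected 1"),
    "collapsed")
  expect_equal(nrow(mk), 2L)
  expect_equal(mk[cow_id == "C1", yield_kg], 40.0)
})

test_that("residency inference bridges short silences and splits pen moves", {
  # one cow, events daily in pen1 for 10 days -> one 10-day interval
  secs <- (0:9) * 86400 + 3600
  ev <- make_events(secs, rep("C1", 10))
  r <- infer_residency(ev)
  expect_equal(nrow(r), 1L)
  expect_equal(as.integer(r$exit_date - r$entry_date) + 1L, 10L)

  # 5 days, 1 silent day, 5 days -> bridged into one 11-day interval
  secs2 <- c(0:4, 6:10) * 86400 + 3600
  r2 <- infer_residency(make_events(secs2, rep("C1", 10)))
  expect_equal(nrow(r2), 1L)
  expect_equal(as.integer(r2$exit_date - r2$entry_date) + 1L, 11L)

  # gap above max_silent_days splits
  secs3 <- c(0:4, 9:13) * 86400 + 3600
  r3 <- infer_residency(make_events(secs3, rep("C1", 10)),
                        max_silent_days = 3)
  expect_equal(nrow(r3), 2L)

  # a pen change always splits, even on consecutive days
  ev4 <- rbind(make_events((0:4) * 86400 + 10, rep("C1", 5), pen = "pen1"),
               make_events((5:9) * 86400 + 10, rep("C1", 5), pen = "pen2"))
  r4 <- infer_residency(ev4)
  expect_equal(nrow(r4), 2L)
  expect_equal(sort(r4$pen_id), c("pen1", "pen2"))
})

test_that("majority pen wins a split day, ties go to the first event", {
  ev <- rbind(
    make_events(c(10, 20, 30), rep("C1", 3), pen = "pen2"),
    make_events(c(15, 25), rep("C1", 2), pen = "pen1"))
  r <- infer_residency(ev)
  expect_equal(r$pen_id, "pen2")
  ev_tie <- rbind(make_events(c(10, 40), rep("C1", 2), pen = "pen2"),
                  make_events(c(20, 30), rep("C1", 2), pen = "pen1"))
  r2 <- infer_residency(ev_tie)
  expect_equal(r2$pen_id, "pen2")   # first event of the day is pen2
})

test_that("inferred residency matches ground truth on nearly all cow-days", {
  cfg <- synthetic_config(n_pens = 2, cows_per_pen = 15, study_days = 60,
                          seed = 12)
  sim <- generate_herd(cfg)
  inf <- infer_residency(sim$events)
  expand <- function(res) {
    d <- as.data.table(res)[, .(date = seq(entry_date, exit_date,
                                           by = "day")),
                            by = .(.r = seq_len(nrow(res)), cow_id, pen_id)]
    unique(paste(d$cow_id, d$pen_id, d$date))
  }
  truth_days <- expand(sim$residency)
  inf_days <- expand(inf)
  agreement <- length(intersect(inf_days, truth_days)) / length(truth_days)
  expect_gte(agreement, 0.95)
})

test_that("residency filter applies the strict 30-day rule everywhere", {
  res <- data.table(
    cow_id = c("C1", "C2", "C3", "C3"),
    pen_id = "pen1",
    entry_date = as.Date(c("2019-03-01", "2019-03-01", "2019-03-01",
                           "2019-05-01")),
    exit_date = as.Date(c("2019-03-29", "2019-03-30", "2019-03-15",
                          "2019-05-20")))
  # totals: C1 = 29 (excluded), C2 = 30 (kept), C3 = 15 + 20 = 35 (kept)
  ev <- make_events(c(1, 2, 3), c("C1", "C2", "C3"))
  mk <- data.table(date = as.Date("2019-03-02"),
                   cow_id = c("C1", "C2"), pen_id = "pen1", yield_kg = 30,
                   lactation_number = 1L, dim = 10L)
  out <- apply_residency_filter(res, events = ev, milk = mk)
  expect_equal(out$excluded, "C1")
  expect_false("C1" %in% out$residency$cow_id)
  expect_false("C1" %in% out$events$cow_id)
  expect_false("C1" %in% out$milk$cow_id)
  # idempotence
  again <- apply_residency_filter(out$residency, events = out$events,
                                  milk = out$milk)
  expect_equal(again$excluded, character(0))
  expect_identical(again$residency, out$residency)
})

test_that("planted short stays are exactly the excluded cows", {
  set.seed(31)
  long <- data.table(cow_id = sprintf("L%02d", 1:20), pen_id = "pen1",
                     entry_date = as.Date("2019-03-01"),
                     exit_date = as.Date("2019-03-01") + 59)
  short <- data.table(cow_id = sprintf("S%02d", 1:10), pen_id = "pen1",
                      entry_date = as.Date("2019-03-01"),
                      exit_date = as.Date("2019-03-01") +
                        sample(0:28, 10, replace = TRUE))
  out <- apply_residency_filter(rbind(long, short))
  expect_setequal(out$excluded, short$cow_id)
})

test_that("monthly gate counts partition the event total", {
  ev <- make_events(c(1, 2, 3) * 3600, c("C1", "C2", "C3"))
  ev$timestamp <- as.POSIXct("2019-03-10", tz = "UTC") + c(1, 2, 3)
  mc <- monthly_gate_counts(ev)
  expect_equal(mc[month == "2019-03", n], 3L)
  expect_equal(sum(mc$n), 3L)

  ev2 <- rbind(
    make_events(1:60, sprintf("C%02d", 1:60 %% 7)),
    within(make_events(1:40, sprintf("C%02d", 1:40 %% 7)), {
      timestamp <- timestamp + 40 * 86400
    }))
  mc2 <- monthly_gate_counts(ev2)
  expect_equal(sum(mc2$n), 100L)
  expect_setequal(mc2$n[mc2$n > 0], c(60L, 40L))
  # months inside the span with no events appear as zero
  ev3 <- make_events(c(1, 100 * 86400), c("C1", "C1"))
  mc3 <- monthly_gate_counts(ev3)
  expect_true(any(mc3$n == 0L))
  expect_equal(sum(mc3$n), 2L)
})

test_that("dim/lactation inconsistencies are flagged, not fixed", {
  mk <- data.table(
    date = as.Date("2019-03-01") + 0:3,
    cow_id = "C1", pen_id = "pen1", yield_kg = 30,
    lactation_number = c(2L, 2L, 2L, 1L),
    dim = c(100L, 101L, 103L, 1L))
  flags <- validate_milk_records(mk)
  expect_true("dim_not_advancing_with_date" %in% flags$problem)
  expect_true("lactation_number_decreased" %in% flags$problem)
})
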
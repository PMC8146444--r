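# Readers and validators for the three CSV schemas (gate events, daily milk
# records, pen residency), residency inference from the event stream, the
# minimum-residency filter, and per-pen monthly traffic counts.

#' Read sort-gate events
#'
#' Reads a `gate_events.csv` file (columns `timestamp, cow_id, pen_id,
#' destination`), rejects malformed rows (unparseable timestamp, empty cow or
#' pen id) with a message, and returns events sorted by timestamp within pen,
#' stable on input order for equal timestamps.
#'
#' @param path CSV file path.
#' @return a `data.table` of events with attribute `n_rejected`.
#' @export
read_gate_events <- function(path) {
  dt <- suppressWarnings(
    fread(path, colClasses = list(character = c("timestamp", "cow_id",
                                                "pen_id"))))
  req <- c("timestamp", "cow_id", "pen_id", "destination")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("gate events file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_in <- nrow(dt)
  if (n_in == 0L) {
    out <- data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                      cow_id = character(), pen_id = character(),
                      destination = character())
    setattr(out, "n_rejected", 0L)
    return(out)
  }
  ts <- as.POSIXct(strptime(dt$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  retry <- is.na(ts)
  if (any(retry))
    ts[retry] <- as.POSIXct(strptime(dt$timestamp[retry],
                                     "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  ok <- !is.na(ts) & nzchar(dt$cow_id) & nzchar(dt$pen_id)
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message(sprintf("read_gate_events: rejected %d malformed row(s) of %d",
                    n_rej, n_in))
  out <- dt[ok, .(timestamp = ts[ok], cow_id, pen_id,
                  destination = as.character(destination))]
  out[, .row := .I]
  setorder(out, pen_id, timestamp, .row)
  out[, .row := NULL]
  setattr(out, "n_rejected", n_rej)
  out[]
}

#' Read daily milk records
#'
#' Reads a `milk_records.csv` file (columns `date, cow_id, pen_id, yield_kg,
#' lactation_number, dim`).  Rows with an unparseable date, empty ids, or a
#' negative yield are rejected with a message; duplicate (cow, date) rows are
#' collapsed by summing their yields with a warning (partial daily totals).
#'
#' @param path CSV file path.
#' @return a `data.table` of daily records with attribute `n_rejected`.
#' @export
read_milk_records <- function(path) {
  dt <- suppressWarnings(
    fread(path, colClasses = list(character = c("cow_id", "pen_id"))))
  req <- c("date", "cow_id", "pen_id", "yield_kg", "lactation_number", "dim")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("milk records file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_in <- nrow(dt)
  d <- as.Date(as.character(dt$date), optional = TRUE)
  y <- suppressWarnings(as.numeric(dt$yield_kg))
  ok <- !is.na(d) & nzchar(dt$cow_id) & nzchar(dt$pen_id) & !is.na(y) & y >= 0
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message(sprintf("read_milk_records: rejected %d malformed row(s) of %d",
                    n_rej, n_in))
  out <- dt[ok, .(date = d[ok], cow_id, pen_id, yield_kg = y[ok],
                  lactation_number = as.integer(lactation_number),
                  dim = as.integer(dim))]
  dup <- anyDuplicated(out, by = c("cow_id", "date"))
  if (dup) {
    warning("duplicate (cow, date) milk rows collapsed by summing yields",
            call. = FALSE)
    out <- out[, .(pen_id = pen_id[1L], yield_kg = sum(yield_kg),
                   lactation_number = lactation_number[1L], dim = dim[1L]),
               by = .(cow_id, date)]
    setcolorder(out, c("date", "cow_id", "pen_id", "yield_kg",
                       "lactation_number", "dim"))
  }
  setorder(out, cow_id, date)
  setattr(out, "n_rejected", n_rej)
  out[]
}

#' Read an explicit residency table
#'
#' @param path CSV with columns `cow_id, pen_id, entry_date, exit_date`
#'   (exit inclusive).
#' @return a `data.table` of residency intervals.
#' @export
read_residency <- function(path) {
  dt <- suppressWarnings(
    fread(path, colClasses = list(character = c("cow_id", "pen_id"))))
  req <- c("cow_id", "pen_id", "entry_date", "exit_date")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("residency file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- dt[, .(cow_id, pen_id, entry_date = as.Date(as.character(entry_date)),
                exit_date = as.Date(as.character(exit_date)))]
  if (any(out$exit_date < out$entry_date))
    stop("residency intervals with exit before entry", call. = FALSE)
  setorder(out, cow_id, entry_date)
  out[]
}

#' Infer pen residency from the gate-event stream
#'
#' Each cow-day with at least one event is assigned the pen holding the
#' majority of that day's events (ties broken by the pen of the day's first
#' event).  Residency intervals are maximal runs of same-pen days, bridging
#' event-free gaps of up to `max_silent_days`; a pen change always splits an
#' interval.
#'
#' @param events a gate-event table (as from [read_gate_events()]).
#' @param max_silent_days largest run of event-free days bridged into an
#'   interval.
#' @return a `data.table` of residency intervals (`cow_id, pen_id,
#'   entry_date, exit_date`).
#' @export
infer_residency <- function(events, max_silent_days = 3L) {
  if (nrow(events) == 0L)
    return(data.table(cow_id = character(), pen_id = character(),
                      entry_date = as.Date(character()),
                      exit_date = as.Date(character())))
  ev <- as.data.table(events)[, .(cow_id, pen_id,
                                  day = as.Date(timestamp, tz = "UTC"),
                                  ord = .I)]
  # Majority pen per cow-day; tie -> pen of the day's first event.
  byday <- ev[, .(n = .N, first_ord = min(ord)), by = .(cow_id, day, pen_id)]
  setorder(byday, cow_id, day, -n, first_ord)
  byday <- byday[, .SD[1L], by = .(cow_id, day)]
  setorder(byday, cow_id, day)
  byday[, gap := c(1L, as.integer(diff(day))), by = cow_id]
  byday[, pen_change := pen_id != shift(pen_id, fill = pen_id[1L]),
        by = cow_id]
  byday[, new_run := gap > max_silent_days + 1L | pen_change]
  byday[, run := cumsum(new_run) , by = cow_id]
  out <- byday[, .(pen_id = pen_id[1L], entry_date = min(day),
                   exit_date = max(day)), by = .(cow_id, run)]
  out[, run := NULL]
  setorder(out, cow_id, entry_date)
  out[]
}

#' Apply the minimum-residency filter
#'
#' Cows whose total residency across all intervals is below `min_days` are
#' removed from the residency table and, when supplied, from the event and
#' milk tables as well.  The reference analysis discarded cows with less
#' than 30 days in a pen.
#'
#' @param residency residency interval table.
#' @param events optional gate-event table to filter alongside.
#' @param milk optional milk-record table to filter alongside.
#' @param min_days minimum total days of residency to retain a cow.
#' @return list with `residency`, `events`, `milk` (filtered or NULL) and
#'   `excluded` (character vector of removed cow ids).
#' @export
apply_residency_filter <- function(residency, events = NULL, milk = NULL,
                                   min_days = 30L) {
  res <- as.data.table(residency)
  tot <- res[, .(days = sum(as.integer(exit_date - entry_date) + 1L)),
             by = cow_id]
  excluded <- sort(tot[days < min_days, cow_id])
  list(residency = res[!cow_id %in% excluded],
       events = if (!is.null(events))
         as.data.table(events)[!cow_id %in% excluded] else NULL,
       milk = if (!is.null(milk))
         as.data.table(milk)[!cow_id %in% excluded] else NULL,
       excluded = excluded)
}

#' Per-pen monthly gate-passage counts
#'
#' Counts events per pen and calendar month over the full span of the data;
#' months inside the span with no events are reported as zero.
#'
#' @param events gate-event table.
#' @return `data.table` with columns `pen_id, month` (\"YYYY-MM\") and `n`.
#' @export
monthly_gate_counts <- function(events) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0L)
    return(data.table(pen_id = character(), month = character(),
                      n = integer()))
  ev[, month := month_key(timestamp)]
  counts <- ev[, .(n = .N), by = .(pen_id, month)]
  mrange <- range(as.Date(paste0(counts$month, "-01")))
  all_months <- format(seq(mrange[1], mrange[2], by = "month"), "%Y-%m")
  grid <- CJ(pen_id = unique(ev$pen_id), month = all_months)
  out <- counts[grid, on = c("pen_id", "month")]
  out[is.na(n), n := 0L]
  setorder(out, pen_id, month)
  out[]
}

#' Flag DIM / lactation bookkeeping inconsistencies
#'
#' Reports (never fixes) records where days in milk does not advance by one
#' day per calendar day within a cow's lactation, or where lactation number
#' decreases over time.
#'
#' @param milk milk-record table.
#' @return `data.table` of flagged rows with a `problem` column.
#' @export
validate_milk_records <- function(milk) {
  mk <- as.data.table(milk)
  setorder(mk, cow_id, date)
  mk[, `:=`(d_date = as.integer(date - shift(date)),
            d_dim = dim - shift(dim),
            d_lact = lactation_number - shift(lactation_number)),
     by = cow_id]
  bad_dim <- mk[d_lact == 0 & !is.na(d_date) & d_dim != d_date]
  bad_lact <- mk[!is.na(d_lact) & d_lact < 0]
  out <- rbind(bad_dim[, problem := "dim_not_advancing_with_date"],
               bad_lact[, problem := "lactation_number_decreased"])
  out[, c("d_date", "d_dim", "d_lact") := NULL]
  out[]
}
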
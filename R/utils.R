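# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats rnorm rpois runif rlnorm sd quantile setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Make a sorted integer vector strictly increasing with minimal bumps:
# out[i] = max(x[i], out[i-1] + 1).  Identity cummax(x - i) + i.
strictly_increasing <- function(x) {
  if (length(x) == 0L) return(x)
  i <- seq_along(x)
  cummax(x - i) + i
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}

# Deterministic radix (C-locale) ordering for character ids.
id_order <- function(...) order(..., method = "radix")

# Canonical unordered pair: cow_a < cow_b in C-locale.
canonical_pairs <- function(a, b) {
  swap <- a > b
  list(cow_a = ifelse(swap, b, a), cow_b = ifelse(swap, a, b))
}

fmt_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

month_key <- function(ts) format(ts, "%Y-%m", tz = "UTC")
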
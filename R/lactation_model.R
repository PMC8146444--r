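# Wood's lactation curve fitted per cow and lactation: the expected daily
# milk production that each cow's observed yields are compared against.

#' Wood's lactation curve
#'
#' `Y(t) = alpha * t^beta * exp(-gamma * t)`: the classical gamma-shaped
#' lactation curve, rising to a peak at `t = beta / gamma` days in milk and
#' decaying thereafter.
#'
#' @param t days in milk (>= 1).
#' @param alpha scale (kg/day at the curve's unit point).
#' @param beta dimensionless rise exponent (> 0).
#' @param gamma decay rate per day (>= 0).
#' @return expected daily yield (kg) at each `t`.
#' @export
wood_curve <- function(t, alpha, beta, gamma) {
  alpha * t^beta * exp(-gamma * t)
}

#' Fit Wood's curve to one cow-lactation
#'
#' Minimises the residual sum of squares of daily yields against the Wood
#' curve by bounded nonlinear least squares (Levenberg-Marquardt), starting
#' from the log-linearised ordinary least squares solution of
#' `ln Y = ln alpha + beta ln t - gamma t`.  Records at DIM 0 and zero
#' yields are excluded from the log-linear start (zero yields also from the
#' fit); groups with fewer than `min_obs` usable records are skipped.
#'
#' @param dim integer days in milk of the records.
#' @param yield_kg observed daily yields (kg).
#' @param min_obs minimum usable records for a fit.
#' @param bounds list with `lower` and `upper` numeric length-3 vectors for
#'   `(alpha, beta, gamma)`.
#' @return one-row `data.table`: `alpha, beta, gamma, n_obs, rss, converged`.
#'   Skipped groups return `converged = FALSE` with `NA` parameters.
#' @export
fit_wood <- function(dim, yield_kg, min_obs = 5L,
                     bounds = list(lower = c(1e-6, 1e-6, 0),
                                   upper = c(200, 3, 0.5))) {
  keep <- !is.na(dim) & !is.na(yield_kg) & dim >= 1 & yield_kg > 0
  t <- as.numeric(dim[keep])
  y <- as.numeric(yield_kg[keep])
  skipped <- data.table(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                        n_obs = length(t), rss = NA_real_, converged = FALSE)
  if (length(t) < min_obs) return(skipped)

  # Log-linear initialisation, clamped into bounds.
  ll <- unname(stats::lm.fit(cbind(1, log(t), -t), log(y))$coefficients)
  start <- c(alpha = exp(ll[1]), beta = ll[2], gamma = ll[3])
  start <- pmin(pmax(start, bounds$lower + 1e-9), bounds$upper - 1e-9)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ alpha * t^beta * exp(-gamma * t),
      start = list(alpha = start[[1]], beta = start[[2]],
                   gamma = start[[3]]),
      lower = bounds$lower, upper = bounds$upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(skipped)
  cf <- stats::coef(fit)
  # A fit pinned into a degenerate corner of the box (vanishing scale with
  # maximal rise and decay) is a failed fit, not a lactation curve.
  pinned <- cf[["alpha"]] <= bounds$lower[1] * 2 &&
    cf[["beta"]] >= bounds$upper[2] - 1e-6 &&
    cf[["gamma"]] >= bounds$upper[3] - 1e-6
  if (pinned) return(skipped)
  data.table(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
             gamma = unname(cf["gamma"]), n_obs = length(t),
             rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' Fit Wood's curve for every cow-lactation in a milk table
#'
#' The final baseline model varies `(alpha, beta, gamma)` freely for every
#' cow and lactation combination — deliberately on the overfitting side, so
#' deviations attributed to broken affinity periods are conservative.  An
#' optional shrinkage step refits sparse groups (fewer than `shrink_n`
#' records) with `(beta, gamma)` held at the pen's mean converged values and
#' only `alpha` free (closed-form least squares), stabilising thin curves.
#'
#' @param milk milk-record table (`date, cow_id, pen_id, yield_kg,
#'   lactation_number, dim`).
#' @param min_obs minimum records per cow-lactation.
#' @param shrink_sparse enable the sparse-group shrinkage refit.
#' @param shrink_n group size below which shrinkage applies.
#' @return `data.table` of fits: `cow_id, lactation_number, pen_id, alpha,
#'   beta, gamma, n_obs, rss, converged`.
#' @export
fit_lactations <- function(milk, min_obs = 5L, shrink_sparse = FALSE,
                           shrink_n = 30L) {
  mk <- as.data.table(milk)
  setorder(mk, cow_id, lactation_number, date)
  fits <- mk[, c(list(pen_id = pen_id[1L]),
                 fit_wood(dim, yield_kg, min_obs = min_obs)),
             by = .(cow_id, lactation_number)]
  if (shrink_sparse) {
    pen_means <- fits[converged == TRUE,
                      .(beta_m = mean(beta), gamma_m = mean(gamma)),
                      by = pen_id]
    small <- fits[converged == TRUE & n_obs < shrink_n]
    if (nrow(small) && nrow(pen_means)) {
      for (r in seq_len(nrow(small))) {
        pm <- pen_means[pen_id == small$pen_id[r]]
        if (!nrow(pm)) next
        g <- mk[cow_id == small$cow_id[r] &
                  lactation_number == small$lactation_number[r] &
                  yield_kg > 0 & dim >= 1]
        f <- wood_curve(g$dim, 1, pm$beta_m, pm$gamma_m)
        a <- sum(g$yield_kg * f) / sum(f^2)
        fits[cow_id == small$cow_id[r] &
               lactation_number == small$lactation_number[r],
             `:=`(alpha = a, beta = pm$beta_m, gamma = pm$gamma_m,
                  rss = sum((g$yield_kg - a * f)^2))]
      }
    }
  }
  fits[]
}

#' Daily deviations from the fitted Wood curve
#'
#' For every milk record of a converged cow-lactation fit, the deviation
#' `observed - expected` (kg/day) of the day's yield from the cow's fitted
#' lactation curve: positive when the cow over-produces for her lactation
#' and stage of lactation.  Days without records are absent, not zero.
#'
#' @param milk milk-record table.
#' @param fits output of [fit_lactations()].
#' @return `data.table`: `cow_id, pen_id, date, dim, lactation_number,
#'   observed_kg, expected_kg, residual_kg`.
#' @export
lactation_residuals <- function(milk, fits) {
  mk <- as.data.table(milk)
  f <- as.data.table(fits)[converged == TRUE,
                           .(cow_id, lactation_number, alpha, beta, gamma)]
  out <- f[mk, on = c("cow_id", "lactation_number"), nomatch = NULL]
  out[, expected_kg := wood_curve(dim, alpha, beta, gamma)]
  out <- out[, .(cow_id, pen_id, date, dim, lactation_number,
                 observed_kg = yield_kg, expected_kg,
                 residual_kg = yield_kg - expected_kg)]
  setorder(out, cow_id, date)
  out[]
}
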
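#!/usr/bin/env Rscript
# Stage 4 -- expected-production baselines.
#
# Fits Wood's lactation curve Y(t) = alpha t^beta exp(-gamma t) to every
# cow x lactation combination by bounded nonlinear least squares and
# computes each day's deviation of observed from expected yield.  These
# deviations are the outcome the affinity contrast is run on.

suppressMessages({
  library(herdaffinity)
  library(data.table)
})

milk <- read_milk_records("results/data/milk_records.csv")
residency <- read_residency("results/data/residency.csv")
milk <- apply_residency_filter(residency, milk = milk, min_days = 30)$milk

fits <- fit_lactations(milk, min_obs = 5)
fwrite(fits, "results/fits.csv")
message(sprintf("fitted %d cow-lactation groups: %d converged, %d skipped",
                nrow(fits), sum(fits$converged), sum(!fits$converged)))
cv <- fits[converged == TRUE]
message(sprintf("parameter ranges: alpha %.1f-%.1f, beta %.2f-%.2f, gamma %.4f-%.4f",
                min(cv$alpha), max(cv$alpha), min(cv$beta), max(cv$beta),
                min(cv$gamma), max(cv$gamma)))

resid <- lactation_residuals(milk, fits)
fwrite(resid, "results/residuals.csv")
message(sprintf("daily deviations: %d days, mean %+.3f kg, SD %.2f kg",
                nrow(resid), mean(resid$residual_kg),
                sd(resid$residual_kg)))
message("wrote results/fits.csv, results/residuals.csv")
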
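#!/usr/bin/env Rscript
# Stage 2 -- affinity scoring and social-network metrics.
#
# Reads the gate-event log, applies the <30-day residency filter, scores
# each pen's pairwise affinities with the lag-sequence method (exponential
# decay over the previous 4 passages) weighted by monthly gate traffic and
# normalised by pen residency, and summarises each pen's weighted network.

suppressMessages({
  library(herdaffinity)
  library(data.table)
})

events <- read_gate_events("results/data/gate_events.csv")
residency <- read_residency("results/data/residency.csv")

flt <- apply_residency_filter(residency, events = events, min_days = 30)
message(sprintf("residency filter: excluded %d cow(s) with < 30 days",
                length(flt$excluded)))

spec <- scoring_spec("lag_sequence", apply_month_weights = TRUE,
                     apply_residency_norm = TRUE)
nets <- score_affinity(flt$events, spec, residency = flt$residency)

scores <- rbindlist(lapply(nets, network_edges))
fwrite(scores, "results/scores.csv")

metrics <- metrics_table(lapply(nets, compute_metrics))
fwrite(metrics, "results/metrics.csv")
message("per-pen network metrics:")
for (i in seq_len(nrow(metrics)))
  message(sprintf(
    "  %s: %d cows, %d edges, density %.2f, degree max/mean %d/%.0f",
    metrics$pen_id[i], metrics$n_nodes[i], metrics$n_edges[i],
    metrics$density[i], metrics$degree_max[i], metrics$degree_mean[i]))
message("wrote results/scores.csv, results/metrics.csv")
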
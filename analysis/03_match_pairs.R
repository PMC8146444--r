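#!/usr/bin/env Rscript
# Stage 3 -- exclusive maximum-affinity pairs.
#
# Rebuilds each pen's scored network and matches cows into exclusive pairs:
# Irving's stable-roommates algorithm on the score-derived preferences,
# falling back to maximum-weight (blossom) matching if no stable matching
# exists.  Zero-score pairs are excluded.  Recovery is then checked against
# the generator's planted pairs.

suppressMessages({
  library(herdaffinity)
  library(data.table)
})

scores <- fread("results/scores.csv")
pairs <- rbindlist(lapply(split(scores, scores$pen_id), function(e)
  stepwise_match(network_from_edges(e))))
fwrite(pairs, "results/pairs.csv")

message(sprintf("matched %d exclusive pairs across %d pens (%s)",
                nrow(pairs), length(unique(pairs$pen_id)),
                paste(unique(pairs$algorithm), collapse = "+")))

gt <- jsonlite::read_json("results/data/ground_truth.json",
                          simplifyVector = TRUE)
planted <- as.data.table(gt$planted_pairs)
hit <- nrow(merge(planted[, .(pen_id, cow_a, cow_b)],
                  pairs[, .(pen_id, cow_a, cow_b)],
                  by = c("pen_id", "cow_a", "cow_b")))
message(sprintf("planted-pair recovery: %d / %d (%.0f%%)", hit,
                nrow(planted), 100 * hit / nrow(planted)))
message("wrote results/pairs.csv")
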
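#!/usr/bin/env Rscript
# Stage 3: burst segmentation, lag fit and functional-network construction.
#
# Reads the event tables from stage 1, splits them into bursts at the
# 200 ms cut-off, fits the culture-specific Gaussian lag width sigma,
# builds the delay-weighted directed networks, and screens the cut-off
# for stability of the burst partition (variation of information).

suppressPackageStartupMessages(library(burstnet))
dir.create("results", showWarnings = FALSE)

for (nm in c("planted", "clustered", "homogeneous")) {
  train <- read_events(sprintf("results/%s_events.tsv", nm))
  bursts <- segment_bursts(train, 0.2)
  lagm <- fit_lag_model(bursts)
  net <- build_functional_network(bursts, lagm, 0.2)
  write_network(net, sprintf("results/%s_functional.edgelist", nm))
  sidecar <- list(
    dataset = nm, cutoff_s = 0.2, sigma_s = lagm$sigma,
    sigma_method = lagm$fit_method, n_bursts = length(bursts),
    burst_size_histogram = as.list(table(vapply(bursts, nrow, integer(1)))),
    n_nodes = length(net$nodes), n_links = n_links(net))
  jsonlite::write_json(sidecar, sprintf("results/%s_network.json", nm),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d bursts, sigma = %.1f ms, network %d nodes / %d links\n",
              nm, length(bursts), 1000 * lagm$sigma, length(net$nodes),
              n_links(net)))
}

train <- read_events("results/planted_events.tsv")
cs <- cutoff_sensitivity(train, seq(0.05, 0.5, by = 0.025))
utils::write.table(cs, "results/cutoff_sensitivity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("cut-off screen: partition stabilizes from %.3g s (VI = 0 beyond)\n",
            attr(cs, "plateau_start")))
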
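#!/usr/bin/env Rscript
# Representational generality: 20-dim bottlenecked linear encoders from
# the embedding space to each representation, n^2 linear transfer
# decoders, per-target tournament matrices, and the averaged generality
# and single-target transfer scores.
suppressPackageStartupMessages(library(langenc))

dir.create("results/04_generality", recursive = TRUE, showWarnings = FALSE)
res <- run_pipeline(list(encoding = list(enabled = FALSE),
                         nwp = list(enabled = FALSE),
                         varpart = list(enabled = FALSE)),
                    outdir = "results/04_generality", seed = 1)

m <- res$metric_table
cov <- vapply(res$truth$rep_coverage, function(x) length(x$used_factors),
              integer(1))
best <- m$rep_id[which.max(m$generality)]
cat(sprintf("\ngenerality scores span [%.2f, %.2f]; top representation: %s (%d factors)\n",
            min(m$generality), max(m$generality), best, cov[[best]]))
cat(sprintf("mean score by coverage: %s\n",
            paste(sprintf("%d:%.2f", sort(unique(cov)),
                          tapply(m$generality, cov, mean)), collapse = "  ")))
cat(sprintf("transfer target: %s\n", res$generality$transfer_target))
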
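#!/usr/bin/env Rscript
# Compound-library triage: apply the six-descriptor filter (MW < 553 Da,
# rotatable bonds <= 14, donors <= 6, acceptors >= 3, PSA >= 30 A^2,
# logP >= -0.5) and keep docking scores of -8 or lower, ranked.

suppressMessages(library(pocketscan))

set.seed(2026)
n <- 500
library_tab <- data.frame(
  id = sprintf("NC%05d", seq_len(n)),
  mw = round(runif(n, 150, 800), 1),
  rot_bonds = sample(0:22, n, replace = TRUE),
  hbd = sample(0:9, n, replace = TRUE),
  hba = sample(0:10, n, replace = TRUE),
  psa = round(runif(n, 0, 160), 1),
  logp = round(runif(n, -4, 7), 2),
  score = round(rnorm(n, -6.5, 1.6), 2)
)
write.csv(library_tab, "results/library_descriptors.csv", row.names = FALSE)

filt <- filter_library(library_tab)
cat(sprintf("descriptor filter: %d of %d compounds pass\n", filt$n_pass, n))
cat("rejections per criterion (a compound can violate several):\n")
print(filt$rejections)

hits <- filter_by_score(filt$passing, threshold = -8)
cat(sprintf("docking-score cutoff at -8: %d ranked hits; best: %s (%.2f)\n",
            nrow(hits), if (nrow(hits)) hits$id[1] else "none",
            if (nrow(hits)) hits$score[1] else NA))
write.csv(hits, "results/screening_hits.csv", row.names = FALSE)
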
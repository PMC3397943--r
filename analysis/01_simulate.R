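#!/usr/bin/env Rscript
# Build the synthetic two-state benchmark every downstream step runs on:
# 60 C-alpha conformers (30 GDP-like, 30 GTP-like) separated along a planted
# switch-region mode, state-dependent probe poses over a planted pocket, and
# an alignment with known conserved, diverse and gappy columns.

suppressMessages(library(pocketscan))

out_dir <- "results/benchmark"
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# 120 columns: 30 invariant, 60 two-letter mixes, 20 near-uniform, 10 gappy
cols <- c(
  lapply(1:30, function(i) stats::setNames(1, AA20[(i %% 20) + 1])),
  lapply(1:60, function(i) {
    l <- AA20[c((i %% 20) + 1, ((i + 7) %% 20) + 1)]
    stats::setNames(c(0.7, 0.3), l)
  }),
  lapply(1:20, function(i) stats::setNames(rep(1 / 21, 21), c(AA20, "-"))),
  lapply(1:10, function(i) stats::setNames(c(0.6, 0.4), c("G", "-")))
)

spec <- synthetic_spec(alignment_columns = cols, n_seq = 300, seed = 2026)
manifest <- write_synthetic_benchmark(spec, out_dir)

cat("benchmark written under", out_dir, "\n")
cat("  structures:", 2 * 30, "(30 per state), residues:", spec$n_residues, "\n")
cat("  planted switch block:", min(spec$switch_block), "-",
    max(spec$switch_block), "; planted pocket:", min(spec$pocket), "-",
    max(spec$pocket), "\n")
cat("  probe presence probability GDP/GTP:",
    paste(spec$probe_prob, collapse = " / "), "\n")
cat("  alignment: ", spec$n_seq, "rows x", length(cols), "columns\n")
# everything on disk is plain text and re-derives from seed 2026
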
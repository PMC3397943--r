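#!/usr/bin/env Rscript
# Sequence conservation of the benchmark alignment (21- and 7-letter Shannon
# entropy, gap masking, conserved calls) and solvent exposure of the ensemble
# (Shrake-Rupley SASA, relative exposure vs the reference maxima).

suppressMessages(library(pocketscan))

aln <- read_alignment("results/benchmark/alignment.fasta")
prof <- conservation_profile(aln)
cat(sprintf("alignment: %d rows x %d columns; %d masked (>30%% gaps), %d conserved (C21 or C7 > 0.6)\n",
            aln$n_seq, aln$n_col, sum(prof$masked), sum(prof$conserved)))
# generative design: columns 1-30 invariant, 31-90 two-letter, 91-110 uniform,
# 111-120 gappy
cat(sprintf("  conserved among invariant columns 1-30: %d/30; among uniform columns 91-110: %d/20\n",
            sum(prof$conserved[1:30]), sum(prof$conserved[91:110])))
write.csv(prof, "results/conservation.csv", row.names = FALSE)

ens <- read_ensemble_manifest("results/benchmark/manifest.tsv")
# exposure over a 10-member subsample keeps this step inside a few seconds
subset <- ens$structures[seq(1, length(ens$structures), by = 6)]
exposures <- lapply(subset, function(s) relative_exposure(sasa(s)))
eprof <- exposure_profile(exposures)
cat(sprintf("exposure over %d structures: mean %.0f%%, %d residues exposed (>40%%) in every member\n",
            length(subset), mean(eprof$mean_percent),
            sum(vapply(split(eprof$mean_percent, eprof$label), min, 1) > 40)))
write.csv(eprof, "results/exposure.csv", row.names = FALSE)
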
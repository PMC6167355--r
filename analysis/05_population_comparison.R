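#!/usr/bin/env Rscript

# Stage 5 — inter-population comparison machinery.
#
# The survey's reference populations are external publications, so the
# comparison stage is exercised on synthetic populations: a focal population
# (the simulated cohort's pooled frequencies) plus reference populations
# diverged from it under the Balding-Nichols model at two levels, forming
# two clusters. Nei distances, PCA, MDS and the NJ tree are written under
# results/comparison/, both for the full 19-locus panel and for the 11-locus
# overlap preset.

suppressMessages(library(xstrpop))

seed <- 20181001
out <- "results/comparison"

focal <- read_frequency_table("results/cohort/freq_pooled.csv")
anc <- lapply(focal$tab, function(d) setNames(d$freq, d$allele))

near <- simulate_divergent_populations(
  synthetic_spec(0, 0, anc, n_populations = 4, fst_divergence = 0.01,
                 seed = seed + 1))
far <- simulate_divergent_populations(
  synthetic_spec(0, 0, anc, n_populations = 4, fst_divergence = 0.15,
                 seed = seed + 2))
tables <- c(list(focal = focal),
            setNames(near, paste0("near", 1:4)),
            setNames(far, paste0("far", 1:4)))

cmp <- compare_populations(tables, components = 3)
write_comparison_bundle(cmp, out)
d <- cmp$distances
cat("Nei distances: focal vs near cluster",
    sprintf("%.4f-%.4f", min(d["focal", paste0("near", 1:4)]),
            max(d["focal", paste0("near", 1:4)])),
    "; focal vs far cluster",
    sprintf("%.4f-%.4f", min(d["focal", paste0("far", 1:4)]),
            max(d["focal", paste0("far", 1:4)])), "\n")
cat("PCA: first three components explain",
    sprintf("%.3f%%", sum(cmp$pca$pct_variance[1:3])),
    "of the variance\n")
cat("MDS stress-1:", sprintf("%.4f", cmp$mds$stress), "\n")

cmp11 <- compare_populations(tables, loci = argus_overlap_loci(),
                             components = 3)
write_comparison_bundle(cmp11, file.path(out, "overlap11"))
cat("11-locus preset: mean Nei distance",
    sprintf("%.4f", mean(cmp11$distances[upper.tri(cmp11$distances)])),
    "vs", sprintf("%.4f", mean(d[upper.tri(d)])), "for 19 loci\n")
cat("wrote", out, "\n")
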
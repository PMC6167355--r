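#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# No raw casework genotypes are distributable, so the whole pipeline runs on
# a synthetic cohort with the survey's design: 265 females + 248 males typed
# at the 19 panel X-STRs (778 X chromosomes per locus), linkage-group
# haplotype structure inside the seven canonical groups, and microvariant
# allele labels. Writes the genotype table, the generating truth record and
# the three stratified allele-frequency tables under results/cohort/.

suppressMessages(library(xstrpop))

seed <- 20181001
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

g <- gelao_like_fixture(seed = seed)
cat("simulated cohort:", length(g$sample_id), "samples,",
    length(g$loci), "loci;",
    "chromosomes per locus:", unique(chromosome_counts(g)), "\n")

write_genotypes(g, file.path(out, "genotypes.csv"))
truth <- attr(g, "truth")
jsonlite::write_json(
  list(seed = seed, n_females = truth$n_females, n_males = truth$n_males,
       loci = lapply(truth$loci, as.list),
       linkage_groups = lapply(truth$linkage_groups, function(lg)
         list(loci = lg$loci, n_haplotypes = nrow(lg$haplotypes)))),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

for (stratum in c("pooled", "female", "male")) {
  fr <- allele_frequencies(g, stratum)
  write_frequency_table(fr, file.path(out, paste0("freq_", stratum, ".csv")))
  cat(sprintf("%-7s stratum: %d-%d alleles per locus, N = %d-%d\n", stratum,
              min(vapply(fr$tab, nrow, integer(1))),
              max(vapply(fr$tab, nrow, integer(1))),
              min(fr$N), max(fr$N)))
}
cat("wrote", out, "\n")
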
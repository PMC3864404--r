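#!/usr/bin/env Rscript
# Intra-sample clonal diversity: purity- and copy-number-adjusted cellular
# frequencies per mutation, summarized per sample as the interquartile
# range. Samples dominated by a single clone with clonal mutations score
# near zero; clone mixtures score high.

suppressMessages(library(clonescape))

rows <- list()
for (i in 1:6) {
  outdir <- file.path("results", "cases", sprintf("case%d", i))
  counts <- read_amplicon_counts(file.path(outdir, "counts.tsv"))
  profiles <- read_segments(file.path(outdir, "segments.tsv"))
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  comp <- truth$compositions
  tc <- vapply(split(comp$tumour_content, comp$sample_id), `[`,
               numeric(1), 1L)
  pm <- call_presence(counts)
  sites <- unique(counts[c("mutation_id", "chrom", "pos")])
  freqs <- suppressWarnings(
    estimate_cellular_frequencies(pm, sites, profiles, tc))
  div <- sample_diversity(freqs)
  div <- cbind(case = sprintf("case%d", i), div)
  write.csv(freqs, file.path(outdir, "cellular_frequencies.csv"),
            row.names = FALSE)
  rows[[i]] <- div
}
diversity <- do.call(rbind, rows)
write.csv(diversity, "results/diversity.csv", row.names = FALSE)
print(diversity, row.names = FALSE)
cat(sprintf("IQR range across cohort: %.3f (min) to %.3f (max)\n",
            min(diversity$iqr), max(diversity$iqr)))
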
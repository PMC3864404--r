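#!/usr/bin/env Rscript
# Plasma ctDNA detection per case: exact binomial background tests with
# per-case Benjamini-Hochberg adjustment, the minimum detectable allelic
# ratio, and enrichment of ancestral-clone mutations among detections.

suppressMessages(library(clonescape))

rows <- list()
for (i in 1:6) {
  outdir <- file.path("results", "cases", sprintf("case%d", i))
  plasma <- read_amplicon_counts(file.path(outdir, "plasma.tsv"))
  counts <- read_amplicon_counts(file.path(outdir, "counts.tsv"))
  pm <- call_presence(counts)
  grouping <- setNames(rep("case", ncol(pm$call)), colnames(pm$call))
  cats <- classify_mutations(pm, grouping)
  anc <- setNames(cats$category == "ancestral", cats$mutation_id)
  det <- suppressWarnings(ctdna_detect(plasma, ancestral = anc,
                                       error_rate = 0.001, fdr = 0.05))
  write.csv(det$results, file.path(outdir, "ctdna_results.csv"),
            row.names = FALSE)
  s <- det$summary
  rows[[i]] <- data.frame(case = sprintf("case%d", i),
                          n_assayed = s$n_assayed, n_covered = s$n_covered,
                          n_detected = s$n_detected,
                          min_detectable_ratio = s$min_detectable_ratio,
                          enrichment_p = s$enrichment_p)
}
summary <- do.call(rbind, rows)
write.csv(summary, "results/ctdna_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat(sprintf(
  "cohort: %d/%d assayed sites covered, %d/%d covered sites detected\n",
  sum(summary$n_covered), sum(summary$n_assayed),
  sum(summary$n_detected), sum(summary$n_covered)))

# sensitivity of detection to the plasma tumour fraction (case 1 panel):
# at 5000x the assay saturates well above the minimum detectable ratio,
# so partial detection emerges only at much lower shedding
cat("\ndetected fraction vs plasma tumour fraction (case 1):\n")
for (f in c(0.001, 0.005, 0.02)) {
  cfg <- sim_config(random_seed = 101, plasma_tumour_fraction = f)
  tree <- simulate_clone_tree(cfg)
  det_f <- suppressWarnings(
    ctdna_detect(simulate_ctdna(tree, cfg), error_rate = 0.001, fdr = 0.05))
  cat(sprintf("  fraction %.3f: %3d/%3d detected\n", f,
              det_f$summary$n_detected, det_f$summary$n_assayed))
}
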
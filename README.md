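# clonescape

Multi-region clonal-evolution analysis for high-grade serous ovarian cancer
(HGSC).

HGSC patients are often sampled at several tumour sites — ovarian quadrants,
metastases, fallopian-tube lesions — plus plasma. Each bulk sample mixes
tumour clones descended from a single *TP53*-mutant ancestral cell, and the
clinical questions (which driver events are truncal? is the tumour already
heterogeneous before therapy? can plasma DNA track it?) are questions about
that clonal architecture. `clonescape` implements the analysis stack for
such studies, with a clonal-evolution simulator standing in for patient
data so every statistic is validated against known ground truth.

## What it computes

* **Presence/absence calling.** For each mutation × sample cell of a deep
  amplicon count table, `PRESENT` iff depth ≥ 50, variant reads ≥ 5 and the
  one-sided exact binomial tail P(X ≥ v | n, e) < α against background
  error e (defaults α = 0.01, e = 10⁻³); `INCONCLUSIVE` below minimum
  depth. Conservation per case/mass: % of the group's mutation universe
  present in all evaluable samples; categories ancestral / shared /
  private.
* **Mutational-profile phylogenies.** d(i,j) = 1 − Pearson r between
  per-sample VAF profiles, an all-zero control appended as root (r with a
  constant vector defined as 0), resolved by an in-package deterministic
  Saitou–Nei neighbour joining, written as canonical Newick.
* **Copy-number architecture.** Zygosity states from allele-specific
  segments (HOMD, HEMD, HET, NLOH, ALOH, ASCNA, BCNA); compound-event
  weights (ALOH/NLOH/HOMD → 2, HEMD → 1, HET/amplification → 0); fraction
  of genome under compound LOH; per-gene weight projection and a
  Euclidean/NJ architecture tree; whole-genome-doubling detection via the
  allele-wise (m,n) → (2m,2n) signature per chromosome.
* **Plasma ctDNA detection.** Exact binomial background tests with
  per-panel Benjamini–Hochberg FDR (< 0.05), the minimum detectable
  allelic ratio, and Fisher-exact enrichment of ancestral-clone mutations
  among detections.
* **Clonal diversity.** Cellular frequency
  φ = vaf · (c_n(1 − t) + c_t·t)/(t·m) clamped to [0, 1], with c_t looked
  up from the sample's segments; per-sample diversity as the IQR of φ
  (type-7 quantiles).
* **Simulator.** Clone trees with Poisson branch mutations (truncal
  mutation guaranteed), Dirichlet regional clone mixtures, negative
  binomial ~5000× amplicon depths with sequencing error, per-clone
  allele-specific CNA profiles with optional whole-genome doubling, and
  low-tumour-fraction plasma counts.

See `vignettes/clonal-architecture.Rmd` for the models, parameter
rationale, and limitations.

## Worked example

```r
library(clonescape)

cfg    <- sim_config(n_clones = 4, n_samples = 4, random_seed = 11)
tree   <- simulate_clone_tree(cfg)
comp   <- simulate_regions(tree, cfg)
counts <- simulate_amplicon_counts(tree, comp, cfg)

pm <- call_presence(counts)
pm
#> presence_matrix: 92 mutations x 4 samples
#>   PRESENT: 299
#>   ABSENT: 69
#>   INCONCLUSIVE: 0

conservation_stats(pm, setNames(rep("case", 4), colnames(pm$call)))$per_group
#>   group n_mutations n_conserved fraction_conserved
#> 1  case          92          45           48.91304

phy <- neighbour_joining(profile_distance_matrix(pm))
write_newick(phy)
#> (control:0.728066,((S01:0.00210614,S03:0):0.270569,S04:0):0.150927,S02:0.271934);
```

The simulated case carries 92 validated mutations across 4 regional
samples; 48.9% are present in every sample (the ancestral set plus
mutations of clones represented everywhere). In the tree, the control —
an aberration-free profile acting as root — attaches outside the samples,
and samples whose dominant clones are close in the clone tree attach as
neighbours with short branches.

## Repository layout

The repository is organised as an analysis workflow over the package:

* `R/` — all computation (simulator, presence calling, phylogenies,
  copy-number states, ctDNA statistics, diversity, orchestration).
* `analysis/01_simulate.R … 06_diversity.R` — numbered narrative drivers
  that simulate a six-case cohort (case 3 with an early whole-genome
  doubling) and run each analysis stage, writing tables under `results/`.
  Run them in order from the repository root.
* `tests/testthat/` — unit, property and acceptance tests.
* `scripts/acceptance.R` — headline-quantity reproduction (below).

`run_pipeline()` executes the same stages from a single (YAML-able)
configuration and writes a manifest with output hashes; identical
configuration and seed reproduce identical hashes.

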
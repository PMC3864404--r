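---
title: "Methods: multi-region clonal architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region clonal architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescape)
```

# Scope and model

`clonescape` analyses multi-region tumour sequencing studies of high-grade
serous ovarian carcinoma (HGSC): several spatially separated samples per
patient ("case"), each a bulk mixture of tumour clones, assayed by targeted
deep amplicon sequencing (~5000x), allele-specific copy-number profiling,
and plasma cell-free DNA sequencing. The package implements the statistics
of that study design — presence/absence calling, mutation conservation,
mutational and copy-number phylogenies, ctDNA detection, and intra-sample
clonal diversity — together with a clonal-evolution simulator that provides
ground truth for validating every stage.

## The clonal-evolution simulator

The simulator is the package's study-design stand-in for patient data, not a
fitting device. Its generative model is:

* **Clone tree.** A random recursive tree over `n_clones` clones rooted at
  the ancestral clone `C1`. Each branch acquires a Poisson number of SNVs
  (`mutations_per_branch_mean`, default 20) under the infinite-sites
  assumption; the root branch always carries at least one mutation — the
  stand-in for the truncal *TP53* mutation that defines a monoclonal origin.
  A clone carries its own branch's mutations plus all ancestral ones, so
  root-branch mutations are carried by every clone.
* **Regional samples.** Each of `n_samples` (default 6, within the 3–10
  samples per case of the target design) mixes 1–3 clones with fractions
  from a flat Dirichlet, so regional clonal dominance varies; tumour content
  is uniform on 0.5–0.9, the realistic purity range for macrodissected
  high-grade serous tumours.
* **Amplicon counts.** Depth per (mutation, sample) is negative binomial
  with mean 5000 (`depth_dispersion` is the NB size, default 50),
  emulating overdispersed targeted sequencing at a median above 5000x.
  Expected VAF at a carried site follows the diploid heterozygous rule
  `t·f/2` (tumour content `t`, carrier cell fraction `f`, multiplicity 1,
  copy number 2); sequencing error (default `1e-3` per read) converts
  non-variant reads at rate `e`, so variant reads are binomial with success
  probability `VAF + e(1 − VAF)`, and absent sites draw at `e` alone.
* **Copy-number profiles.** Each branch acquires a Poisson number of
  segmental events (default mean 2; lengths uniform on 10–80 Mb) that add or
  remove one copy of a physical parental allele; an optional whole-genome
  doubling doubles both alleles genome-wide at a designated clone. Events
  compose along each lineage, so a deletion followed by doubling yields
  copy-neutral LOH (2, 0) — the compound states the downstream analysis
  classifies. Each sample reports its *dominant* clone's integer profile,
  as bulk genotyping arrays report the majority population; fractional
  clone-mixture copy numbers are deliberately out of scope.
* **Plasma.** One pseudo-sample mixing all clones with equal shedding
  weights at tumour fraction `plasma_tumour_fraction` (default 0.05),
  counted exactly like a tumour sample.

Everything is a pure function of the configuration: each stage seeds its
own generator from `random_seed`, so identical configurations give
byte-identical outputs while stages remain independently re-runnable.

**What the simulator does not emulate.** Assay dropout (every simulated
site has coverage, whereas real plasma panels lose ~30% of sites),
per-site error-rate variation, subclonal copy-number mixtures within a
sample, mutation multiplicity above 1, and trunk-biased mutation loads
(branch means are equal, so the ancestral fraction of a case's mutations
concentrates near `1/n_clones` instead of spanning the wide 10–90% range
real cases show). Passing tests therefore validate the statistical
machinery under a controlled design, not cohort-level numbers from any
particular patient series.

# Presence/absence calling and conservation

A cell of the mutation-by-sample matrix is `PRESENT` when depth ≥
`min_depth` (default 50), variant reads ≥ `min_var_reads` (default 5), and
the one-sided exact binomial tail `P(X ≥ var | depth, error_rate)` is below
`alpha` (default 0.01 at error rate `1e-3`); `ABSENT` when evaluable but not
significant; `INCONCLUSIVE` below `min_depth` (the grey cells of a
validation heatmap). The error rate and thresholds are exposed because
validated panel-specific values belong to the assay, not the method; the
defaults control the empirical null false-positive rate below `alpha` at
5000x (property-tested on 10^4 null sites).

Conservation per group (case, or single tumour mass) is the percentage of
the group's mutation universe — mutations `PRESENT` in at least one sample
of the group — that is `PRESENT` in every *evaluable* sample.
`INCONCLUSIVE` cells are excluded from the all-samples requirement rather
than counted against it, mirroring how inconclusive validation cells are
displayed without contradicting conservation claims. Summaries are the mean
and sample (n−1) SD over groups. Mutation categories within a case:
`ancestral` (present in all evaluable samples), `private` (exactly one),
`shared` (two or more but not all), `undetected` (none).

# Mutational-profile phylogenies

Each sample's profile is its VAF vector over the case's mutation union
(`mode = "vaf"`, default; 1/0 presence under `mode = "binary"` as a
robustness check), with `INCONCLUSIVE` set to 0. Distance is
`1 − Pearson r`. An all-zero control profile — the aberration-free root — is
appended; since a constant vector has undefined correlation, `r` with it is
*defined* as 0, placing the control at distance 1 from every sample rather
than leaving it undefined. That convention reproduces the control's
root-like placement: it attaches outside the samples, which share ancestral
mutations and correlate positively with each other.

Neighbour joining is implemented in-package (Saitou–Nei Q-criterion,
standard branch-length formulas) because deterministic behaviour is part of
the contract: Q-ties (within 1e-12) are broken by the lexicographically
smallest pair of subtree labels, and negative branch lengths are clamped to
zero, the common display convention. The implementation is property-tested
against two independent oracles: path distances of randomly generated
additive trees (recovered to 1e-9 over 200 random trees, n ≤ 8) and
`ape::nj` topologies. Newick output is canonical — siblings ordered by
smallest leaf label, branch lengths at 6 significant digits, control leaf
as outgroup — so equal trees serialize identically and round-trip through
`ape::read.tree`.

One caveat established analytically while testing: when an *ancestral*
clone is itself sampled pure, its profile is a subset of both daughters'
profiles and the Pearson metric cannot separate the daughters as sisters.
The sister-recovery property is therefore stated (and holds, ≥90% of seeds)
for samples dominated by leaf clones — the realistic regional-dominance
scenario.

# Copy-number zygosity, compound events and doubling

Zygosity is a total function of integer (major, minor) copies: HOMD (0,0),
HEMD (1,0), HET (1,1), NLOH (2,0), ALOH (m ≥ 3, 0), BCNA (m = n ≥ 2),
ASCNA otherwise. Architecture-tree weights follow the compound-event
logic — states requiring at least two sequential events (ALOH, NLOH, HOMD)
weigh 2, HEMD weighs 1, HET weighs 0. Two readings were genuinely open and
are resolved as follows: balanced amplification (BCNA) weighs 0, read as
amplification without LOH alongside allele-specific amplification; and the
"proportion of the genome altered by compound events" counts NLOH + ALOH
only (the named compound LOH classes), with HOMD contributing to weights
but not to that fraction.

Genes take the state of the segment containing their midpoint — a
deterministic, split-invariant rule — and genes unassessed in any sample
are dropped from the shared universe. The architecture tree appends an
all-zero control gene-weight vector and runs the same neighbour-joining
over Euclidean distances.

Whole-genome doubling between a reference and a test sample is scored on
the intersected segmentation: a piece is doubling-consistent when the test
state is the exact allele-wise doubling of the reference state — HEMD→NLOH,
HET→(2,2), generally (m,n)→(2m,2n) — excluding null (0,0) reference pieces,
which would otherwise make a profile trivially "doubled" relative to
itself. A chromosome is flagged when the consistent fraction of assessable
length reaches `threshold` (default 0.5; the per-chromosome binary call is
a formalization choice, exposed as a parameter). Under the simulator's
default CNA noise, doubled-descendant samples flag ~21 of 22 autosomes and
non-doubled pairs ~0.

# Plasma ctDNA detection

Each covered site gets the one-sided exact binomial background test;
q-values are Benjamini–Hochberg within the patient panel (per-case
adjustment, matching per-case reporting), and detection is `q < 0.05`. The
minimum detectable allelic ratio — the dashed per-patient line of a plasma
VAF plot — is the smallest `k/depth` with unadjusted tail below `alpha`
(k ≥ 1 always; at least one variant read is required even at `alpha = 1`),
evaluated at the panel's median covered depth. Ancestral-clone enrichment
among detections is a one-sided Fisher exact test on the 2×2
detection-by-ancestry table over covered sites; degenerate margins return
p = 1 with a warning. The background error rate is a single global
parameter (default `1e-3`) rather than per-site, the simplest model
consistent with a pooled control estimate.

# Cellular frequency and diversity

The cellular-frequency estimator is deterministic:
`φ = vaf · (c_n(1 − t) + c_t·t) / (t·m)`, clamped to [0, 1], with the
tumour total copy number `c_t` looked up from the sample's segment profile
at the mutation's position (gaps default to diploid with a warning; `c_t`
is floored at 1 so homozygous-deleted sites stay defined). Multiplicity
defaults to `m = 1`; the full Dirichlet-process clustering that averages
over multiplicity states is an external method deliberately not
re-implemented, so the estimator is a declared simplification and published
per-sample IQR values are context, not targets. Diversity per sample is the
IQR (Q3 − Q1) of φ with linear-interpolation (type-7) quantiles — stated
explicitly because IQR values depend on the quantile convention; fewer than
four frequencies flags the score low-confidence.

# Numerical and testing choices

* Coordinates are 0-based half-open everywhere; files are validated on read.
* Binomial tails use `stats::pbinom` upper tails; BH uses `stats::p.adjust`;
  Fisher tests use `stats::fisher.test`; interval arithmetic uses
  GenomicRanges/IRanges.
* CNA events name *physical* parental alleles, so sequential events
  compose; states are reported as (major, minor) = (max, min).
* Test problem sizes were chosen to estimate each property stably while
  keeping the suite fast: 10^4 sites for null calibration (3-SE bounds),
  200 random additive trees for NJ consistency, 50 simulated tumours for
  doubling recovery, 100 paired seeds for the diversity contrast, and
  single full-size simulated cases (~120 mutations × 6 samples at 5000x)
  for recovery checks.

# Known limitations

* Per-sample copy number is the dominant clone's profile; subclonal CNA
  mixtures and clone-fraction-weighted profiles are out of scope.
* Counts start from tables; no read alignment, variant discovery, array
  normalization or segmentation upstream.
* The conservation and diversity statistics inherit the simulator's
  simplifications above; cohort-level values from patient series are not
  reproduction targets for the simulator defaults.
* No bootstrap support, maximum-likelihood or parsimony trees; neighbour
  joining only, as the downstream displays require.
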
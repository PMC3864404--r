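#' Default autosome genome
#'
#' Twenty-two autosomes with rounded, human-scale lengths (in bases). Used as
#' the coordinate system for simulated copy-number events and segment
#' profiles. Coordinates are 0-based half-open throughout the package.
#'
#' @return A data.frame with columns `chrom` and `length`.
#' @export
default_genome <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(250, 243, 198, 190, 182, 171, 159, 145, 138, 134, 135,
               133, 114, 107, 102, 90, 83, 80, 59, 63, 48, 51) * 1e6,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects every parameter of the clonal-evolution simulator. Defaults
#' emulate the study design the package targets: multi-region sampling of a
#' monoclonal tumour (a TP53-bearing ancestral clone), targeted amplicon
#' sequencing at a median depth above 5000x, and low-tumour-fraction plasma.
#'
#' @param n_clones Number of clones in the tree (>= 1).
#' @param n_samples Number of regional tumour samples.
#' @param mutations_per_branch_mean Poisson mean of SNVs acquired per branch.
#' @param depth_mean Mean amplicon depth (negative binomial).
#' @param depth_dispersion Negative-binomial size parameter; larger values
#'   give depths closer to Poisson.
#' @param sequencing_error_rate Per-read probability of observing the variant
#'   allele at a site the sampled cells do not carry.
#' @param plasma_tumour_fraction Fraction of plasma cell-free DNA derived from
#'   tumour cells.
#' @param cna_events_per_branch_mean Poisson mean of segmental copy-number
#'   events acquired per branch.
#' @param cna_length_range Length range (bases) from which event sizes are
#'   drawn uniformly.
#' @param wgd_clone Clone at which a whole-genome doubling occurs: a clone id
#'   (e.g. `"C3"`), `"none"`, or `"random"` (a uniformly chosen non-root
#'   clone, when the tree has one).
#' @param region_support_max Maximum number of clones mixed in one regional
#'   sample (support drawn uniformly from `1:region_support_max`).
#' @param tumour_content_range Range of per-sample tumour purity, drawn
#'   uniformly.
#' @param genome Genome as a data.frame `chrom`, `length`.
#' @param random_seed Integer seed; fixes all downstream randomness.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_clones = 6L,
                       n_samples = 6L,
                       mutations_per_branch_mean = 20,
                       depth_mean = 5000,
                       depth_dispersion = 50,
                       sequencing_error_rate = 0.001,
                       plasma_tumour_fraction = 0.05,
                       cna_events_per_branch_mean = 2,
                       cna_length_range = c(1e7, 8e7),
                       wgd_clone = "none",
                       region_support_max = 3L,
                       tumour_content_range = c(0.5, 0.9),
                       genome = default_genome(),
                       random_seed = 1L) {
  cfg <- list(
    n_clones = as.integer(n_clones),
    n_samples = as.integer(n_samples),
    mutations_per_branch_mean = mutations_per_branch_mean,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    sequencing_error_rate = sequencing_error_rate,
    plasma_tumour_fraction = plasma_tumour_fraction,
    cna_events_per_branch_mean = cna_events_per_branch_mean,
    cna_length_range = cna_length_range,
    wgd_clone = wgd_clone,
    region_support_max = as.integer(region_support_max),
    tumour_content_range = tumour_content_range,
    genome = genome,
    random_seed = as.integer(random_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_clones) || cfg$n_clones < 1L)
    stop("configuration error: n_clones must be >= 1", call. = FALSE)
  if (is.na(cfg$n_samples) || cfg$n_samples < 1L)
    stop("configuration error: n_samples must be >= 1", call. = FALSE)
  if (cfg$mutations_per_branch_mean < 0)
    stop("configuration error: mutations_per_branch_mean must be >= 0",
         call. = FALSE)
  if (cfg$cna_events_per_branch_mean < 0)
    stop("configuration error: cna_events_per_branch_mean must be >= 0",
         call. = FALSE)
  for (p in c("sequencing_error_rate", "plasma_tumour_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration error: ", p, " must be in [0, 1]", call. = FALSE)
  }
  if (cfg$depth_mean <= 0 || cfg$depth_dispersion <= 0)
    stop("configuration error: depth parameters must be positive",
         call. = FALSE)
  if (cfg$region_support_max < 1L)
    stop("configuration error: region_support_max must be >= 1",
         call. = FALSE)
  if (!all(c("chrom", "length") %in% names(cfg$genome)) ||
      any(cfg$genome$length <= 0))
    stop("configuration error: genome must have chrom and positive length",
         call. = FALSE)
  invisible(cfg)
}
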
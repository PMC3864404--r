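#' Simulate deep amplicon read counts
#'
#' For every (mutation, sample) pair, total depth is drawn from a negative
#' binomial with mean `depth_mean` and size `depth_dispersion` (floored at 1
#' read), emulating overdispersed targeted deep sequencing. The expected
#' variant allele fraction at a carried site follows the diploid
#' heterozygous model
#' \deqn{VAF = t \cdot f \cdot m / c = t f / 2}
#' with tumour content `t`, carrier cell fraction `f`, mutation multiplicity
#' `m = 1` and site copy number `c = 2`. Sequencing error converts
#' non-variant reads to variant reads at `sequencing_error_rate`, so variant
#' reads are binomial with success probability `VAF + e (1 - VAF)`; sites
#' absent from the sampled cells draw variant reads at the error rate alone.
#'
#' @param tree A `clone_tree`.
#' @param compositions Output of [simulate_regions()].
#' @param config A [sim_config()] object.
#' @return Amplicon counts: a data.frame with columns `mutation_id`, `chrom`,
#'   `pos`, `sample_id`, `ref_count`, `var_count`, plus a `true_vaf` column
#'   carrying the error-free expected VAF (simulation ground truth).
#' @export
simulate_amplicon_counts <- function(tree, compositions, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, 2L))
  known <- unlist(tree$branch_mutations, use.names = FALSE)
  if (!all(tree$mutations$mutation_id %in% known))
    stop("consistency error: mutation referenced by no clone", call. = FALSE)

  f <- carrier_fractions(tree, compositions)
  tc <- vapply(split(compositions$tumour_content, compositions$sample_id),
               `[`, numeric(1), 1L)
  samples <- colnames(f)
  err <- config$sequencing_error_rate

  grid <- expand.grid(mutation_id = rownames(f), sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  vaf <- tc[grid$sample_id] * f[cbind(grid$mutation_id, grid$sample_id)] / 2
  p <- vaf + err * (1 - vaf)
  depth <- pmax(1L, stats::rnbinom(n, mu = config$depth_mean,
                                   size = config$depth_dispersion))
  var_count <- stats::rbinom(n, depth, p)

  m <- tree$mutations[match(grid$mutation_id, tree$mutations$mutation_id), ]
  out <- data.frame(
    mutation_id = grid$mutation_id,
    chrom = m$chrom,
    pos = m$pos,
    sample_id = grid$sample_id,
    ref_count = depth - var_count,
    var_count = var_count,
    true_vaf = vaf,
    stringsAsFactors = FALSE
  )
  out[order(out$mutation_id, out$sample_id), , drop = FALSE]
}

#' Simulate plasma circulating tumour DNA counts
#'
#' Produces one pseudo-sample (`"plasma"`) whose clone composition is a
#' shedding-weighted average over all clones (equal shedding by default) and
#' whose effective tumour content is `plasma_tumour_fraction`, so an
#' ancestral heterozygous diploid mutation has expected VAF
#' `plasma_tumour_fraction / 2`. Counts are drawn exactly as in
#' [simulate_amplicon_counts()].
#'
#' @param tree A `clone_tree`.
#' @param config A [sim_config()] object.
#' @param shedding Optional non-negative shedding weight per clone (recycled
#'   named or positional); defaults to equal weights.
#' @return Amplicon counts for the single plasma pseudo-sample (same columns
#'   as [simulate_amplicon_counts()]).
#' @export
simulate_ctdna <- function(tree, config, shedding = NULL) {
  validate_sim_config(config)
  if (is.null(shedding)) shedding <- rep(1, length(tree$clones))
  if (any(shedding < 0) || sum(shedding) == 0)
    stop("configuration error: shedding weights must be non-negative and not all zero",
         call. = FALSE)
  comp <- data.frame(
    sample_id = "plasma",
    clone = tree$clones,
    fraction = shedding / sum(shedding),
    tumour_content = config$plasma_tumour_fraction,
    stringsAsFactors = FALSE
  )
  cfg <- config
  cfg$random_seed <- stage_seed(config, 3L)
  simulate_amplicon_counts(tree, comp, cfg)
}
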
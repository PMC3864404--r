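# Stage-specific seeds derived from the config seed keep every stage a pure
# function of the configuration while allowing stages to be re-run alone.
stage_seed <- function(config, offset) {
  as.integer((as.numeric(config$random_seed) * 101 + offset) %% 2^30)
}

#' Simulate regional sample compositions
#'
#' Each regional tumour sample is a mixture of a small number of clones:
#' a support of 1 to `region_support_max` clones is chosen uniformly, and
#' mixture fractions over the support are drawn from a flat Dirichlet
#' (alpha = 1), so regional clonal dominance varies between samples. Tumour
#' content is drawn uniformly from `tumour_content_range`.
#'
#' @param tree A `clone_tree`.
#' @param config A [sim_config()] object.
#' @return A data.frame of class `sample_composition` with columns
#'   `sample_id`, `clone`, `fraction`, `tumour_content`; fractions sum to 1
#'   within each sample.
#' @export
simulate_regions <- function(tree, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, 1L))
  n_clones <- length(tree$clones)
  rows <- lapply(seq_len(config$n_samples), function(i) {
    k <- sample.int(min(config$region_support_max, n_clones), 1L)
    support <- sort(sample(tree$clones, k))
    frac <- rdirichlet_flat(k)
    data.frame(
      sample_id = sprintf("S%02d", i),
      clone = support,
      fraction = frac,
      tumour_content = stats::runif(1, config$tumour_content_range[1],
                                    config$tumour_content_range[2]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_composition", "data.frame")
  out
}

# Flat Dirichlet via normalized standard exponentials
rdirichlet_flat <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

#' Dominant clone of each sample
#' @param compositions A `sample_composition` data.frame.
#' @return Named character vector: sample id -> clone with largest fraction
#'   (ties broken by clone id order).
#' @export
dominant_clones <- function(compositions) {
  vapply(split(compositions, compositions$sample_id), function(d) {
    d <- d[order(-d$fraction, d$clone), ]
    d$clone[1]
  }, character(1))
}

# Fraction of cells in each sample carrying each mutation
carrier_fractions <- function(tree, compositions) {
  ids <- tree$mutations$mutation_id
  samples <- unique(compositions$sample_id)
  f <- matrix(0, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  for (s in samples) {
    comp <- compositions[compositions$sample_id == s, ]
    for (m in ids) {
      f[m, s] <- sum(comp$fraction[comp$clone %in% tree$carriers[[m]]])
    }
  }
  f
}
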
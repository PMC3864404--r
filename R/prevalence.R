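#' Purity- and copy-number-adjusted cellular frequency
#'
#' Deterministic estimator of the fraction of tumour cells carrying a
#' mutation:
#' \deqn{\phi = vaf \cdot \frac{c_n (1 - t) + c_t \, t}{t \, m}}
#' with tumour content `t`, tumour total copy number `c_t` at the site,
#' normal copy number `c_n` (2 for autosomes) and mutation multiplicity `m`.
#' The estimate is clamped to `[0, 1]`. At `t = 1`, `c_t = 2`, `m = 1` a
#' clonal heterozygous mutation (vaf 0.5) gives exactly 1.
#'
#' @param vaf Allelic ratio in `[0, 1]` (vectorized).
#' @param t Tumour content in `(0, 1]`.
#' @param c_t Tumour total copy number at the site (>= 1).
#' @param c_n Normal copy number (default 2).
#' @param m Mutation multiplicity, `1 <= m <= c_t` (default 1).
#' @return Cellular frequency in `[0, 1]`.
#' @export
cellular_frequency <- function(vaf, t, c_t, c_n = 2, m = 1) {
  if (any(t <= 0)) stop("undefined-purity error: t must be > 0",
                        call. = FALSE)
  if (any(t > 1) || any(vaf < 0) || any(vaf > 1))
    stop("input error: vaf and t must be in [0, 1]", call. = FALSE)
  if (any(c_t < 1) || any(m < 1) || any(m > c_t))
    stop("input error: need c_t >= 1 and 1 <= m <= c_t", call. = FALSE)
  phi <- vaf * (c_n * (1 - t) + c_t * t) / (t * m)
  pmin(pmax(phi, 0), 1)
}

#' Intra-sample clonal diversity as the IQR of cellular frequencies
#'
#' Interquartile range Q3 - Q1 of a sample's per-mutation cellular
#' frequencies, with linear-interpolation (type-7) quantiles. A wide IQR
#' indicates mutations at heterogeneous prevalences, i.e. intra-sample
#' clonal diversity; a near-zero IQR a clonally homogeneous sample.
#'
#' @param frequencies Numeric vector of cellular frequencies.
#' @return List `iqr`, `n_mutations`, `low_confidence` (fewer than 4
#'   frequencies).
#' @export
diversity_iqr <- function(frequencies) {
  frequencies <- frequencies[!is.na(frequencies)]
  if (length(frequencies) == 0)
    stop("input error: no cellular frequencies", call. = FALSE)
  q <- stats::quantile(frequencies, c(0.25, 0.75), type = 7, names = FALSE)
  list(iqr = q[2] - q[1], n_mutations = length(frequencies),
       low_confidence = length(frequencies) < 4)
}

#' Cellular frequencies for every presence-matrix cell of a sample set
#'
#' Looks up each mutation's site in the sample's allele-specific segment
#' profile to obtain the tumour total copy number (sites in coverage gaps
#' default to diploid, with a warning), and applies [cellular_frequency()]
#' to the observed allelic ratios of evaluable cells.
#'
#' @param matrix A `presence_matrix`.
#' @param sites data.frame `mutation_id`, `chrom`, `pos` (1-based site
#'   positions).
#' @param profiles Named list: sample id -> segment profile (may be `NULL`
#'   for all-diploid).
#' @param tumour_content Named numeric vector: sample id -> purity.
#' @param m Multiplicity (default 1).
#' @return data.frame `mutation_id`, `sample_id`, `vaf`, `c_t`, `phi`.
#' @export
estimate_cellular_frequencies <- function(matrix, sites, profiles,
                                          tumour_content, m = 1) {
  samples <- colnames(matrix$call)
  out <- lapply(samples, function(s) {
    evaluable <- matrix$call[, s] != "INCONCLUSIVE" & !is.na(matrix$vaf[, s])
    ids <- rownames(matrix$call)[evaluable]
    loc <- sites[match(ids, sites$mutation_id), ]
    c_t <- rep(2, length(ids))
    prof <- profiles[[s]]
    if (!is.null(prof)) {
      pts <- GenomicRanges::GRanges(
        seqnames = loc$chrom,
        ranges = IRanges::IRanges(start = loc$pos, width = 1L))
      hit <- GenomicRanges::findOverlaps(pts, profile_granges(prof),
                                         select = "first")
      if (anyNA(hit))
        warning("sites outside segment coverage default to c_t = 2 in ", s)
      found <- !is.na(hit)
      c_t[found] <- prof$major_cn[hit[found]] + prof$minor_cn[hit[found]]
    }
    c_t <- pmax(c_t, 1)  # homozygous-deletion sites: keep estimator defined
    data.frame(mutation_id = ids, sample_id = s,
               vaf = matrix$vaf[ids, s], c_t = c_t,
               phi = cellular_frequency(matrix$vaf[ids, s],
                                        tumour_content[[s]], c_t, m = m),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-sample diversity scores from a cellular-frequency table
#' @param frequencies Output of [estimate_cellular_frequencies()].
#' @return data.frame `sample_id`, `iqr`, `n_mutations`, `low_confidence`.
#' @export
sample_diversity <- function(frequencies) {
  out <- lapply(split(frequencies, frequencies$sample_id), function(d) {
    s <- diversity_iqr(d$phi)
    data.frame(sample_id = d$sample_id[1], iqr = s$iqr,
               n_mutations = s$n_mutations,
               low_confidence = s$low_confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
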
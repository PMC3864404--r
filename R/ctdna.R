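#' One-sided exact binomial detection test
#'
#' Upper-tail probability \eqn{P(X \ge var\_count)} for
#' \eqn{X \sim Binomial(depth, error\_rate)}: the probability that
#' background sequencing error alone produces at least the observed number
#' of variant reads. Vectorized; cells with zero depth get `NA` (no
#' coverage) and are excluded from downstream testing.
#'
#' @param var_count Observed variant reads (vector).
#' @param depth Total reads (vector).
#' @param error_rate Background per-read error rate.
#' @return Vector of one-sided p-values; `NA` where depth is 0.
#' @export
binomial_detection_test <- function(var_count, depth, error_rate) {
  if (error_rate < 0 || error_rate >= 1)
    stop("input error: error_rate must be in [0, 1)", call. = FALSE)
  if (any(var_count < 0) || any(var_count > depth))
    stop("input error: var_count must be in [0, depth]", call. = FALSE)
  p <- ifelse(var_count == 0, 1,
              stats::pbinom(var_count - 1, depth, error_rate,
                            lower.tail = FALSE))
  p[depth == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, as in
#' [stats::p.adjust()]. `NA` p-values (no coverage) propagate as `NA` and do
#' not count towards the number of tests.
#'
#' @param p_values Vector of p-values in `[0, 1]` (may contain `NA`).
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Minimum detectable allelic ratio
#'
#' The smallest variant allele fraction `k / depth` (with `k >= 1`) at which
#' the unadjusted one-sided exact binomial test is significant, i.e. the
#' smallest `k` with \eqn{P(X \ge k | depth, error\_rate) < alpha}. This is
#' the per-patient dashed detection limit of a plasma VAF plot.
#'
#' @param depth Sequencing depth (>= 1).
#' @param error_rate Background error rate.
#' @param alpha Unadjusted significance level.
#' @return The ratio `k / depth`; 1.0 with a warning when no `k <= depth`
#'   reaches significance.
#' @export
min_detectable_ratio <- function(depth, error_rate, alpha = 0.05) {
  depth <- round(depth)  # tolerate non-integer summary depths (medians)
  if (depth < 1) stop("input error: depth must be >= 1", call. = FALSE)
  # smallest q with F(q) >= 1 - alpha has P(X >= q + 1) <= alpha; scan
  # upward from there for the strict inequality
  k <- stats::qbinom(1 - alpha, depth, error_rate) + 1
  while (k <= depth &&
         stats::pbinom(k - 1, depth, error_rate, lower.tail = FALSE) >= alpha)
    k <- k + 1
  k <- max(k, 1)
  if (k > depth) {
    warning("no variant count up to depth reaches significance; returning 1")
    return(1.0)
  }
  k / depth
}

#' Enrichment of ancestral-clone mutations among plasma-detected sites
#'
#' One-sided Fisher exact test (alternative: detected sites are enriched for
#' ancestral mutations) on the 2x2 table of covered mutations cross-
#' classified by detection status and ancestral status.
#'
#' @param detected Logical vector over covered mutations.
#' @param ancestral Logical vector over covered mutations.
#' @return One-sided (greater) hypergeometric p-value; 1 with a warning when
#'   a table margin is zero.
#' @export
ancestral_enrichment <- function(detected, ancestral) {
  stopifnot(length(detected) == length(ancestral))
  tab <- table(factor(detected, levels = c(TRUE, FALSE)),
               factor(ancestral, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); enrichment p = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Detect tumour mutations in plasma ctDNA counts
#'
#' Runs the exact binomial background test at every covered site of a
#' patient panel, adjusts within the panel by Benjamini-Hochberg, and calls
#' a mutation detected at `q < fdr`. Summarizes coverage, detections, the
#' minimum detectable allelic ratio at the panel's median covered depth, and
#' ancestral-clone enrichment among detections when ancestral flags are
#' given.
#'
#' @param counts Plasma amplicon counts data.frame (`mutation_id`,
#'   `ref_count`, `var_count`).
#' @param ancestral Optional named logical vector (mutation id -> is the
#'   mutation ancestral, i.e. present in all tumour samples of the case).
#' @param error_rate Background error rate.
#' @param fdr False-discovery-rate threshold for detection.
#' @param alpha Unadjusted level used for the minimum detectable ratio.
#' @return List with `results` (per-mutation data.frame: depth, var_count,
#'   allelic_ratio, p_value, q_value, covered, detected, ancestral) and
#'   `summary` (n_assayed, n_covered, n_detected, min_detectable_ratio,
#'   enrichment_p).
#' @export
ctdna_detect <- function(counts, ancestral = NULL, error_rate = 0.001,
                         fdr = 0.05, alpha = 0.05) {
  depth <- counts$ref_count + counts$var_count
  pval <- binomial_detection_test(counts$var_count, depth, error_rate)
  qval <- fdr_adjust(pval)
  covered <- depth >= 1
  detected <- covered & !is.na(qval) & qval < fdr

  anc <- if (is.null(ancestral)) rep(NA, nrow(counts))
         else unname(ancestral[counts$mutation_id])
  results <- data.frame(
    mutation_id = counts$mutation_id,
    depth = depth,
    var_count = counts$var_count,
    allelic_ratio = ifelse(depth > 0, counts$var_count / depth, NA_real_),
    p_value = pval,
    q_value = qval,
    covered = covered,
    detected = detected,
    ancestral = anc,
    stringsAsFactors = FALSE
  )
  med_depth <- stats::median(depth[covered])
  enr <- if (!is.null(ancestral) && any(covered))
    ancestral_enrichment(detected[covered], anc[covered]) else NA_real_
  list(results = results,
       summary = list(
         n_assayed = nrow(counts),
         n_covered = sum(covered),
         n_detected = sum(detected),
         min_detectable_ratio =
           if (any(covered)) min_detectable_ratio(med_depth, error_rate, alpha)
           else NA_real_,
         enrichment_p = enr
       ))
}
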
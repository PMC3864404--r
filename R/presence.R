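#' Call mutation presence/absence from deep amplicon counts
#'
#' A (mutation, sample) cell is called `PRESENT` when its depth reaches
#' `min_depth`, its variant reads reach `min_var_reads`, and the one-sided
#' exact binomial tail \eqn{P(X \ge var | depth, error\_rate)} falls below
#' `alpha` — i.e. the variant allele fraction exceeds the sequencing
#' background. Cells with adequate depth but a non-significant test are
#' `ABSENT`; cells below `min_depth` are `INCONCLUSIVE` (the grey cells of a
#' validation heatmap).
#'
#' @param counts Amplicon counts data.frame (`mutation_id`, `sample_id`,
#'   `ref_count`, `var_count`).
#' @param error_rate Per-read background error rate (in `[0, 1)`).
#' @param alpha Significance level of the exact binomial test.
#' @param min_depth Minimum depth for an evaluable cell.
#' @param min_var_reads Minimum variant reads for a `PRESENT` call.
#' @return An object of class `presence_matrix`: list with character matrix
#'   `call` (mutations x samples, values `PRESENT`/`ABSENT`/`INCONCLUSIVE`),
#'   numeric matrices `vaf` (allelic ratio; `NA` at depth 0) and `depth`,
#'   and the calling parameters in `params`.
#' @export
call_presence <- function(counts, error_rate = 0.001, alpha = 0.01,
                          min_depth = 50, min_var_reads = 5) {
  if (any(counts$ref_count < 0) || any(counts$var_count < 0))
    stop("input error: negative read counts", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("input error: error_rate must be in [0, 1)", call. = FALSE)
  if (min_depth < 1)
    stop("input error: min_depth must be >= 1", call. = FALSE)
  if (anyDuplicated(counts[c("mutation_id", "sample_id")]))
    stop("input error: duplicated (mutation, sample) pairs", call. = FALSE)

  muts <- unique(counts$mutation_id)
  samples <- unique(counts$sample_id)
  depth <- counts$ref_count + counts$var_count
  pval <- binomial_detection_test(counts$var_count, depth, error_rate)
  call <- ifelse(depth < min_depth, "INCONCLUSIVE",
                 ifelse(counts$var_count >= min_var_reads & pval < alpha,
                        "PRESENT", "ABSENT"))

  shape <- function(x, default) {
    m <- matrix(default, nrow = length(muts), ncol = length(samples),
                dimnames = list(muts, samples))
    m[cbind(counts$mutation_id, counts$sample_id)] <- x
    m
  }
  structure(list(
    call = shape(call, "INCONCLUSIVE"),
    vaf = shape(ifelse(depth > 0, counts$var_count / depth, NA_real_), NA_real_),
    depth = shape(depth, 0),
    params = list(error_rate = error_rate, alpha = alpha,
                  min_depth = min_depth, min_var_reads = min_var_reads)
  ), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$call), "mutations x", ncol(x$call),
      "samples\n")
  tab <- table(factor(x$call, levels = c("PRESENT", "ABSENT", "INCONCLUSIVE")))
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

check_grouping <- function(matrix, grouping) {
  samples <- colnames(matrix$call)
  if (!all(samples %in% names(grouping)))
    stop("grouping error: every sample must be mapped to one group",
         call. = FALSE)
  g <- grouping[samples]
  if (any(table(g) == 0))
    stop("grouping error: empty group", call. = FALSE)
  g
}

#' Mutation conservation statistics per group
#'
#' For each group of samples (a case, or a single tumour mass), the
#' conserved fraction is the percentage of that group's mutation universe
#' (mutations `PRESENT` in at least one sample of the group) that is
#' `PRESENT` in every evaluable sample of the group. `INCONCLUSIVE` cells
#' are excluded from the all-samples requirement rather than counted against
#' it. The summary is the mean and sample (n-1) standard deviation of the
#' per-group fractions.
#'
#' @param matrix A `presence_matrix`.
#' @param grouping Named character vector: sample id -> group id.
#' @return List with `per_group` (data.frame `group`, `n_mutations`,
#'   `n_conserved`, `fraction_conserved` in percent) and `summary`
#'   (`mean`, `sd`, `n_groups`).
#' @export
conservation_stats <- function(matrix, grouping) {
  g <- check_grouping(matrix, grouping)
  groups <- unique(g)
  per_group <- do.call(rbind, lapply(groups, function(gr) {
    calls <- matrix$call[, names(g)[g == gr], drop = FALSE]
    universe <- rowSums(calls == "PRESENT") >= 1
    conserved <- universe & rowSums(calls == "ABSENT") == 0
    data.frame(group = gr,
               n_mutations = sum(universe),
               n_conserved = sum(conserved),
               fraction_conserved =
                 if (sum(universe) > 0) 100 * sum(conserved) / sum(universe)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_group = per_group,
       summary = summarize_conservation(per_group$fraction_conserved))
}

#' Mean and sample SD of per-group conservation fractions
#' @param fractions Numeric vector of per-group conserved percentages.
#' @return List `mean`, `sd` (n-1 denominator; `NA` for a single group),
#'   `n_groups`.
#' @export
summarize_conservation <- function(fractions) {
  fractions <- fractions[!is.na(fractions)]
  list(mean = mean(fractions), sd = stats::sd(fractions),
       n_groups = length(fractions))
}

#' Classify mutations as ancestral, shared or private within groups
#'
#' Within each group (case): `ancestral` mutations are `PRESENT` in all
#' evaluable samples, `private` in exactly one sample, `shared` in at least
#' two but not all; mutations never `PRESENT` in the group are `undetected`.
#'
#' @param matrix A `presence_matrix`.
#' @param grouping Named character vector: sample id -> group id.
#' @return data.frame `mutation_id`, `group`, `n_present`, `n_evaluable`,
#'   `category`.
#' @export
classify_mutations <- function(matrix, grouping) {
  g <- check_grouping(matrix, grouping)
  out <- lapply(unique(g), function(gr) {
    calls <- matrix$call[, names(g)[g == gr], drop = FALSE]
    n_present <- rowSums(calls == "PRESENT")
    n_eval <- rowSums(calls != "INCONCLUSIVE")
    category <- ifelse(n_present == 0, "undetected",
                ifelse(n_present == n_eval, "ancestral",
                ifelse(n_present == 1, "private", "shared")))
    data.frame(mutation_id = rownames(calls), group = gr,
               n_present = n_present, n_evaluable = n_eval,
               category = category, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
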
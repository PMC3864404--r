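#' Read / write amplicon count tables
#'
#' Tab-separated with columns `mutation_id`, `chrom`, `pos` (1-based),
#' `sample_id`, `ref_count`, `var_count`.
#'
#' @param path File path.
#' @return `read_amplicon_counts()`: the counts data.frame.
#' @export
read_amplicon_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mutation_id", "chrom", "pos", "sample_id", "ref_count",
            "var_count")
  if (!all(need %in% names(x)))
    stop("I/O error: counts file missing columns ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  x
}

#' @rdname read_amplicon_counts
#' @param counts Counts data.frame.
#' @export
write_amplicon_counts <- function(counts, path) {
  cols <- intersect(c("mutation_id", "chrom", "pos", "sample_id",
                      "ref_count", "var_count"), names(counts))
  utils::write.table(counts[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write allele-specific segment tables
#'
#' BED-like tab-separated, 0-based half-open: `sample_id`, `chrom`, `start`,
#' `end`, `major_cn`, `minor_cn`.
#'
#' @param path File path.
#' @return `read_segments()`: named list of per-sample segment profiles.
#' @export
read_segments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "major_cn", "minor_cn")
  if (!all(need %in% names(x)))
    stop("I/O error: segments file missing columns ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  if (any(x$end <= x$start))
    stop("I/O error: segment with end <= start", call. = FALSE)
  if (any(x$minor_cn > x$major_cn) || any(x$minor_cn < 0))
    stop("I/O error: invalid allele-specific copy numbers", call. = FALSE)
  lapply(split(x[setdiff(names(x), "sample_id")], x$sample_id),
         function(d) { rownames(d) <- NULL; d })
}

#' @rdname read_segments
#' @param profiles Named list of segment profiles.
#' @export
write_segments <- function(profiles, path) {
  rows <- lapply(names(profiles), function(s)
    cbind(sample_id = s, profiles[[s]][c("chrom", "start", "end",
                                         "major_cn", "minor_cn")]))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the presence matrix as TSV
#'
#' Rows are mutations, columns samples; each cell is `P`, `A` or `I`
#' followed by `:` and the allelic ratio when defined.
#'
#' @param matrix A `presence_matrix`.
#' @param path File path.
#' @export
write_presence_matrix <- function(matrix, path) {
  code <- c(PRESENT = "P", ABSENT = "A", INCONCLUSIVE = "I")
  cells <- matrix(paste0(code[matrix$call],
                         ifelse(is.na(matrix$vaf), "",
                                sprintf(":%.6g", matrix$vaf))),
                  nrow = nrow(matrix$call), dimnames = dimnames(matrix$call))
  utils::write.table(data.frame(mutation_id = rownames(cells), cells,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Serializes the clone tree (parents, branch mutations, per-mutation
#' carrier sets, WGD clone) and the sample compositions.
#'
#' @param tree A `clone_tree`.
#' @param compositions Output of [simulate_regions()] (optional).
#' @param path File path.
#' @export
write_truth <- function(tree, compositions = NULL, path) {
  truth <- list(
    clones = tree$clones,
    parent = as.list(tree$parent),
    branch_mutations = tree$branch_mutations,
    branch_cna = tree$branch_cna,
    carriers = tree$carriers,
    wgd_clone = tree$wgd_clone,
    mutations = tree$mutations
  )
  if (!is.null(compositions)) truth$compositions <- compositions
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
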
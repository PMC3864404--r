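#' Classify allele-specific copy number into a zygosity state
#'
#' Total function of integer (major, minor) copy numbers:
#' \itemize{
#'   \item `HOMD` (0,0) homozygous deletion
#'   \item `HEMD` (1,0) hemizygous deletion
#'   \item `HET`  (1,1) diploid heterozygous
#'   \item `NLOH` (2,0) copy-neutral LOH
#'   \item `ALOH` (m,0), m >= 3, amplified LOH
#'   \item `BCNA` (m,m), m >= 2, balanced amplification
#'   \item `ASCNA` everything else (allele-specific amplification)
#' }
#' NLOH and ALOH are compound events: they require at least two sequential
#' copy-number changes (a deletion followed by amplification of the
#' remaining allele).
#'
#' @param major,minor Integer copy numbers, `major >= minor >= 0`
#'   (vectorized).
#' @return Character vector of states.
#' @export
classify_zygosity <- function(major, minor) {
  if (any(minor > major))
    stop("input error: minor copy number exceeds major", call. = FALSE)
  if (any(major < 0 | minor < 0))
    stop("input error: negative copy number", call. = FALSE)
  ifelse(major == 0 & minor == 0, "HOMD",
  ifelse(major == 1 & minor == 0, "HEMD",
  ifelse(major == 1 & minor == 1, "HET",
  ifelse(major == 2 & minor == 0, "NLOH",
  ifelse(minor == 0, "ALOH",
  ifelse(major == minor, "BCNA", "ASCNA"))))))
}

#' Integer weight of a zygosity state
#'
#' Weights used for the copy-number architecture tree: states reachable only
#' through at least two sequential events (ALOH, NLOH, homozygous deletion)
#' weigh 2, a hemizygous deletion weighs 1, and diploid heterozygous or
#' amplification without LOH (allele-specific or balanced) weighs 0.
#'
#' @param state Character vector of states from [classify_zygosity()].
#' @return Integer vector of weights.
#' @export
compound_weight <- function(state) {
  w <- c(ALOH = 2L, NLOH = 2L, HOMD = 2L, HEMD = 1L,
         HET = 0L, ASCNA = 0L, BCNA = 0L)
  if (!all(state %in% names(w)))
    stop("input error: unknown zygosity state", call. = FALSE)
  unname(w[state])
}

segment_states <- function(profile) {
  classify_zygosity(profile$major_cn, profile$minor_cn)
}

#' Fraction of the genome altered by compound LOH events
#'
#' Length-weighted fraction of the assessable genome (the profile's covered
#' length, clipped to the genome) in a compound LOH state (NLOH or ALOH).
#' Homozygous deletions contribute to tree weights but not to this fraction.
#'
#' @param profile Segment profile (`chrom`, `start`, `end`, `major_cn`,
#'   `minor_cn`).
#' @param genome Genome data.frame (`chrom`, `length`).
#' @return Fraction in `[0, 1]`; 0 with a warning for an empty profile.
#' @export
compound_fraction <- function(profile, genome = default_genome()) {
  if (nrow(profile) == 0) {
    warning("empty segment profile; compound fraction is 0")
    return(0)
  }
  glen <- genome$length[match(profile$chrom, genome$chrom)]
  len <- pmin(profile$end, glen) - pmax(profile$start, 0)
  len <- pmax(len, 0)
  st <- segment_states(profile)
  sum(len[st %in% c("NLOH", "ALOH")]) / sum(len)
}

profile_granges <- function(profile) {
  GenomicRanges::GRanges(
    seqnames = profile$chrom,
    ranges = IRanges::IRanges(start = profile$start + 1L, end = profile$end)
  )
}

#' Project segment states onto genes
#'
#' Each gene takes the state of the segment containing its midpoint (a
#' deterministic, split-invariant rule); genes whose midpoint falls in a
#' coverage gap are unassessed (`NA`) and excluded downstream.
#'
#' @param profile Segment profile data.frame.
#' @param genes data.frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return data.frame `gene`, `state`, `major_cn`, `minor_cn`, `weight`
#'   (`NA` where unassessed).
#' @export
project_to_genes <- function(profile, genes) {
  mid <- floor((genes$start + genes$end) / 2)
  pts <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = mid + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(pts, profile_granges(profile),
                                      select = "first")
  st <- segment_states(profile)
  out <- data.frame(
    gene = genes$gene,
    state = st[hits],
    major_cn = profile$major_cn[hits],
    minor_cn = profile$minor_cn[hits],
    stringsAsFactors = FALSE
  )
  out$weight <- NA_integer_
  ok <- !is.na(out$state)
  out$weight[ok] <- compound_weight(out$state[ok])
  out
}

#' Copy-number architecture tree from per-gene compound weights
#'
#' Stacks the samples' per-gene weight vectors (dropping genes unassessed in
#' any sample), appends an all-zero control, computes pairwise Euclidean
#' distances, and resolves the tree by [neighbour_joining()].
#'
#' @param weights Named list (or matrix, samples x genes) of per-gene
#'   integer weights; `NA` marks unassessed genes.
#' @param control Label for the zero-weight control profile.
#' @return List with `tree` (a `phylo`) and `distances` (the Euclidean
#'   matrix including the control).
#' @export
cna_distance_tree <- function(weights, control = "control") {
  W <- if (is.matrix(weights)) weights else do.call(rbind, weights)
  if (is.null(rownames(W))) rownames(W) <- names(weights)
  W <- W[, colSums(is.na(W)) == 0, drop = FALSE]
  if (ncol(W) == 0) stop("input error: empty shared gene universe",
                         call. = FALSE)
  W <- rbind(W, 0)
  rownames(W)[nrow(W)] <- control
  D <- as.matrix(stats::dist(W, method = "euclidean"))
  list(tree = neighbour_joining(D, control = control), distances = D)
}

# intersect two segment profiles: pieces covered by both, with both states
intersect_profiles <- function(ref, test) {
  gr_ref <- profile_granges(ref)
  gr_test <- profile_granges(test)
  pieces <- GenomicRanges::disjoin(suppressWarnings(c(gr_ref, gr_test)))
  hr <- GenomicRanges::findOverlaps(pieces, gr_ref, select = "first")
  ht <- GenomicRanges::findOverlaps(pieces, gr_test, select = "first")
  keep <- !is.na(hr) & !is.na(ht)
  pieces <- pieces[keep]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(pieces)),
    start = GenomicRanges::start(pieces) - 1L,
    end = GenomicRanges::end(pieces),
    ref_major = ref$major_cn[hr[keep]], ref_minor = ref$minor_cn[hr[keep]],
    test_major = test$major_cn[ht[keep]], test_minor = test$minor_cn[ht[keep]],
    stringsAsFactors = FALSE
  )
}

#' Pairwise copy-number and zygosity concordance between two samples
#'
#' Counts shared-universe genes by their total copy number (major + minor)
#' in each sample and whether the two samples agree on LOH-vs-heterozygous
#' status (LOH = minor allele lost). This is the data behind a pairwise
#' copy-number dot plot: dot size = count, colour = same zygosity.
#'
#' @param genesA,genesB Outputs of [project_to_genes()] for the two samples
#'   over the same gene list.
#' @return data.frame `cn_a`, `cn_b`, `same_zygosity`, `n`.
#' @export
pairwise_state_concordance <- function(genesA, genesB) {
  stopifnot(identical(genesA$gene, genesB$gene))
  ok <- !is.na(genesA$state) & !is.na(genesB$state)
  a <- genesA[ok, ]; b <- genesB[ok, ]
  tab <- stats::aggregate(
    list(n = a$gene),
    by = list(cn_a = a$major_cn + a$minor_cn,
              cn_b = b$major_cn + b$minor_cn,
              same_zygosity = (a$minor_cn == 0) == (b$minor_cn == 0)),
    FUN = length)
  tab[order(tab$cn_a, tab$cn_b, tab$same_zygosity), , drop = FALSE]
}

#' Detect whole-genome-doubling signatures between two samples
#'
#' Intersects the two segmentations and measures, per chromosome, the
#' fraction of assessable length whose test-sample state is the exact
#' allele-wise doubling of the reference state — hemizygous deletions seen
#' as NLOH, diploid heterozygous regions as balanced (2,2), and generally
#' (m, n) as (2m, 2n) for non-null reference states. A chromosome is
#' flagged doubled when this fraction reaches `threshold`.
#'
#' @param reference,test Segment profiles on the same genome.
#' @param threshold Minimum doubling-consistent fraction (default 0.5).
#' @return List with `per_chrom` (data.frame `chrom`, `assessable`,
#'   `consistent`, `fraction`, `doubled`) and `n_doubled`.
#' @export
detect_doubling <- function(reference, test, threshold = 0.5) {
  pieces <- intersect_profiles(reference, test)
  if (nrow(pieces) == 0)
    stop("input error: profiles cover disjoint genomes", call. = FALSE)
  len <- pieces$end - pieces$start
  consistent <- pieces$test_major == 2L * pieces$ref_major &
    pieces$test_minor == 2L * pieces$ref_minor &
    (pieces$ref_major + pieces$ref_minor) > 0L
  per_chrom <- do.call(rbind, lapply(split(seq_len(nrow(pieces)),
                                           pieces$chrom), function(i) {
    data.frame(chrom = pieces$chrom[i[1]],
               assessable = sum(len[i]),
               consistent = sum(len[i][consistent[i]]),
               stringsAsFactors = FALSE)
  }))
  per_chrom$fraction <- per_chrom$consistent / per_chrom$assessable
  per_chrom$doubled <- per_chrom$fraction >= threshold
  rownames(per_chrom) <- NULL
  list(per_chrom = per_chrom, n_doubled = sum(per_chrom$doubled))
}
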
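#' Apply one copy-number event to an allele-specific profile
#'
#' Profiles track the two physical parental alleles (`a`, `b`) per segment;
#' the event's `allele` field names the physical allele (`"major"` = a,
#' `"minor"` = b at the ancestral diploid state), so sequential events on a
#' lineage compose: losing allele b then gaining a copy of allele a yields
#' (2, 0), copy-neutral LOH. A whole-genome doubling event (`is_wgd`)
#' doubles both alleles over the entire genome. Copy numbers are floored at
#' zero.
#'
#' @param profile data.frame `chrom`, `start`, `end`, `a`, `b` (0-based
#'   half-open, sorted, non-overlapping).
#' @param event One-row data.frame with `chrom`, `start`, `end`, `allele`,
#'   `delta`, `is_wgd`.
#' @param genome Genome data.frame (`chrom`, `length`), used for bounds
#'   checks.
#' @return The updated profile, with adjacent equal-state segments merged.
#' @export
apply_cna_event <- function(profile, event, genome) {
  if (isTRUE(event$is_wgd)) {
    profile$a <- profile$a * 2L
    profile$b <- profile$b * 2L
    return(merge_equal_segments(profile))
  }
  glen <- genome$length[match(event$chrom, genome$chrom)]
  if (is.na(glen) || event$start < 0 || event$end > glen ||
      event$end <= event$start)
    stop("bounds error: CNA event outside genome", call. = FALSE)

  on_chr <- profile$chrom == event$chrom
  seg <- profile[on_chr, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    cuts <- sort(unique(c(s$start, s$end,
                          pmin(pmax(c(event$start, event$end), s$start), s$end))))
    for (j in seq_len(length(cuts) - 1L)) {
      p <- s
      p$start <- cuts[j]
      p$end <- cuts[j + 1L]
      if (p$start >= event$start && p$end <= event$end) {
        col <- if (identical(event$allele, "major")) "a" else "b"
        p[[col]] <- max(0L, p[[col]] + event$delta)
      }
      pieces[[length(pieces) + 1L]] <- p
    }
  }
  seg <- do.call(rbind, pieces)
  out <- rbind(profile[!on_chr, , drop = FALSE], seg)
  out <- out[order(match(out$chrom, genome$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  merge_equal_segments(out)
}

merge_equal_segments <- function(profile) {
  if (nrow(profile) < 2L) return(profile)
  keep <- rep(TRUE, nrow(profile))
  for (i in 2:nrow(profile)) {
    same <- profile$chrom[i] == profile$chrom[i - 1L] &&
      profile$start[i] == profile$end[i - 1L] &&
      profile$a[i] == profile$a[i - 1L] &&
      profile$b[i] == profile$b[i - 1L]
    if (same) {
      profile$start[i] <- profile$start[i - 1L]
      keep[i - 1L] <- FALSE
    }
  }
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

diploid_profile <- function(genome) {
  data.frame(chrom = genome$chrom, start = 0L,
             end = as.integer(genome$length), a = 1L, b = 1L,
             stringsAsFactors = FALSE)
}

#' Integer allele-specific profile of one clone
#'
#' Applies the branch events along the lineage from the ancestral clone down
#' to `clone`, in ancestral order (within a branch, in the order listed;
#' a whole-genome doubling on a branch is applied after that branch's
#' segmental events).
#'
#' @param tree A `clone_tree`.
#' @param clone Clone id.
#' @param genome Genome data.frame.
#' @return A segment profile data.frame `chrom`, `start`, `end`, `major_cn`,
#'   `minor_cn`.
#' @export
clone_cna_profile <- function(tree, clone, genome) {
  prof <- diploid_profile(genome)
  for (cl in clone_lineage(tree, clone)) {
    ev <- tree$branch_cna[[cl]]
    if (is.null(ev) || nrow(ev) == 0L) next
    ord <- order(ev$is_wgd)  # segmental first, then WGD
    for (i in ord) prof <- apply_cna_event(prof, ev[i, ], genome)
  }
  data.frame(chrom = prof$chrom, start = prof$start, end = prof$end,
             major_cn = pmax(prof$a, prof$b), minor_cn = pmin(prof$a, prof$b),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample allele-specific copy-number profiles
#'
#' Each sample's profile is its dominant clone's integer allele-specific
#' profile, mirroring how bulk genotyping arrays report the majority cell
#' population; fractional clone-mixture copy numbers are out of scope.
#'
#' @param tree A `clone_tree`.
#' @param compositions Output of [simulate_regions()].
#' @param config A [sim_config()] object.
#' @return Named list: sample id -> segment profile data.frame (`chrom`,
#'   `start`, `end`, `major_cn`, `minor_cn`), with the dominant clone in
#'   attribute `"clone"`.
#' @export
simulate_cna_profiles <- function(tree, compositions, config) {
  validate_sim_config(config)
  dom <- dominant_clones(compositions)
  profiles <- lapply(names(dom), function(s) {
    p <- clone_cna_profile(tree, dom[[s]], config$genome)
    attr(p, "clone") <- dom[[s]]
    p
  })
  names(profiles) <- names(dom)
  profiles
}
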
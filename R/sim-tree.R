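#' Simulate a clone phylogeny with branch mutations and CNA events
#'
#' Grows a random recursive tree of `n_clones` clones rooted at the ancestral
#' clone `C1`. Each branch acquires a Poisson number of SNVs under the
#' infinite-sites assumption; the root branch always carries at least one
#' mutation (the TP53 stand-in, always the first mutation id), so every
#' descendant clone inherits an ancestral mutation set. Each branch also
#' acquires segmental copy-number events, and optionally one clone undergoes
#' whole-genome doubling.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `clone_tree`: a list with elements
#'   `clones`, `parent` (named character, `NA` at the root),
#'   `branch_mutations` (named list of mutation ids), `branch_cna` (named
#'   list of event data.frames with columns `chrom`, `start`, `end`,
#'   `allele`, `delta`, `is_wgd`), `wgd_clone` (`NA` or a clone id),
#'   `mutations` (data.frame `mutation_id`, `chrom`, `pos`, `clone`), and
#'   `carriers` (named list: mutation id -> clones carrying it).
#' @export
simulate_clone_tree <- function(config) {
  validate_sim_config(config)
  set.seed(config$random_seed)

  n <- config$n_clones
  clones <- paste0("C", seq_len(n))
  parent <- rep(NA_character_, n)
  names(parent) <- clones
  if (n > 1L) {
    for (i in 2:n) {
      parent[i] <- clones[sample.int(i - 1L, 1L)]
    }
  }

  # SNVs per branch; root branch forced to carry >= 1 (the ancestral set)
  n_mut <- stats::rpois(n, config$mutations_per_branch_mean)
  n_mut[1] <- max(1L, n_mut[1])
  total <- sum(n_mut)
  mut_ids <- sprintf("m%04d", seq_len(max(total, 1L))[seq_len(total)])
  branch_mutations <- split(mut_ids, rep(clones, n_mut))
  branch_mutations <- branch_mutations[intersect(clones, names(branch_mutations))]
  missing <- setdiff(clones, names(branch_mutations))
  for (cl in missing) branch_mutations[[cl]] <- character(0)
  branch_mutations <- branch_mutations[clones]

  genome <- config$genome
  chrom_idx <- sample.int(nrow(genome), total, replace = TRUE)
  mutations <- data.frame(
    mutation_id = mut_ids,
    chrom = genome$chrom[chrom_idx],
    pos = 1L + floor(stats::runif(total) * (genome$length[chrom_idx] - 1)),
    clone = rep(clones, n_mut),
    stringsAsFactors = FALSE
  )

  wgd <- config$wgd_clone
  if (identical(wgd, "none")) {
    wgd <- NA_character_
  } else if (identical(wgd, "random")) {
    wgd <- if (n > 1L) clones[1L + sample.int(n - 1L, 1L)] else NA_character_
  } else if (!is.na(wgd) && !wgd %in% clones) {
    stop("configuration error: wgd_clone not in tree", call. = FALSE)
  }

  branch_cna <- lapply(clones, function(cl) {
    k <- stats::rpois(1L, config$cna_events_per_branch_mean)
    ev <- simulate_cna_events(k, genome, config$cna_length_range)
    if (!is.na(wgd) && cl == wgd) {
      ev <- rbind(ev, data.frame(chrom = NA_character_, start = 0L, end = 0L,
                                 allele = NA_character_, delta = 0L,
                                 is_wgd = TRUE, stringsAsFactors = FALSE))
    }
    ev
  })
  names(branch_cna) <- clones

  tree <- structure(list(
    clones = clones,
    parent = parent,
    branch_mutations = branch_mutations,
    branch_cna = branch_cna,
    wgd_clone = wgd,
    mutations = mutations
  ), class = "clone_tree")
  tree$carriers <- clone_carriers(tree)
  tree
}

simulate_cna_events <- function(k, genome, length_range) {
  if (k == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), allele = character(0),
                      delta = integer(0), is_wgd = logical(0),
                      stringsAsFactors = FALSE))
  }
  idx <- sample.int(nrow(genome), k, replace = TRUE)
  len <- stats::runif(k, length_range[1], length_range[2])
  len <- pmin(len, genome$length[idx])
  start <- floor(stats::runif(k) * (genome$length[idx] - len))
  data.frame(
    chrom = genome$chrom[idx],
    start = as.integer(start),
    end = as.integer(start + len),
    allele = sample(c("major", "minor"), k, replace = TRUE),
    delta = sample(c(-1L, 1L, 1L), k, replace = TRUE),
    is_wgd = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Lineage of a clone, root first
#' @param tree A `clone_tree`.
#' @param clone Clone id.
#' @return Character vector of clone ids from the root down to `clone`.
#' @export
clone_lineage <- function(tree, clone) {
  path <- clone
  while (!is.na(tree$parent[[path[1]]])) {
    path <- c(tree$parent[[path[1]]], path)
  }
  path
}

#' Per-mutation carrier clone sets
#'
#' A clone carries every mutation acquired on its own branch and on each
#' ancestral branch, so root-branch mutations are carried by all clones.
#'
#' @param tree A `clone_tree`.
#' @return Named list: mutation id -> character vector of carrying clones.
#' @export
clone_carriers <- function(tree) {
  per_clone <- lapply(tree$clones, function(cl) {
    unlist(tree$branch_mutations[clone_lineage(tree, cl)], use.names = FALSE)
  })
  names(per_clone) <- tree$clones
  ids <- tree$mutations$mutation_id
  carriers <- lapply(ids, function(m) {
    tree$clones[vapply(per_clone, function(s) m %in% s, logical(1))]
  })
  names(carriers) <- ids
  carriers
}
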
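# Hand-built clone tree with fully controlled branch mutations / CNA events.
# Mutation sites are placed along chr1 unless a sites table is supplied.
make_clone_tree <- function(parent, branch_mutations,
                            branch_cna = NULL, wgd_clone = NA_character_,
                            genome = default_genome(), sites = NULL) {
  clones <- names(parent)
  if (is.null(branch_cna)) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), allele = character(0),
                        delta = integer(0), is_wgd = logical(0))
    branch_cna <- stats::setNames(rep(list(empty), length(clones)), clones)
  }
  ids <- unlist(branch_mutations, use.names = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(mutation_id = ids, chrom = "chr1",
                        pos = seq(1e6, by = 1e6, length.out = length(ids)),
                        stringsAsFactors = FALSE)
  }
  sites$clone <- rep(names(branch_mutations),
                     lengths(branch_mutations))[match(sites$mutation_id, ids)]
  tree <- structure(list(
    clones = clones, parent = parent,
    branch_mutations = branch_mutations, branch_cna = branch_cna,
    wgd_clone = wgd_clone, mutations = sites
  ), class = "clone_tree")
  tree$carriers <- clone_carriers(tree)
  tree
}

# Counts table from a (mutations x samples) matrix of var counts at a
# shared constant depth (or a matching depth matrix).
make_counts <- function(var, depth = 1000) {
  if (!is.matrix(depth))
    depth <- matrix(depth, nrow = nrow(var), ncol = ncol(var),
                    dimnames = dimnames(var))
  grid <- expand.grid(mutation_id = rownames(var),
                      sample_id = colnames(var),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  v <- var[cbind(grid$mutation_id, grid$sample_id)]
  d <- depth[cbind(grid$mutation_id, grid$sample_id)]
  data.frame(grid, chrom = "chr1",
             pos = match(grid$mutation_id, rownames(var)) * 1000L,
             ref_count = d - v, var_count = v, stringsAsFactors = FALSE)
}

# Segment profile shorthand
make_profile <- function(chrom, start, end, major, minor) {
  data.frame(chrom = chrom, start = start, end = end,
             major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
}

# A small genome for CNA tests
toy_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr3"),
             length = c(100, 200, 300), stringsAsFactors = FALSE)
}
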
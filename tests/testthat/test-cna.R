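test_that("zygosity classification is a total function of (major, minor)", {
  expect_equal(classify_zygosity(0, 0), "HOMD")
  expect_equal(classify_zygosity(1, 0), "HEMD")
  expect_equal(classify_zygosity(1, 1), "HET")
  expect_equal(classify_zygosity(2, 0), "NLOH")
  expect_equal(classify_zygosity(c(3, 5), c(0, 0)), c("ALOH", "ALOH"))
  expect_equal(classify_zygosity(2, 2), "BCNA")
  expect_equal(classify_zygosity(c(2, 3, 4), c(1, 1, 2)),
               c("ASCNA", "ASCNA", "ASCNA"))
  expect_error(classify_zygosity(1, 2), "minor")
  expect_error(classify_zygosity(-1, -1), "negative")
})

test_that("compound weights match the architecture-tree weight table", {
  expect_equal(compound_weight(c("ALOH", "NLOH", "HOMD")), c(2L, 2L, 2L))
  expect_equal(compound_weight("HEMD"), 1L)
  expect_equal(compound_weight(c("HET", "ASCNA", "BCNA")), c(0L, 0L, 0L))
  expect_error(compound_weight("XYZ"), "unknown")
})

test_that("compound fraction is length arithmetic over NLOH/ALOH segments", {
  genome <- toy_genome()
  all_het <- make_profile(genome$chrom, 0, genome$length, 1, 1)
  expect_equal(compound_fraction(all_het, genome), 0)

  p <- make_profile(c("chr1", "chr2", "chr3", "chr3"),
                    c(0, 0, 0, 150), c(100, 200, 150, 300),
                    c(2, 1, 3, 1), c(0, 1, 0, 1))
  # NLOH over chr1 (100) + ALOH over half of chr3 (150) out of 600
  expect_equal(compound_fraction(p, genome), 250 / 600)
  expect_warning(out <- compound_fraction(p[0, ], genome), "empty")
  expect_equal(out, 0)

  # half NLOH / half HET on a single chromosome
  g1 <- genome[1, ]
  half <- make_profile("chr1", c(0, 50), c(50, 100), c(2, 1), c(0, 1))
  expect_equal(compound_fraction(half, g1), 0.5)
})

test_that("compound fraction is invariant under segment splitting", {
  genome <- toy_genome()
  whole <- make_profile(c("chr1", "chr2", "chr3"), 0, genome$length,
                        c(2, 1, 3), c(0, 1, 0))
  split2 <- make_profile(
    c("chr1", "chr1", "chr2", "chr3", "chr3"),
    c(0, 40, 0, 0, 111), c(40, 100, 200, 111, 300),
    c(2, 2, 1, 3, 3), c(0, 0, 1, 0, 0))
  expect_equal(compound_fraction(split2, genome),
               compound_fraction(whole, genome))
})

test_that("genes take the state of the segment containing their midpoint", {
  prof <- make_profile("chr1", c(0, 50), c(50, 100), c(2, 1), c(0, 1))
  genes <- data.frame(
    gene = c("inside", "spanning", "gap"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10, 40, 10), end = c(20, 70, 20), stringsAsFactors = FALSE)
  out <- project_to_genes(prof, genes)
  expect_equal(out$state[out$gene == "inside"], "NLOH")
  # midpoint of [40, 70) is 55: second segment decides
  expect_equal(out$state[out$gene == "spanning"], "HET")
  expect_true(is.na(out$state[out$gene == "gap"]))
  expect_equal(out$weight, c(2L, 0L, NA))
})

test_that("architecture tree distances follow Euclidean arithmetic on weights", {
  W <- rbind(A = c(2, 2, 0), B = c(2, 0, 0))
  out <- cna_distance_tree(W)
  expect_equal(unname(out$distances["A", "B"]), 2)
  expect_equal(unname(out$distances["A", "control"]), sqrt(8))
  expect_equal(unname(out$distances["B", "control"]), 2)
  expect_s3_class(out$tree, "phylo")

  # all-HET samples coincide with the zero control
  W0 <- rbind(A = c(0, 0, 0), B = c(0, 0, 0), C = c(0, 0, 0))
  out0 <- cna_distance_tree(W0)
  expect_true(all(out0$distances[, "control"] == 0))

  # identical profiles at distance 0 from each other
  W2 <- rbind(A = c(2, 1, 0), B = c(2, 1, 0), C = c(0, 0, 2))
  out2 <- cna_distance_tree(W2)
  expect_equal(unname(out2$distances["A", "B"]), 0)

  # genes unassessed in any sample are dropped; empty universe errors
  W3 <- rbind(A = c(NA, 1), B = c(2, NA))
  expect_error(cna_distance_tree(W3), "empty")
})

test_that("pairwise concordance counts genes by total CN and shared zygosity", {
  prof1 <- make_profile("chr1", 0, 100, 1, 0)
  prof2 <- make_profile("chr1", 0, 100, 2, 0)
  prof3 <- make_profile("chr1", 0, 100, 1, 1)
  genes <- data.frame(gene = paste0("g", 1:5), chrom = "chr1",
                      start = seq(0, 80, 20), end = seq(10, 90, 20),
                      stringsAsFactors = FALSE)
  gA <- project_to_genes(prof1, genes)
  gB <- project_to_genes(prof2, genes)
  tab <- pairwise_state_concordance(gA, gB)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$cn_a, 1); expect_equal(tab$cn_b, 2)
  expect_true(tab$same_zygosity); expect_equal(tab$n, 5)

  # equal total CN but differing zygosity: (1,1) vs (2,0)
  tab2 <- pairwise_state_concordance(project_to_genes(prof3, genes), gB)
  expect_equal(tab2$cn_a, 2); expect_equal(tab2$cn_b, 2)
  expect_false(tab2$same_zygosity)

  # identical profiles: diagonal mass, all same zygosity
  tab3 <- pairwise_state_concordance(gA, gA)
  expect_true(all(tab3$cn_a == tab3$cn_b) && all(tab3$same_zygosity))
})

test_that("doubling detection follows the allele-wise doubling signature", {
  genome <- toy_genome()
  ref <- make_profile(c("chr1", "chr2", "chr3"), 0, genome$length,
                      c(1, 1, 2), c(0, 1, 1))
  doubled <- make_profile(c("chr1", "chr2", "chr3"), 0, genome$length,
                          c(2, 2, 4), c(0, 2, 2))
  out <- detect_doubling(ref, doubled)
  expect_true(all(out$per_chrom$doubled))
  expect_equal(out$n_doubled, 3)

  # identity is not doubling (and (0,0) -> (0,0) does not count)
  ref2 <- make_profile(c("chr1", "chr2"), 0, c(100, 200),
                       c(1, 0), c(1, 0))
  out2 <- detect_doubling(ref2, ref2)
  expect_equal(out2$n_doubled, 0)

  # half-chromosome doubling: fraction 0.5 flagged at threshold 0.5
  ref3 <- make_profile(c("chr1", "chr1"), c(0, 50), c(50, 100),
                       c(1, 1), c(0, 1))
  test3 <- make_profile(c("chr1", "chr1"), c(0, 50), c(50, 100),
                        c(2, 1), c(0, 1))
  out3 <- detect_doubling(ref3, test3, threshold = 0.5)
  expect_equal(out3$per_chrom$fraction, 0.5)
  expect_true(out3$per_chrom$doubled)
  expect_equal(detect_doubling(ref3, test3, threshold = 0.6)$n_doubled, 0)

  expect_error(detect_doubling(ref3, make_profile("chr9", 0, 10, 1, 1)),
               "disjoint")
})

test_that("whole-genome doubling maps HEMD to NLOH and HET to balanced 2+2", {
  genome <- toy_genome()
  ref <- make_profile(c("chr1", "chr2"), 0, c(100, 200), c(1, 1), c(0, 1))
  wgd <- data.frame(chrom = NA, start = 0L, end = 0L, allele = NA,
                    delta = 0L, is_wgd = TRUE)
  doubled <- local({
    p <- data.frame(chrom = ref$chrom, start = ref$start, end = ref$end,
                    a = ref$major_cn, b = ref$minor_cn)
    p <- apply_cna_event(p, wgd, genome)
    make_profile(p$chrom, p$start, p$end, pmax(p$a, p$b), pmin(p$a, p$b))
  })
  st <- classify_zygosity(doubled$major_cn, doubled$minor_cn)
  expect_equal(st, c("NLOH", "BCNA"))
  expect_equal(detect_doubling(ref, doubled)$n_doubled, 2)
})

test_that("simulated WGD descendants are flagged against non-WGD references", {
  cfg <- sim_config(n_clones = 4, wgd_clone = "random", random_seed = 77)
  tree <- simulate_clone_tree(cfg)
  expect_false(is.na(tree$wgd_clone))
  wgd_desc <- Filter(function(cl)
    tree$wgd_clone %in% clone_lineage(tree, cl), tree$clones)
  non_wgd <- setdiff(tree$clones, wgd_desc)
  profs <- lapply(tree$clones, clone_cna_profile, tree = tree,
                  genome = cfg$genome)
  names(profs) <- tree$clones
  out <- detect_doubling(profs[[non_wgd[1]]], profs[[wgd_desc[1]]])
  expect_gte(out$n_doubled, 20)
  if (length(non_wgd) > 1) {
    out0 <- detect_doubling(profs[[non_wgd[1]]], profs[[non_wgd[2]]])
    expect_lte(out0$n_doubled, 2)
  }
})
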
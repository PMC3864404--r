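test_that("degenerate single-clone tree puts every mutation in the ancestral clone", {
  cfg <- sim_config(n_clones = 1, n_samples = 2, random_seed = 3)
  tree <- simulate_clone_tree(cfg)
  expect_identical(tree$clones, "C1")
  expect_true(all(vapply(tree$carriers, identical, logical(1), "C1")))
  comp <- simulate_regions(tree, cfg)
  expect_true(all(comp$fraction == 1))
})

test_that("simulation is a pure function of the configuration", {
  cfg <- sim_config(random_seed = 7)
  t1 <- simulate_clone_tree(cfg)
  t2 <- simulate_clone_tree(cfg)
  expect_identical(t1, t2)
  c1 <- simulate_amplicon_counts(t1, simulate_regions(t1, cfg), cfg)
  c2 <- simulate_amplicon_counts(t2, simulate_regions(t2, cfg), cfg)
  expect_identical(c1, c2)
  expect_identical(simulate_ctdna(t1, cfg), simulate_ctdna(t2, cfg))
})

test_that("total mutation count matches the Poisson closed form", {
  totals <- vapply(seq_len(1000), function(s) {
    cfg <- sim_config(n_clones = 5, n_samples = 1,
                      mutations_per_branch_mean = 20, random_seed = s)
    nrow(simulate_clone_tree(cfg)$mutations)
  }, numeric(1))
  # sum of 5 Poisson(20) branches: mean 100, per-replicate SD 10
  se <- 10 / sqrt(1000)
  expect_lt(abs(mean(totals) - 100), 3 * se)
})

test_that("flat Dirichlet mixture fractions have the closed-form mean", {
  set.seed(42)
  draws <- t(replicate(1e4, clonescape:::rdirichlet_flat(3)))
  expect_true(all(abs(rowSums(draws) - 1) < 1e-9))
  # each component is Beta(1, 2): mean 1/3, var 1/18
  se <- sqrt(1 / 18 / 1e4)
  expect_true(all(abs(colMeans(draws) - 1 / 3) < 3 * se))
})

test_that("sparsity one gives clone-pure regional samples", {
  cfg <- sim_config(n_clones = 5, n_samples = 8, region_support_max = 1,
                    random_seed = 11)
  comp <- simulate_regions(simulate_clone_tree(cfg), cfg)
  expect_true(all(comp$fraction == 1))
  expect_equal(nrow(comp), 8)
})

test_that("observed VAF follows the t*f/2 diploid rule in expectation", {
  cfg <- sim_config(n_clones = 1, n_samples = 1,
                    mutations_per_branch_mean = 1000,
                    sequencing_error_rate = 0, random_seed = 5)
  tree <- simulate_clone_tree(cfg)
  comp <- data.frame(sample_id = "S01", clone = "C1", fraction = 1,
                     tumour_content = 1)
  counts <- simulate_amplicon_counts(tree, comp, cfg)
  vaf <- counts$var_count / (counts$ref_count + counts$var_count)
  expect_lt(abs(mean(vaf) - 0.5), 0.01)
  expect_true(all(counts$true_vaf == 0.5))
})

test_that("absent sites draw variant reads at the error rate alone", {
  cfg <- sim_config(n_clones = 1, n_samples = 1,
                    mutations_per_branch_mean = 1000,
                    sequencing_error_rate = 0.001, random_seed = 5)
  tree <- simulate_clone_tree(cfg)
  # tumour content 0: no mutation-carrying cells in the sample
  comp <- data.frame(sample_id = "S01", clone = "C1", fraction = 1,
                     tumour_content = 0)
  counts <- simulate_amplicon_counts(tree, comp, cfg)
  expect_lt(abs(mean(counts$var_count) - 5), 0.5)

  # and zero carrier fraction with zero error gives exactly zero
  cfg0 <- sim_config(n_clones = 1, n_samples = 1,
                     mutations_per_branch_mean = 100,
                     sequencing_error_rate = 0, random_seed = 5)
  counts0 <- simulate_amplicon_counts(simulate_clone_tree(cfg0), comp, cfg0)
  expect_true(all(counts0$var_count == 0))
})

test_that("ancestral mutations are carried everywhere, private ones only downstream", {
  cfg <- sim_config(n_clones = 6, random_seed = 19)
  tree <- simulate_clone_tree(cfg)
  comp <- simulate_regions(tree, cfg)
  f <- clonescape:::carrier_fractions(tree, comp)
  anc <- tree$branch_mutations$C1
  expect_true(all(f[anc, ] > 0))
  by_sample <- split(comp, comp$sample_id)
  for (m in tree$mutations$mutation_id) {
    no_carrier <- vapply(by_sample, function(d)
      !any(d$clone %in% tree$carriers[[m]]), logical(1))
    if (any(no_carrier)) expect_true(all(f[m, no_carrier] == 0))
    if (any(!no_carrier)) expect_true(all(f[m, !no_carrier] > 0))
  }
})

test_that("copy-number events compose sequentially into compound states", {
  genome <- toy_genome()
  prof <- clonescape:::diploid_profile(genome)
  # no events: everything diploid heterozygous
  expect_true(all(prof$a == 1 & prof$b == 1))

  del <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                    allele = "minor", delta = -1L, is_wgd = FALSE)
  wgd <- data.frame(chrom = NA, start = 0L, end = 0L, allele = NA,
                    delta = 0L, is_wgd = TRUE)
  amp <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                    allele = "major", delta = 1L, is_wgd = FALSE)

  # deletion then whole-genome doubling: NLOH on the deleted segment
  p <- apply_cna_event(apply_cna_event(prof, del, genome), wgd, genome)
  chr1 <- p[p$chrom == "chr1", ]
  expect_equal(classify_zygosity(max(chr1$a, chr1$b), min(chr1$a, chr1$b)),
               "NLOH")
  # untouched chromosomes double to balanced (2,2)
  chr2 <- p[p$chrom == "chr2", ]
  expect_equal(c(chr2$a, chr2$b), c(2, 2))

  # deletion then +1 on the remaining allele: (2,0), classified NLOH
  p2 <- apply_cna_event(apply_cna_event(prof, del, genome), amp, genome)
  chr1 <- p2[p2$chrom == "chr1", ]
  expect_equal(c(chr1$a, chr1$b), c(2, 0))
  expect_equal(classify_zygosity(2, 0), "NLOH")
})

test_that("events outside the genome and invalid configs are rejected", {
  genome <- toy_genome()
  prof <- clonescape:::diploid_profile(genome)
  bad <- data.frame(chrom = "chr1", start = 50L, end = 150L,
                    allele = "major", delta = 1L, is_wgd = FALSE)
  expect_error(apply_cna_event(prof, bad, genome), "bounds")
  expect_error(sim_config(n_clones = 0), "n_clones")
  expect_error(sim_config(mutations_per_branch_mean = -1), "configuration")
  expect_error(sim_config(sequencing_error_rate = 1.5), "error_rate")
})

test_that("plasma counts scale with the plasma tumour fraction", {
  cfg <- sim_config(n_clones = 1, mutations_per_branch_mean = 500,
                    plasma_tumour_fraction = 0.1,
                    sequencing_error_rate = 0, random_seed = 23)
  tree <- simulate_clone_tree(cfg)
  plasma <- simulate_ctdna(tree, cfg)
  vaf <- plasma$var_count / (plasma$ref_count + plasma$var_count)
  expect_lt(abs(mean(vaf) - 0.05), 0.005)

  cfg0 <- sim_config(n_clones = 1, mutations_per_branch_mean = 500,
                     plasma_tumour_fraction = 0,
                     sequencing_error_rate = 0, random_seed = 23)
  plasma0 <- simulate_ctdna(simulate_clone_tree(cfg0), cfg0)
  expect_true(all(plasma0$var_count == 0))
})
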
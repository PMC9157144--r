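test_that("simulation is byte-identical under a fixed configuration", {
  cfg <- sim_config(K = 20, M = 400, chrom_length = 4e5, seed = 5)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  t1 <- sample_study_individuals(p1, 3, seed = 9)
  t2 <- sample_study_individuals(p2, 3, seed = 9)
  expect_identical(t1, t2)
  r1 <- simulate_reads(t1, p1$markers, cfg, coverage = 2)
  r2 <- simulate_reads(t2, p2$markers, cfg, coverage = 2)
  expect_identical(r1, r2)
})

test_that("degenerate generator settings collapse the panel onto haplotype 1", {
  cfg <- sim_config(K = 4, M = 60, theta_sim = 0, rho_scale = 0,
                    n_diverged = 0, seed = 2)
  p <- generate_panel(cfg)
  for (k in 2:4) expect_identical(p$haplotypes[k, ], p$haplotypes[1, ])
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(K = 5), "even")
  expect_error(sim_config(M = 1), "M must be")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(delta = 1.5), "probability")
})

test_that("site-frequency spectrum is skewed toward rare alleles", {
  p <- generate_panel(sim_config(K = 100, M = 5000, seed = 11,
                                 n_diverged = 0))
  # independent tally from column sums
  counts <- colSums(p$haplotypes)
  maf <- pmin(counts, 100 - counts) / 100
  tab <- tabulate(ceiling(maf[maf > 0] * 20), 10)
  expect_equal(which.max(tab), 1L)
  expect_true(all(diff(tab[1:6]) < 0))
  expect_gt(tab[1] / sum(tab), 0.4)
  # and the stored panel MAF agrees with the tally
  expect_equal(p$markers$maf, pmin(counts, 100 - counts) / 100)
})

test_that("study individuals are faithful panel mosaics", {
  cfg <- sim_config(K = 12, M = 300, theta_sim = 0, rho_scale = 0,
                    n_diverged = 0, seed = 21)
  p <- generate_panel(cfg)
  # identical-haplotype panel: every study genotype is homozygous for it
  truth <- sample_study_individuals(p, 4, theta_sim = 0, seed = 3)
  expect_true(all(truth$genotypes == rep(2L * p$haplotypes[1, ],
                                         each = 4L)))
  # full divergence flips every copied allele
  td <- sample_study_individuals(p, 2, theta_sim = 0, divergence_rate = 1,
                                 seed = 3)
  src <- attr(td, "source_alleles")
  expect_true(all(td$haplotypes == 1L - src))
  expect_error(sample_study_individuals(p, 2, divergence_rate = 1.2),
               "divergence_rate")
  expect_error(sample_study_individuals(p, 0), "n must be")
})

test_that("miscopy rate of study mosaics matches theta within binomial error", {
  cfg <- sim_config(K = 40, M = 2000, chrom_length = 2e6, seed = 13)
  p <- generate_panel(cfg)
  truth <- sample_study_individuals(p, 50, theta_sim = 0.001, seed = 17)
  src <- attr(truth, "source_alleles")
  n_alleles <- length(src)
  flips <- sum(truth$haplotypes != src)
  se <- sqrt(n_alleles * 0.001 * 0.999)
  expect_lt(abs(flips - n_alleles * 0.001), 3 * se)
})

test_that("read simulation follows the error and deamination rules", {
  cfg <- sim_config(K = 4, M = 3, seed = 1, eps = 0, delta = 0)
  markers <- make_markers(ref = c("C", "A", "G"), alt = c("T", "C", "A"))
  truth <- make_truth(matrix(0L, 2, 3))  # one hom-ref individual
  pile <- simulate_reads(truth, markers, cfg, coverage = 50)
  expect_true(all(pile$n_alt == 0L))

  # C/T site, true C/C, delta = 0.5: half of the reads count as the T allele
  cfg2 <- sim_config(K = 4, M = 3, seed = 8, eps = 0, delta = 0.5)
  pile2 <- simulate_reads(truth, markers, cfg2, coverage = 2000)
  frac <- pile2$n_alt[1, 1] / (pile2$n_alt[1, 1] + pile2$n_ref[1, 1])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
  # transversion A/C with genotype A/A never gains alt counts, even delta = 1
  cfg3 <- sim_config(K = 4, M = 3, seed = 8, eps = 0, delta = 1)
  pile3 <- simulate_reads(truth, markers, cfg3, coverage = 200)
  expect_identical(pile3$n_alt[1, 2], 0L)
  # G/A site with genotype G/G and delta = 1: every read deaminates to alt
  expect_identical(pile3$n_ref[1, 3], 0L)
  expect_gt(pile3$n_alt[1, 3], 0L)

  expect_error(simulate_reads(truth, markers[1:2, ], cfg), "marker list")
})

test_that("read depth is Poisson with the target mean", {
  cfg <- sim_config(K = 4, M = 10000, chrom_length = 1e7, seed = 4,
                    delta = 0, eps = 0)
  markers <- generate_panel(sim_config(K = 4, M = 10000, chrom_length = 1e7,
                                       seed = 4))$markers
  truth <- make_truth(matrix(0L, 10, 10000))
  pile <- simulate_reads(truth, markers, cfg, coverage = 2)
  dp <- as.vector(pileup_depth(pile))  # 100,000 site-individual draws
  expect_lt(abs(mean(dp) - 2) / 2, 0.05)
  expect_lt(abs(var(dp) - 2) / 2, 0.05)
})

test_that("deamination creates excess alt evidence only where the product matches the other allele", {
  cfg <- sim_config(K = 4, M = 4, seed = 31, eps = 0, delta = 0.2)
  markers <- make_markers(ref = c("C", "T", "A", "G"),
                          alt = c("T", "C", "C", "C"))
  truth <- make_truth(matrix(0L, 2, 4))  # hom-ref
  pile <- simulate_reads(truth, markers, cfg, coverage = 2000)
  expect_gt(pile$n_alt[1, 1], 0L)        # C->T feeds the alt allele
  expect_identical(pile$n_alt[1, 2], 0L) # ref T cannot deaminate
  expect_identical(pile$n_alt[1, 3], 0L) # transversion: product matches neither
  expect_identical(pile$n_alt[1, 4], 0L) # G->A, but alt is C
})

test_that("downsampling is binomial thinning with composable rates", {
  set.seed(71)
  cfg <- sim_config(K = 4, M = 20000, chrom_length = 2e7, seed = 6,
                    delta = 0, eps = 0)
  truth <- make_truth(matrix(rbinom(2 * 20000, 1, 0.3), 2, 20000))
  markers <- make_markers(rep("A", 20000), rep("C", 20000))
  pile <- simulate_reads(truth, markers, cfg, coverage = 2)

  same <- downsample(pile, pile$realized_coverage[1], seed = 1)
  expect_identical(same$n_ref[1, ], pile$n_ref[1, ])
  zero <- downsample(pile, 0, seed = 1)
  expect_true(all(pileup_depth(zero) == 0L))
  expect_error(downsample(pile, 5), "exceeds")

  half <- downsample(pile, 0.5, seed = 2)
  expect_true(all(half$n_ref <= pile$n_ref & half$n_alt <= pile$n_alt))
  expect_lt(abs(mean(pileup_depth(half)) - 0.5), 3 * sqrt(0.5 / 40000))

  # two-step thinning 2x -> 1x -> 0.5x matches direct 2x -> 0.5x in
  # distribution (depth histograms agree within sampling tolerance)
  two_step <- downsample(downsample(pile, 1, seed = 3), 0.5, seed = 4)
  h1 <- tabulate(pmin(as.vector(pileup_depth(two_step)), 5L) + 1L, 6L) / 40000
  h2 <- tabulate(pmin(as.vector(pileup_depth(half)), 5L) + 1L, 6L) / 40000
  expect_lt(max(abs(h1 - h2)), 0.01)
})
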
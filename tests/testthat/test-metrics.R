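fake_truth_calls <- function(gt) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  structure(list(gt = gt, dp = 0 * gt + 30L, qual = 0 * gt + 99,
                 pass = !is.na(gt)), class = "truth_calls")
}

fake_imputed <- function(best, max_gp = rep(1, length(best))) {
  gp <- matrix(0, 3, length(best))
  gp[cbind(best + 1L, seq_along(best))] <- max_gp
  off <- (1 - max_gp) / 2
  for (g in 0:2) gp[g + 1L, best != g] <- off[best != g]
  structure(list(gp = gp, q = rbind(gp[1, ], gp[2, ] / 2, gp[2, ] / 2,
                                    gp[3, ]),
                 dosage = gp[2, ] + 2 * gp[3, ], best_gt = best,
                 max_gp = max_gp), class = "imputed_genotypes")
}

test_that("overlap splitting partitions the evaluable sites", {
  truth <- fake_truth_calls(c(0L, 1L, 2L, 0L))
  mask <- split_overlap(make_pileup(c(1L, 1L, 2L, 0L), c(0L, 1L, 0L, 0L)),
                        truth)
  expect_equal(mask$overlapping[1, ], c(TRUE, TRUE, TRUE, FALSE))
  mask2 <- split_overlap(make_pileup(c(0L, 2L, 0L, 1L), c(0L, 0L, 0L, 0L)),
                         truth)
  expect_equal(which(mask2$overlapping[1, ]), c(2L, 4L))
  # partition invariant
  ht <- mask2$has_truth[1, ]
  expect_equal(sum(ht & mask2$overlapping[1, ]) +
                 sum(ht & !mask2$overlapping[1, ]), sum(ht))
  expect_error(split_overlap(make_pileup(0L, 0L), truth), "match")
})

test_that("concordance stratifies by overlap and gold-standard genotype class", {
  truth <- fake_truth_calls(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 1L, 2L))
  mask <- split_overlap(make_pileup(rep(1L, 10), rep(0L, 10)), truth)

  perfect <- concordance(list(fake_imputed(truth$gt[1, ])), truth, mask)
  expect_true(all(perfect$concordance[perfect$n > 0] == 1))

  two_off <- truth$gt[1, ]
  two_off[c(1, 2)] <- c(2L, 0L)
  cc <- concordance(list(fake_imputed(two_off)), truth, mask)
  expect_equal(cc$concordance[cc$stratum == "all" & cc$class == "all"], 0.8)

  # all-heterozygous truth imputed hom-ref: het stratum 0, hom-ref undefined
  truth_het <- fake_truth_calls(rep(1L, 6))
  mask_h <- split_overlap(make_pileup(rep(1L, 6), rep(0L, 6)), truth_het)
  cc2 <- concordance(list(fake_imputed(rep(0L, 6))), truth_het, mask_h)
  expect_equal(cc2$concordance[cc2$stratum == "all" & cc2$class == "het"], 0)
  expect_true(is.na(cc2$concordance[cc2$stratum == "all" &
                                      cc2$class == "hom_ref"]))
  expect_equal(cc2$n[cc2$stratum == "all" & cc2$class == "hom_ref"], 0)
})

test_that("MAF bins are left-open, equal width, excluding monomorphic sites", {
  expect_equal(maf_bin(c(0.005, 0.01, 0.011, 0.5)), c(1L, 1L, 2L, 50L))
  expect_true(is.na(maf_bin(0)))
  expect_error(maf_bin(0.6), "maf")
  expect_error(maf_bin(-0.1), "maf")
})

test_that("heterozygote discordance curves report per-bin rates and gaps", {
  truth <- fake_truth_calls(rep(1L, 8))
  mask <- split_overlap(make_pileup(rep(1L, 8), rep(0L, 8)), truth)
  maf <- rep(0.105, 8)  # all sites in bin 11
  perfect <- het_discordance_by_maf(list(fake_imputed(rep(1L, 8))), truth,
                                    maf, mask = mask)
  sub <- perfect[perfect$stratum == "all", ]
  expect_equal(sub$discordance[sub$bin == 11], 0)
  expect_true(all(is.na(sub$discordance[sub$bin != 11])))

  half <- het_discordance_by_maf(
    list(fake_imputed(c(rep(1L, 4), rep(0L, 4)))), truth, maf, mask = mask)
  sub <- half[half$stratum == "all", ]
  expect_equal(sub$discordance[sub$bin == 11], 0.5)
  expect_equal(sub$n[sub$bin == 11], 8)
})

test_that("reference affinity counts agreement with the panel modal genotype", {
  # 4-individual toy panel with genotype counts (2 hom-ref, 1 het, 1 hom-alt)
  H <- matrix(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L), 8, 1)
  panel <- make_panel(H, rho = numeric(0))
  expect_equal(modal_genotypes(panel), 0L)
  expect_equal(reference_affinity(0L, panel), 1)
  expect_equal(reference_affinity(1L, panel), 0)

  H2 <- matrix(0L, 4, 6)  # modal hom-ref at all sites
  panel2 <- make_panel(H2)
  expect_equal(reference_affinity(c(0L, 1L, 0L, 1L, 0L, 1L), panel2), 0.5)
  expect_error(modal_genotypes(make_panel(H2[0, , drop = FALSE])), "panel")
})

test_that("affinity difference is zero for perfect imputation and signed as defined", {
  H <- matrix(0L, 4, 6)
  panel <- make_panel(H)
  maf <- rep(0.3, 6)
  truth_gts <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 1)
  same <- affinity_difference_curve(truth_gts, truth_gts, panel, maf)
  expect_equal(same$affinity_difference[same$n > 0], 0)
  # imputed = modal everywhere while truth is half-modal: difference -0.5
  modal_imp <- matrix(0L, 1, 6)
  d <- affinity_difference_curve(truth_gts, modal_imp, panel, maf)
  expect_equal(d$affinity_difference[d$n > 0], -0.5)
})

test_that("posterior probability filtering reports retained fractions", {
  expect_error(gp_filter(list(), min_gp = 0), "min_gp")
  expect_error(gp_filter(list(), min_gp = 1.01), "min_gp")

  imp <- fake_imputed(c(0L, 0L), max_gp = c(0.995, 0.5))
  res <- gp_filter(list(imp), min_gp = 0.99)
  expect_equal(res$kept[[1]], c(TRUE, FALSE))
  expect_equal(res$retained$retained, 0.5)

  all_sure <- fake_imputed(c(0L, 1L, 2L), max_gp = rep(1, 3))
  expect_equal(gp_filter(list(all_sure))$retained$retained, 1)

  withbin <- gp_filter(list(imp), min_gp = 0.99, maf = c(0.05, 0.05))
  expect_equal(withbin$by_bin$mean[5], 0.5)
})
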
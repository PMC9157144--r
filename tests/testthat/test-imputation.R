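test_that("window planning advances by the stride and stitches by nearest midpoint", {
  plan <- plan_windows(100000, 50000, 25000)
  expect_equal(plan$start, c(1, 25001, 50001))
  expect_equal(plan$end, c(50000, 75000, 100000))

  expect_equal(nrow(plan_windows(30000, 50000, 25000)), 1L)
  expect_equal(plan_windows(30000, 50000, 25000)$end, 30000)

  plan2 <- plan_windows(70, 50, 25)
  expect_equal(plan2$start, c(1, 26))
  expect_equal(plan2$end, c(50, 70))
  src <- attr(plan2, "source")
  # midpoints are 25.5 and 48; the boundary falls between markers 36 and 37
  expect_equal(src[36], 1L)
  expect_equal(src[37], 2L)
  expect_equal(src[40], 2L)

  expect_error(plan_windows(100, 50, 50), "overlap")
  expect_error(plan_windows(100, 50, 60), "overlap")
})

test_that("degenerate panels produce the posteriors they force", {
  # all-ref panel, no miscopy: only ref alleles can be copied
  H <- matrix(0L, 4, 6)
  gl <- make_gl(matrix(1, 3, 6))
  imp <- impute_individual(gl, make_panel(H), hmm_params(tau = rep(0.1, 5),
                                                         theta = 0))
  expect_equal(imp$gp[1, ], rep(1, 6))
  expect_equal(imp$best_gt, rep(0L, 6))
  expect_equal(imp$dosage, rep(0, 6))

  # single marker, alleles {0, 1}, uniform likelihood: 4 ordered pairs
  H2 <- matrix(c(0L, 1L), 2, 1)
  imp2 <- impute_individual(make_gl(matrix(1, 3, 1)), make_panel(H2),
                            hmm_params(tau = numeric(0), theta = 0))
  expect_equal(imp2$gp[, 1], c(0.25, 0.5, 0.25))

  bad <- structure(list(lik = matrix(c(0, 0, 0), 3, 1),
                        missing = FALSE), class = "gl_matrix")
  expect_error(impute_individual(bad, make_panel(H2)), "all zero")
  expect_error(impute_individual(make_gl(matrix(1, 3, 1)),
                                 make_panel(H2[0, , drop = FALSE])),
               "empty")
})

test_that("posteriors equal exact path enumeration on random tiny instances", {
  set.seed(101)
  for (r in 1:40) {
    inst <- random_tiny_instance()
    a <- impute_individual(inst$gl, inst$panel, inst$params)
    b <- brute_force_posteriors(inst$gl, inst$panel, inst$params)
    expect_lt(max(abs(a$gp - b$gp)), 1e-10)
    expect_lt(max(abs(a$q - b$q)), 1e-10)
  }
  expect_error(brute_force_posteriors(make_gl(matrix(1, 3, 10)),
                                      make_panel(matrix(0L, 4, 10))),
               "too large")
})

test_that("posteriors match an independent dense forward-backward at larger K", {
  set.seed(55)
  K <- 25; M <- 150
  H <- matrix(rbinom(K * M, 1, 0.3), K, M)
  lik <- matrix(runif(3 * M), 3, M)
  tau <- runif(M - 1, 0, 0.02)
  gl <- make_gl(lik, missing = seq_len(M) %in% sample(M, 30))
  params <- hmm_params(tau = tau, theta = 1e-3)
  imp <- impute_individual(gl, make_panel(H), params)
  likm <- lik
  likm <- sweep(likm, 2, colSums(likm), "/")
  likm[, gl$missing] <- 1 / 3
  qr <- ref_diploid_fb(H, likm, tau, 1e-3)
  expect_lt(max(abs(imp$q - qr)), 1e-10)
})

test_that("reduced-precision storage agrees across block layouts at scale", {
  set.seed(66)
  K <- 120; M <- 1500  # large enough for the float storage path
  H <- matrix(rbinom(K * M, 1, 0.3), K, M)
  lik <- matrix(runif(3 * M), 3, M)
  tau <- runif(M - 1, 0, 0.01)
  q1 <- paleoimpute:::ls_diploid_fb(H, lik, tau, 1e-3)
  q2 <- paleoimpute:::ls_diploid_fb(H, lik, tau, 1e-3,
                                    block_bytes = 4 * K * K * 50)
  expect_lt(max(abs(q1 - q2)), 1e-6)
  # and the double path agrees with itself under forced checkpointing
  K <- 15; M <- 200
  H <- matrix(rbinom(K * M, 1, 0.4), K, M)
  lik <- matrix(runif(3 * M), 3, M)
  tau <- runif(M - 1, 0, 0.05)
  q1 <- paleoimpute:::ls_diploid_fb(H, lik, tau, 0.01)
  q2 <- paleoimpute:::ls_diploid_fb(H, lik, tau, 0.01,
                                    block_bytes = 8 * K * K * 13)
  expect_lt(max(abs(q1 - q2)), 1e-12)
})

test_that("windowed imputation reproduces the unwindowed posterior", {
  set.seed(77)
  K <- 30; M <- 5000
  cfg <- sim_config(K = K, M = M, chrom_length = 5e6, seed = 19,
                    n_diverged = 0)
  p <- generate_panel(cfg)
  truth <- sample_study_individuals(p, 1, seed = 3)
  pile <- simulate_reads(truth, p$markers, cfg, coverage = 1)
  gl <- compute_gl(pile, cfg$eps)[[1]]
  params <- hmm_params(p)
  whole <- impute_individual(gl, p, params)
  windowed <- impute_individual(gl, p, params,
                                segment_size = 2000, overlap = 1000)
  expect_lt(mean(abs(whole$gp - windowed$gp)), 1e-3)
  expect_equal(colSums(windowed$gp), rep(1, M), tolerance = 1e-9)
  expect_equal(windowed$dosage,
               windowed$gp[2, ] + 2 * windowed$gp[3, ], tolerance = 0)
})

test_that("strengthening the likelihood at a site never lowers the truth posterior", {
  set.seed(88)
  K <- 10; M <- 40
  H <- matrix(rbinom(K * M, 1, 0.4), K, M)
  params <- hmm_params(tau = rep(0.02, M - 1), theta = 1e-3)
  target <- 20
  truth_g <- 1L
  post <- sapply(c(0, 1, 2, 4, 8), function(reads) {
    lik <- matrix(1, 3, M)
    # `reads` balanced ref/alt reads at the target site
    p_alt <- c(0.01, 0.5, 0.99)
    lik[, target] <- p_alt^reads * (1 - p_alt)^reads
    imp <- impute_individual(make_gl(lik), make_panel(H), params)
    imp$gp[truth_g + 1L, target]
  })
  expect_true(all(diff(post) >= -1e-12))
})

test_that("joint imputation reduces to the single-sample mode when it must", {
  set.seed(99)
  cfg <- sim_config(K = 20, M = 500, chrom_length = 5e5, seed = 41,
                    n_diverged = 0)
  p <- generate_panel(cfg)
  truth <- sample_study_individuals(p, 3, seed = 11)
  pile <- simulate_reads(truth, p$markers, cfg, coverage = 1)
  gls <- compute_gl(pile, cfg$eps)
  params <- hmm_params(p)
  single <- lapply(gls, impute_individual, panel = p, params = params)
  joint1 <- impute_joint(gls, p, params, iterations = 1)
  expect_equal(joint1, single)
  lone <- impute_joint(gls[1], p, params, iterations = 2)
  expect_equal(lone[[1]], single[[1]])
  expect_error(impute_joint(gls, p, params, iterations = 0), "iterations")
})

test_that("a duplicated individual with dense data helps the focal individual", {
  cfg <- sim_config(K = 20, M = 500, chrom_length = 5e5, seed = 43,
                    n_diverged = 0)
  p <- generate_panel(cfg)
  truth <- sample_study_individuals(p, 2, seed = 13)
  pile <- simulate_reads(truth, p$markers, cfg, coverage = 1)
  gls <- compute_gl(pile, cfg$eps)
  params <- hmm_params(p)
  # duplicate individual 1 with dense (8x) data
  dense <- simulate_reads(truth, p$markers, cfg, coverage = 8,
                          stage = "reads-dense")
  gl_dup <- compute_gl(dense, cfg$eps)[[1]]
  base <- impute_joint(gls, p, params, iterations = 2)
  with_dup <- impute_joint(c(gls, list(gl_dup)), p, params, iterations = 2)
  acc <- function(imp) mean(imp$best_gt == truth$genotypes[1, ])
  expect_gte(acc(with_dup[[1]]), acc(base[[1]]))
})
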
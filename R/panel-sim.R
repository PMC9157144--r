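#' Simulation configuration
#'
#' Bundles the parameters of the synthetic benchmark: panel size, marker count,
#' study-sample size, mosaic miscopy rates, recombination scale, sequencing
#' depth and the two ancient-DNA noise processes (base error and post-mortem
#' deamination).
#'
#' @param K number of panel haplotypes (must be even: haplotypes pair into
#'   panel individuals).
#' @param M number of biallelic markers on the single synthetic chromosome.
#' @param N number of study individuals.
#' @param theta_sim per-site miscopy (mutation) probability used when a panel
#'   haplotype copies an earlier one. Controls panel diversity.
#' @param rho_scale expected recombination intensity per base pair; the
#'   intensity of inter-marker interval `m` is `rho_scale * (pos[m+1]-pos[m])`.
#' @param coverage target mean sequencing depth C (x).
#' @param eps per-read base error probability (symmetric ref/alt flip).
#' @param delta per-read deamination probability: a read whose carried
#'   nucleotide is C is observed as T with probability `delta` (independently
#'   G is observed as A), emulating post-mortem cytosine deamination on both
#'   strands.
#' @param transition_fraction fraction of markers assigned a C/T or G/A
#'   (transition) allele pair; human SNP sets are transition-enriched.
#' @param chrom_length chromosome length in bp over which marker positions are
#'   placed.
#' @param n_diverged number of panel haplotypes assigned to a mildly diverged
#'   subpopulation (labelled `"diverged"`; the rest are `"main"`).
#' @param divergence extra per-site allele-flip probability applied to the
#'   diverged haplotypes.
#' @param seed integer root RNG seed; all stage streams derive from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(K = 200L, M = 20000L, N = 5L,
                       theta_sim = 0.02, rho_scale = 5e-7,
                       coverage = 30, eps = 0.01, delta = 0.02,
                       transition_fraction = 2 / 3,
                       chrom_length = 2e7,
                       n_diverged = round(K / 10), divergence = 0.02,
                       seed = 1L) {
  cfg <- list(K = as.integer(K), M = as.integer(M), N = as.integer(N),
              theta_sim = theta_sim, rho_scale = rho_scale,
              coverage = coverage, eps = eps, delta = delta,
              transition_fraction = transition_fraction,
              chrom_length = chrom_length,
              n_diverged = as.integer(n_diverged), divergence = divergence,
              seed = as.integer(seed))
  probs <- c(theta_sim = theta_sim, eps = eps, delta = delta,
             transition_fraction = transition_fraction,
             divergence = divergence)
  if (any(probs < 0 | probs > 1)) {
    stop("probability parameters must lie in [0, 1]")
  }
  if (cfg$K < 2L || cfg$K %% 2L != 0L) {
    stop("K must be an even number >= 2 (panel haplotypes pair into individuals)")
  }
  if (cfg$M < 2L) stop("M must be >= 2")
  if (cfg$coverage <= 0) stop("coverage must be > 0")
  if (cfg$rho_scale < 0) stop("rho_scale must be >= 0")
  if (cfg$n_diverged < 0L || cfg$n_diverged >= cfg$K) {
    stop("n_diverged must be in [0, K)")
  }
  class(cfg) <- "sim_config"
  cfg
}

transition_pairs <- matrix(c("C", "T", "T", "C", "G", "A", "A", "G"),
                           ncol = 2, byrow = TRUE)
transversion_pairs <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                               "G", "T", "T", "G", "G", "C", "C", "G"),
                             ncol = 2, byrow = TRUE)

# One recombination/miscopy mosaic of the rows of `H` (templates x markers).
# Template switches between adjacent markers with probability tau_m, and each
# copied allele is flipped with probability theta. Returns the haplotype and
# the per-site template row used (the copying path).
mosaic_of <- function(H, tau, theta) {
  M <- ncol(H)
  k <- nrow(H)
  if (k == 1L) {
    tpl <- rep(1L, M)
  } else {
    sw <- stats::runif(M - 1L) < tau
    seg <- cumsum(c(1L, sw))
    tpl <- sample.int(k, seg[M], replace = TRUE)[seg]
  }
  src <- H[cbind(tpl, seq_len(M))]
  hap <- src
  if (theta > 0) {
    flip <- stats::rbinom(M, 1L, theta) == 1L
    hap[flip] <- 1L - hap[flip]
  }
  list(hap = hap, template = tpl, source = src)
}

#' Generate a phased synthetic reference panel
#'
#' Builds a panel of `K` phased haplotypes over `M` biallelic markers with a
#' product-of-approximate-conditionals (PAC) style sequential generator:
#' haplotype 1 is drawn per site from a Beta(0.2, 2) site-frequency prior
#' (skewed toward rare alleles); every later haplotype is a recombining mosaic
#' of the haplotypes generated before it, switching template between adjacent
#' markers with probability `1 - exp(-rho_m)` and flipping the copied allele
#' with probability `theta_sim`. Each marker receives a ref/alt nucleotide
#' pair, transition-type (C/T or G/A, strand randomised) with probability
#' `transition_fraction`. The last `n_diverged` haplotypes receive additional
#' independent allele flips at rate `divergence` and are labelled as a diverged
#' subpopulation, usable for reference-panel subsetting experiments.
#'
#' @param config a [sim_config()] object.
#' @return A `haplotype_panel`: list with `markers` (data.frame: chrom, pos,
#'   ref, alt, maf), `haplotypes` (K x M 0/1 integer matrix, 0 = ref allele),
#'   `interval_rho` (length M-1), `pop_labels` (length K).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "panel"))
  K <- config$K
  M <- config$M

  pos <- sort(sample.int(config$chrom_length, M))
  interval_rho <- config$rho_scale * diff(pos)
  tau <- 1 - exp(-interval_rho)

  freq <- stats::rbeta(M, 0.2, 2)
  H <- matrix(0L, nrow = K, ncol = M)
  H[1L, ] <- stats::rbinom(M, 1L, freq)
  for (k in seq_len(K)[-1L]) {
    H[k, ] <- mosaic_of(H[seq_len(k - 1L), , drop = FALSE],
                        tau, config$theta_sim)$hap
  }

  pop_labels <- rep("main", K)
  if (config$n_diverged > 0L && config$divergence > 0) {
    idx <- seq.int(K - config$n_diverged + 1L, K)
    for (k in idx) {
      flip <- stats::rbinom(M, 1L, config$divergence) == 1L
      H[k, flip] <- 1L - H[k, flip]
    }
    pop_labels[idx] <- "diverged"
  } else if (config$n_diverged > 0L) {
    pop_labels[seq.int(K - config$n_diverged + 1L, K)] <- "diverged"
  }

  is_ts <- stats::runif(M) < config$transition_fraction
  alle <- matrix("", nrow = M, ncol = 2)
  n_ts <- sum(is_ts)
  if (n_ts > 0) {
    alle[is_ts, ] <- transition_pairs[sample.int(4L, n_ts, replace = TRUE), ,
                                      drop = FALSE]
  }
  if (n_ts < M) {
    alle[!is_ts, ] <- transversion_pairs[sample.int(8L, M - n_ts,
                                                    replace = TRUE), ,
                                         drop = FALSE]
  }

  f1 <- colMeans(H)
  markers <- data.frame(chrom = "1", pos = pos,
                        ref = alle[, 1], alt = alle[, 2],
                        maf = pmin(f1, 1 - f1),
                        stringsAsFactors = FALSE)
  structure(list(markers = markers, haplotypes = H,
                 interval_rho = interval_rho, pop_labels = pop_labels),
            class = "haplotype_panel")
}

#' Restrict a panel to the haplotypes of one population label
#'
#' Marker metadata (including the panel allele frequency used for MAF
#' stratification, which is always estimated from the full panel) is retained.
#'
#' @param panel a `haplotype_panel`.
#' @param pop population label to keep.
#' @return A `haplotype_panel` containing only the matching haplotypes.
#' @export
subset_panel <- function(panel, pop) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- panel$pop_labels == pop
  if (!any(keep)) stop("no haplotypes with population label '", pop, "'")
  structure(list(markers = panel$markers,
                 haplotypes = panel$haplotypes[keep, , drop = FALSE],
                 interval_rho = panel$interval_rho,
                 pop_labels = panel$pop_labels[keep]),
            class = "haplotype_panel")
}

#' Sample diploid study individuals as mosaics of the panel
#'
#' Each study haplotype is a recombination/miscopy mosaic of the panel
#' haplotypes (same switch process as the panel generator, allele flip
#' probability `theta_sim`). With `divergence_rate > 0`, additional
#' independent allele flips at that rate emulate a study individual whose
#' variation is not represented in the reference (the hunter-gatherer
#' analogue). Genotypes are the sums of the two haplotypes.
#'
#' @param panel a `haplotype_panel`.
#' @param n number of diploid individuals to sample.
#' @param theta_sim per-allele miscopy probability of the mosaic process.
#' @param divergence_rate per-site private-mutation probability in `[0, 1]`.
#' @param seed integer seed for this stage.
#' @return A `study_truth`: list with `haplotypes` (2N x M), `genotypes`
#'   (N x M dosages in 0..2), `divergence_rate`, and attribute
#'   `source_alleles` (the pre-flip copied alleles, for copying-path audits).
#' @export
sample_study_individuals <- function(panel, n, theta_sim = 0.001,
                                     divergence_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n < 1L) stop("n must be >= 1")
  if (divergence_rate < 0 || divergence_rate > 1) {
    stop("divergence_rate must lie in [0, 1]")
  }
  set.seed(child_seed(seed, "study"))
  M <- ncol(panel$haplotypes)
  tau <- 1 - exp(-panel$interval_rho)
  hap <- matrix(0L, nrow = 2L * n, ncol = M)
  src <- matrix(0L, nrow = 2L * n, ncol = M)
  for (i in seq_len(2L * n)) {
    mz <- mosaic_of(panel$haplotypes, tau, theta_sim)
    h <- mz$hap
    if (divergence_rate > 0) {
      flip <- stats::rbinom(M, 1L, divergence_rate) == 1L
      h[flip] <- 1L - h[flip]
    }
    hap[i, ] <- h
    src[i, ] <- mz$source
  }
  gt <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  structure(list(haplotypes = hap, genotypes = gt,
                 divergence_rate = divergence_rate),
            source_alleles = src, class = "study_truth")
}
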
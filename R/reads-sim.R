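#' Simulate ancient-DNA-like read pileups
#'
#' Per site and individual, read depth is Poisson with mean `coverage`. Each
#' read carries one of the individual's two true alleles (fair coin), a base
#' error flips ref and alt with probability `eps`, and deamination then acts
#' at the nucleotide level: a read whose carried nucleotide is C is observed
#' as T with probability `delta` (independently G is observed as A). The
#' observed nucleotide is counted toward whichever allele it matches; a
#' deaminated base matching neither allele (possible only at transversion
#' sites) is discarded. Counts are sampled directly from the per-read
#' multinomial this model implies, which is distributionally identical to
#' simulating individual reads.
#'
#' @param truth a `study_truth`.
#' @param markers marker data.frame with `ref`/`alt` nucleotide columns
#'   (typically `panel$markers`).
#' @param config a [sim_config()]; uses `coverage`, `eps`, `delta`, `seed`.
#' @param coverage optional override of `config$coverage`; a scalar, or one
#'   value per individual (mixed-coverage cohorts).
#' @param stage RNG stage label (distinct labels give independent pileups).
#' @return A `pileup_columns`: list with integer matrices `n_ref`, `n_alt`
#'   (individuals x markers) and `realized_coverage` (mean depth per
#'   individual).
#' @export
simulate_reads <- function(truth, markers, config, coverage = config$coverage,
                           stage = "reads") {
  stopifnot(inherits(truth, "study_truth"))
  M <- ncol(truth$genotypes)
  if (nrow(markers) != M) {
    stop("marker list length does not match truth matrix")
  }
  if (any(coverage <= 0)) stop("coverage must be > 0")
  coverage <- rep_len(coverage, nrow(truth$genotypes))
  set.seed(child_seed(config$seed, stage))

  eps <- config$eps
  delta <- config$delta
  ref <- markers$ref
  alt <- markers$alt
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T"))) {
    stop("unknown nucleotide codes in ref/alt alleles")
  }
  deam_product <- function(b) ifelse(b == "C", "T", ifelse(b == "G", "A", NA))
  # per-read probabilities of the deamination outcome for each carried allele
  pr_ref <- deam_product(ref)
  pr_alt <- deam_product(alt)
  ref_deam <- ref %in% c("C", "G")
  alt_deam <- alt %in% c("C", "G")
  ref_to_alt <- ifelse(ref_deam & !is.na(pr_ref) & pr_ref == alt, delta, 0)
  ref_to_drop <- ifelse(ref_deam, delta, 0) - ref_to_alt
  alt_to_ref <- ifelse(alt_deam & !is.na(pr_alt) & pr_alt == ref, delta, 0)
  alt_to_drop <- ifelse(alt_deam, delta, 0) - alt_to_ref

  n_ind <- nrow(truth$genotypes)
  n_ref <- matrix(0L, n_ind, M)
  n_alt <- matrix(0L, n_ind, M)
  for (i in seq_len(n_ind)) {
    g <- truth$genotypes[i, ]
    q <- (g / 2) * (1 - eps) + (1 - g / 2) * eps   # P(read carries alt allele)
    p_alt <- q * (1 - alt_to_ref - alt_to_drop) + (1 - q) * ref_to_alt
    p_ref <- (1 - q) * (1 - ref_to_alt - ref_to_drop) + q * alt_to_ref
    p_drop <- pmax(0, 1 - p_alt - p_ref)
    depth <- stats::rpois(M, coverage[i])
    kept <- stats::rbinom(M, depth, 1 - p_drop)
    denom <- p_alt + p_ref
    prob_alt <- ifelse(denom > 0, p_alt / denom, 0)
    a <- stats::rbinom(M, kept, prob_alt)
    n_alt[i, ] <- a
    n_ref[i, ] <- kept - a
  }
  new_pileup(n_ref, n_alt)
}

new_pileup <- function(n_ref, n_alt) {
  structure(list(n_ref = n_ref, n_alt = n_alt,
                 realized_coverage = rowMeans(n_ref + n_alt)),
            class = "pileup_columns")
}

#' Total read depth per site and individual
#' @param pileups a `pileup_columns`.
#' @return Integer matrix of per-site depths.
#' @export
pileup_depth <- function(pileups) pileups$n_ref + pileups$n_alt

#' Downsample pileups to a lower target coverage
#'
#' Each read is retained independently with probability
#' `target_coverage / realized_coverage` (binomial thinning of the ref and
#' alt counts), mirroring read-level downsampling of alignments.
#'
#' @param pileups a `pileup_columns`.
#' @param target_coverage desired mean depth; must not exceed the realized
#'   coverage of any individual.
#' @param seed integer seed for this stage.
#' @return A thinned `pileup_columns` (retained counts never exceed the
#'   originals sitewise).
#' @export
downsample <- function(pileups, target_coverage, seed = 1L) {
  stopifnot(inherits(pileups, "pileup_columns"))
  if (any(target_coverage > pileups$realized_coverage)) {
    stop("target coverage exceeds realized coverage")
  }
  if (target_coverage < 0) stop("target coverage must be >= 0")
  set.seed(child_seed(seed, "downsample"))
  n_ind <- nrow(pileups$n_ref)
  M <- ncol(pileups$n_ref)
  n_ref <- matrix(0L, n_ind, M)
  n_alt <- matrix(0L, n_ind, M)
  for (i in seq_len(n_ind)) {
    rate <- target_coverage / pileups$realized_coverage[i]
    n_ref[i, ] <- stats::rbinom(M, pileups$n_ref[i, ], rate)
    n_alt[i, ] <- stats::rbinom(M, pileups$n_alt[i, ], rate)
  }
  new_pileup(n_ref, n_alt)
}
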
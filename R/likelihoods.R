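#' Genotype likelihoods from read counts
#'
#' For alt-allele dosage g in {0, 1, 2} and a site with `r` ref and `a` alt
#' reads, the biallelic sampling-with-error model gives
#' `L(g) = p(g)^a * (1 - p(g))^r` with `p(g) = (g/2)(1-eps) + (1-g/2) eps`,
#' i.e. each read is an independent draw of one of the two true alleles
#' followed by a symmetric error flip. Likelihood triples are normalised to
#' sum to one; zero-depth sites are flagged missing and carry the uniform
#' triple.
#'
#' @param pileup a `pileup_columns`.
#' @param eps base error probability in (0, 0.5).
#' @return A list with one `gl_matrix` per individual: `lik` (3 x M matrix,
#'   rows g = 0, 1, 2) and `missing` (logical, depth-0 sites).
#' @export
compute_gl <- function(pileup, eps) {
  stopifnot(inherits(pileup, "pileup_columns"))
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  if (any(pileup$n_ref < 0) || any(pileup$n_alt < 0)) {
    stop("negative read counts")
  }
  lapply(seq_len(nrow(pileup$n_ref)), function(i) {
    gl_from_counts(pileup$n_ref[i, ], pileup$n_alt[i, ], eps)
  })
}

gl_from_counts <- function(n_ref, n_alt, eps) {
  p_alt <- c(eps, 0.5, 1 - eps)
  # log-space product over reads, then normalised back to linear scale
  loglik <- outer(log(p_alt), n_alt) + outer(log(1 - p_alt), n_ref)
  loglik <- sweep(loglik, 2L, apply(loglik, 2L, max))
  lik <- exp(loglik)
  lik <- sweep(lik, 2L, colSums(lik), "/")
  miss <- (n_ref + n_alt) == 0L
  lik[, miss] <- 1 / 3
  structure(list(lik = lik, missing = miss), class = "gl_matrix")
}

#' Call high-quality gold-standard genotypes from high-coverage pileups
#'
#' Genotypes are the flat-prior posterior mode of [compute_gl()] likelihoods;
#' call confidence is Phred-scaled, `QUAL = -10 log10(1 - posterior)`, capped
#' at 99. A site passes for an individual when depth is at least `min_dp`,
#' QUAL at least `min_qual`, and (for heterozygous calls) both alleles have
#' allele depth of at least `het_ad_frac` of the total depth.
#'
#' @param high_cov_pileups a `pileup_columns` from a high-coverage simulation
#'   (the gold-standard source, typically 30x).
#' @param eps base error probability used for the likelihood model.
#' @param min_dp minimum read depth.
#' @param min_qual minimum Phred-scaled call confidence.
#' @param het_ad_frac minimum minor allele-depth fraction for heterozygotes.
#' @return A `truth_calls`: list of matrices (individuals x markers) `gt`
#'   (called dosage, NA where failing), `dp`, `qual`, `pass`.
#' @export
call_hq_truth <- function(high_cov_pileups, eps, min_dp = 15, min_qual = 50,
                          het_ad_frac = 0.25) {
  gls <- compute_gl(high_cov_pileups, eps)
  dp <- pileup_depth(high_cov_pileups)
  n_ind <- nrow(dp)
  M <- ncol(dp)
  gt <- matrix(NA_integer_, n_ind, M)
  qual <- matrix(0, n_ind, M)
  pass <- matrix(FALSE, n_ind, M)
  for (i in seq_len(n_ind)) {
    post <- gls[[i]]$lik
    g <- max.col(t(post), ties.method = "first") - 1L
    pmax_ <- post[cbind(g + 1L, seq_len(M))]
    q <- -10 * log10(pmax(1 - pmax_, 1e-10))
    q <- pmin(q, 99)
    ad_min <- pmin(high_cov_pileups$n_ref[i, ], high_cov_pileups$n_alt[i, ])
    ok <- dp[i, ] >= min_dp & q >= min_qual &
      (g != 1L | ad_min >= het_ad_frac * dp[i, ])
    gt[i, ok] <- g[ok]
    qual[i, ] <- q
    pass[i, ] <- ok
  }
  structure(list(gt = gt, dp = dp, qual = qual, pass = pass),
            class = "truth_calls")
}

#' Deamination-aware site exclusion
#'
#' Post-mortem deamination is read as C-to-T (and complementary G-to-A)
#' substitutions, so at transition SNPs an apparent damage-product allele is
#' unreliable. A site is dropped for an individual iff the ref/alt pair is
#' {C,T} and the individual's most likely genotype contains the T allele, or
#' the pair is {G,A} and it contains the A allele. Ties in the most likely
#' genotype are treated conservatively: a site is kept only if no tied
#' genotype contains the damage-product allele. Missing (zero-depth) sites
#' are kept. Transversion sites are never dropped.
#'
#' @param markers marker data.frame with `ref`/`alt` columns.
#' @param gl a single `gl_matrix` or a list of them (one per individual).
#' @return A logical kept-site mask per individual (vector, or a list of
#'   vectors when `gl` is a list).
#' @export
deamination_site_filter <- function(markers, gl) {
  if (inherits(gl, "gl_matrix")) {
    return(deamination_mask_one(markers, gl))
  }
  lapply(gl, function(g) deamination_mask_one(markers, g))
}

deamination_mask_one <- function(markers, gl) {
  stopifnot(inherits(gl, "gl_matrix"))
  ref <- markers$ref
  alt <- markers$alt
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T"))) {
    stop("unknown nucleotide codes in ref/alt alleles")
  }
  ct <- (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ga <- (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
  product_is_alt <- (ct & alt == "T") | (ga & alt == "A")
  product_is_ref <- (ct & ref == "T") | (ga & ref == "A")

  lik <- gl$lik
  mx <- pmax(lik[1L, ], lik[2L, ], lik[3L, ])
  tol <- mx * 1e-12
  tied <- sweep(lik, 2L, mx - tol) >= 0   # genotypes tied for the maximum
  # genotype contains the damage product: alt in {1,2} when product==alt,
  # ref in {0,1} when product==ref
  has_product <- (tied[2L, ] | tied[3L, ]) & product_is_alt |
    (tied[1L, ] | tied[2L, ]) & product_is_ref
  kept <- !((ct | ga) & has_product)
  kept[gl$missing] <- TRUE
  kept
}

#' Apply a kept-site mask to genotype likelihoods
#'
#' Dropped sites re-enter imputation as missing data (uniform likelihood
#' triple), so they are imputed purely from flanking haplotype structure.
#'
#' @param gl a single `gl_matrix` or list of them.
#' @param kept logical mask (or list of masks) as returned by
#'   [deamination_site_filter()].
#' @return The filtered `gl_matrix` (or list).
#' @export
apply_site_mask <- function(gl, kept) {
  if (inherits(gl, "gl_matrix")) {
    gl$lik[, !kept] <- 1 / 3
    gl$missing <- gl$missing | !kept
    return(gl)
  }
  Map(apply_site_mask, gl, kept)
}
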
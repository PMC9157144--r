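#' Assign sites to equal-width MAF bins over (0, 0.5]
#'
#' Bin edges are left-open; sites with panel MAF exactly 0 are uninformative
#' for frequency-stratified curves and get `NA`.
#'
#' @param maf numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param bins number of equal-width bins.
#' @return Integer bin index in `1..bins`, `NA` for MAF 0.
#' @export
maf_bin <- function(maf, bins = 50L) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("maf must lie in [0, 0.5]")
  }
  idx <- ceiling(maf * bins / 0.5)
  idx[maf == 0] <- NA_integer_
  pmin(as.integer(idx), bins)
}

#' Edge table for equal-width MAF bins over (0, 0.5]
#' @param bins number of bins.
#' @return Data frame with `bin`, `maf_lo`, `maf_hi`.
#' @export
maf_bin_edges <- function(bins = 50L) {
  data.frame(bin = seq_len(bins),
             maf_lo = (seq_len(bins) - 1L) * 0.5 / bins,
             maf_hi = seq_len(bins) * 0.5 / bins)
}

#' Split evaluable sites by read overlap
#'
#' Metrics are computed only where a passing gold-standard call exists
#' (`has_truth`); those sites are partitioned into "overlapping" (at least one
#' read in the downsampled pileup) and "nonoverlapping" (imputed purely from
#' haplotype context).
#'
#' @param downsampled the downsampled `pileup_columns` used as imputation
#'   input.
#' @param truth a `truth_calls` on the same marker grid.
#' @return An `eval_mask`: logical matrices `has_truth` and `overlapping`
#'   (individuals x markers).
#' @export
split_overlap <- function(downsampled, truth) {
  stopifnot(inherits(downsampled, "pileup_columns"),
            inherits(truth, "truth_calls"))
  dp <- pileup_depth(downsampled)
  if (!identical(dim(dp), dim(truth$gt))) {
    stop("pileup and truth marker grids do not match")
  }
  structure(list(has_truth = truth$pass, overlapping = dp >= 1L),
            class = "eval_mask")
}

strat_index <- function(mask, i) {
  ht <- mask$has_truth[i, ]
  list(all = ht,
       overlapping = ht & mask$overlapping[i, ],
       nonoverlapping = ht & !mask$overlapping[i, ])
}

#' Genotype concordance, stratified by overlap status and genotype class
#'
#' The fraction of evaluable sites whose imputed best-guess genotype equals
#' the gold-standard call, per individual, split by overlap stratum and by
#' the gold-standard genotype class (hom-ref / het / hom-alt). Strata with no
#' evaluable sites are reported as `NA`, not 0.
#'
#' @param imputed list of `imputed_genotypes` (one per individual).
#' @param truth a `truth_calls`.
#' @param mask an `eval_mask` from [split_overlap()].
#' @return A data.frame with columns `individual`, `stratum`, `class`, `n`,
#'   `concordance`.
#' @export
concordance <- function(imputed, truth, mask) {
  stopifnot(inherits(mask, "eval_mask"))
  classes <- c(all = -1L, hom_ref = 0L, het = 1L, hom_alt = 2L)
  out <- list()
  for (i in seq_along(imputed)) {
    match_ <- imputed[[i]]$best_gt == truth$gt[i, ]
    strata <- strat_index(mask, i)
    for (s in names(strata)) {
      for (cl in names(classes)) {
        sel <- strata[[s]]
        if (classes[[cl]] >= 0L) {
          sel <- sel & !is.na(truth$gt[i, ]) & truth$gt[i, ] == classes[[cl]]
        }
        n <- sum(sel, na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          individual = i, stratum = s, class = cl, n = n,
          concordance = if (n > 0) mean(match_[sel], na.rm = TRUE) else NA_real_)
      }
    }
  }
  do.call(rbind, out)
}

#' Heterozygote discordance binned by panel MAF
#'
#' Over sites where the gold-standard genotype is heterozygous, the fraction
#' imputed as anything else, pooled over individuals, in `bins` equal-width
#' MAF bins and separately per overlap stratum. When `kept` masks from a GP
#' filter are supplied, only retained sites enter the discordance and the
#' per-bin retained fraction is reported.
#'
#' @param imputed list of `imputed_genotypes`.
#' @param truth a `truth_calls`.
#' @param maf per-site minor allele frequency from the designated frequency
#'   panel.
#' @param bins number of MAF bins.
#' @param mask an `eval_mask`.
#' @param kept optional list of logical retained-site masks (see
#'   [gp_filter()]).
#' @param smooth apply a 3-point moving average to the per-bin discordance.
#' @return A data.frame with `bin`, `maf_lo`, `maf_hi`, `stratum`, `n`,
#'   `discordance`, `retained` (NA when no filter); empty bins carry NA.
#' @export
het_discordance_by_maf <- function(imputed, truth, maf, bins = 50L, mask,
                                   kept = NULL, smooth = FALSE) {
  bin <- maf_bin(maf, bins)
  edges <- maf_bin_edges(bins)
  out <- list()
  for (s in c("all", "overlapping", "nonoverlapping")) {
    num <- den <- tot <- numeric(bins)
    for (i in seq_along(imputed)) {
      sel <- strat_index(mask, i)[[s]] & !is.na(truth$gt[i, ]) &
        truth$gt[i, ] == 1L & !is.na(bin)
      keep_i <- if (is.null(kept)) rep(TRUE, length(sel)) else kept[[i]]
      disc <- imputed[[i]]$best_gt != truth$gt[i, ]
      tot <- tot + tabulate(bin[sel], bins)
      den <- den + tabulate(bin[sel & keep_i], bins)
      num <- num + tabulate(bin[sel & keep_i & disc], bins)
    }
    d <- ifelse(den > 0, num / den, NA_real_)
    if (smooth) d <- smooth3(d)
    out[[s]] <- data.frame(edges, stratum = s, n = den, discordance = d,
                           retained = if (is.null(kept)) NA_real_ else
                             ifelse(tot > 0, den / tot, NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 3-point moving average, NA-tolerant at the ends
smooth3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - 1L):min(n, i + 1L)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Modal genotypes of the reference panel
#'
#' Panel individuals are consecutive haplotype pairs; the modal genotype per
#' site is the most frequent diploid genotype among them, ties broken toward
#' the lower alt dosage.
#'
#' @param panel a `haplotype_panel`.
#' @return Integer vector of modal dosages (0/1/2) per marker.
#' @export
modal_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$haplotypes
  if (nrow(H) < 2L) stop("panel has no individuals")
  G <- H[seq(1L, nrow(H), 2L), , drop = FALSE] +
    H[seq(2L, nrow(H), 2L), , drop = FALSE]
  counts <- rbind(colSums(G == 0L), colSums(G == 1L), colSums(G == 2L))
  max.col(t(counts), ties.method = "first") - 1L
}

#' Reference affinity of a genotype vector
#'
#' The fraction of (non-missing) sites whose genotype equals the most
#' frequent genotype among the reference-panel individuals; systematic
#' differences between gold-standard and imputed affinities quantify
#' reference bias.
#'
#' @param gts integer dosage vector (NA = unobserved).
#' @param panel a `haplotype_panel`.
#' @param modal optional precomputed [modal_genotypes()] vector.
#' @return Fraction in `[0, 1]`.
#' @export
reference_affinity <- function(gts, panel, modal = modal_genotypes(panel)) {
  ok <- !is.na(gts)
  if (!any(ok)) return(NA_real_)
  mean(gts[ok] == modal[ok])
}

#' Reference-affinity difference across the allele-frequency spectrum
#'
#' Per MAF bin, `affinity(truth) - affinity(imputed)` averaged over
#' individuals; negative values indicate that imputation has made the sample
#' more reference-like than its gold standard (reference bias).
#'
#' @param truth_gts,imputed_gts individuals x markers dosage matrices on the
#'   same evaluable sites (NA = not evaluable).
#' @param panel a `haplotype_panel`.
#' @param maf per-site MAF for binning.
#' @param bins number of MAF bins.
#' @return A data.frame with `bin`, `maf_lo`, `maf_hi`, `n`,
#'   `affinity_difference`.
#' @export
affinity_difference_curve <- function(truth_gts, imputed_gts, panel, maf,
                                      bins = 50L) {
  stopifnot(identical(dim(truth_gts), dim(imputed_gts)))
  modal <- modal_genotypes(panel)
  bin <- maf_bin(maf, bins)
  edges <- maf_bin_edges(bins)
  n_ind <- nrow(truth_gts)
  diffs <- matrix(NA_real_, n_ind, bins)
  for (i in seq_len(n_ind)) {
    ok <- !is.na(truth_gts[i, ]) & !is.na(imputed_gts[i, ]) & !is.na(bin)
    at <- tapply(truth_gts[i, ok] == modal[ok], bin[ok], mean)
    ai <- tapply(imputed_gts[i, ok] == modal[ok], bin[ok], mean)
    idx <- as.integer(names(at))
    diffs[i, idx] <- at - ai
  }
  data.frame(edges,
             n = colSums(!is.na(diffs)),
             affinity_difference = colMeans(diffs, na.rm = TRUE))
}

#' Filter imputed genotypes on posterior probability
#'
#' Sites whose maximum posterior genotype probability falls below `min_gp`
#' are removed; the retained fraction is reported overall per individual and
#' per MAF bin (mean, min and max over individuals) when `maf` is given.
#'
#' @param imputed list of `imputed_genotypes`.
#' @param min_gp minimum posterior genotype probability, in `(0, 1]`.
#' @param maf optional per-site MAF for the binned retention curve.
#' @param bins number of MAF bins.
#' @return A list with `kept` (list of logical masks), `retained`
#'   (data.frame individual/retained), and `by_bin` (when `maf` given).
#' @export
gp_filter <- function(imputed, min_gp = 0.99, maf = NULL, bins = 50L) {
  if (min_gp <= 0 || min_gp > 1) stop("min_gp must lie in (0, 1]")
  if (inherits(imputed, "imputed_genotypes")) imputed <- list(imputed)
  kept <- lapply(imputed, function(x) x$max_gp >= min_gp)
  retained <- data.frame(individual = seq_along(kept),
                         retained = vapply(kept, mean, numeric(1)))
  by_bin <- NULL
  if (!is.null(maf)) {
    bin <- maf_bin(maf, bins)
    frac <- t(vapply(kept, function(k) {
      tab <- tabulate(bin, bins)
      keep_tab <- tabulate(bin[k], bins)
      ifelse(tab > 0, keep_tab / tab, NA_real_)
    }, numeric(bins)))
    by_bin <- data.frame(maf_bin_edges(bins),
                         mean = colMeans(frac, na.rm = TRUE),
                         min = suppressWarnings(apply(frac, 2, min, na.rm = TRUE)),
                         max = suppressWarnings(apply(frac, 2, max, na.rm = TRUE)))
    by_bin$min[!is.finite(by_bin$min)] <- NA_real_
    by_bin$max[!is.finite(by_bin$max)] <- NA_real_
  }
  list(kept = kept, retained = retained, by_bin = by_bin)
}
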
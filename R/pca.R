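#' Fit a reference PCA on a modern genotype panel
#'
#' Markers with reference-panel MAF below `maf_min` or missing call rate above
#' `max_missing` are removed; remaining entries are normalised with the
#' EIGENSTRAT convention, `(g - 2p) / sqrt(p (1 - p))` with `p` the allele
#' frequency estimated from non-missing reference genotypes, missing entries
#' set to 0 after centring. The top `d` components of the singular value
#' decomposition are retained; component signs are canonicalised (the
#' largest-magnitude loading is positive) for run-to-run reproducibility.
#'
#' @param ref_gts reference samples x markers dosage matrix (NA = missing).
#' @param maf_min minimum MAF for a marker to enter the model.
#' @param max_missing maximum missing call rate per marker.
#' @param d number of components.
#' @return A `pca_model`: marker index `markers`, frequencies `p`, normalised
#'   reference matrix `X`, `loadings`, reference `scores`, `d`.
#' @export
fit_reference_pca <- function(ref_gts, maf_min = 0.01, max_missing = 0.10,
                              d = 2L) {
  stopifnot(is.matrix(ref_gts))
  n <- nrow(ref_gts)
  if (n < d + 1L) stop("need at least d + 1 reference samples")
  p <- colMeans(ref_gts, na.rm = TRUE) / 2
  missfrac <- colMeans(is.na(ref_gts))
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(p) & maf >= maf_min & missfrac <= max_missing)
  if (length(keep) == 0L) stop("all markers removed by the PCA filters")

  pk <- p[keep]
  X <- sweep(ref_gts[, keep, drop = FALSE], 2L, 2 * pk)
  X[is.na(X)] <- 0
  X <- sweep(X, 2L, sqrt(pk * (1 - pk)), "/")

  sv <- svd(X, nu = d, nv = d)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
  for (j in seq_len(d)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(markers = keep, p = pk, X = X,
                 loadings = loadings, scores = scores, d = d),
            class = "pca_model")
}

# Moore-Penrose pseudoinverse via SVD (minimum-norm least squares)
pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, 0)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Project a sample with missing data onto a reference PCA (known data
#' regression)
#'
#' Restricting the model to the sample's observed sites, a minimum-norm
#' least-squares map is fitted from the reference samples' normalised
#' genotypes at those sites to their stored PCA scores; the sample's
#' coordinates are that map applied to its own normalised genotypes. With all
#' sites observed and an exact-fit regression this recovers reference
#' samples' stored scores.
#'
#' @param sample_gts full-length dosage vector (NA at unobserved sites).
#' @param model a `pca_model`.
#' @param label optional data label carried through (e.g. "HQ", "imputed").
#' @return A `projection_result`: `coords` (length `d`), `n_observed`,
#'   `label`.
#' @export
kdr_project <- function(sample_gts, model, label = NA_character_) {
  stopifnot(inherits(model, "pca_model"))
  obs <- which(!is.na(sample_gts[model$markers]))
  if (length(obs) == 0L) {
    stop("no observed sites overlap the PCA model markers")
  }
  B <- model$X[, obs, drop = FALSE]
  beta <- pinv(B) %*% model$scores
  x <- (sample_gts[model$markers][obs] - 2 * model$p[obs]) /
    sqrt(model$p[obs] * (1 - model$p[obs]))
  coords <- drop(crossprod(beta, x))
  if (any(!is.finite(coords))) stop("non-finite projection coordinates")
  structure(list(coords = coords, n_observed = length(obs), label = label),
            class = "projection_result")
}

#' Distances of imputed and low-coverage projections to the gold standard
#'
#' Euclidean distance in the first two principal components between each
#' sample's imputed (and low-coverage) projection and its gold-standard
#' projection.
#'
#' @param hq,imputed,lowcov lists of `projection_result` over the same
#'   samples, in the same order.
#' @return A data.frame with `sample`, `d_imputed`, `d_lowcov`.
#' @export
compare_distances <- function(hq, imputed, lowcov) {
  if (length(hq) != length(imputed) || length(hq) != length(lowcov)) {
    stop("projection sets cover different samples")
  }
  d2 <- function(a, b) sqrt(sum((a$coords[1:2] - b$coords[1:2])^2))
  data.frame(sample = seq_along(hq),
             d_imputed = mapply(d2, imputed, hq),
             d_lowcov = mapply(d2, lowcov, hq))
}
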
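#' Haplotype-copying HMM parameters
#'
#' The hidden state is an ordered pair of panel haplotypes. Between adjacent
#' markers each copied haplotype stays on its template with probability
#' `(1 - tau_m) + tau_m / K` and moves to any specific other template with
#' probability `tau_m / K`, with `tau_m = 1 - exp(-rho_m)` taken from the
#' panel's inter-marker recombination intensities. Each copied allele is
#' mis-copied (flipped) with probability `theta`.
#'
#' @param panel a `haplotype_panel` supplying `interval_rho`.
#' @param theta miscopy probability per copied allele, in `[0, 0.5)`.
#' @param tau optional explicit switch-probability vector (length M-1),
#'   overriding the panel-derived one.
#' @return An `hmm_params` list with `tau` and `theta`.
#' @export
hmm_params <- function(panel = NULL, theta = 1e-3, tau = NULL) {
  if (is.null(tau)) {
    stopifnot(inherits(panel, "haplotype_panel"))
    tau <- 1 - exp(-panel$interval_rho)
  }
  if (any(tau < 0 | tau >= 1)) stop("tau must lie in [0, 1)")
  if (theta < 0 || theta >= 0.5) stop("theta must lie in [0, 0.5)")
  structure(list(tau = tau, theta = theta), class = "hmm_params")
}

#' Plan overlapping imputation windows over a marker grid
#'
#' Long marker sets are imputed in overlapping segments; consecutive windows
#' advance by `segment_size - overlap` markers and the final window is
#' truncated at `m`. Results are stitched by assigning each marker to the
#' window whose midpoint is nearest (ties to the earlier window).
#'
#' @param m total marker count.
#' @param segment_size markers per window.
#' @param overlap markers shared by consecutive windows; must be smaller than
#'   `segment_size`.
#' @return A `window_plan`: data.frame with `start`, `end` (1-based,
#'   inclusive) and attribute `source` (integer vector, the stitching window
#'   index per marker).
#' @export
plan_windows <- function(m, segment_size = 50000L, overlap = 25000L) {
  if (overlap < 0 || overlap >= segment_size) {
    stop("overlap must satisfy 0 <= overlap < segment_size")
  }
  if (m < 1) stop("m must be >= 1")
  step <- segment_size - overlap
  start <- 1L
  wins <- list()
  repeat {
    end <- min(start + segment_size - 1L, m)
    wins[[length(wins) + 1L]] <- c(start, end)
    if (end >= m) break
    start <- start + step
  }
  plan <- as.data.frame(do.call(rbind, wins))
  names(plan) <- c("start", "end")
  mid <- (plan$start + plan$end) / 2
  d <- abs(outer(seq_len(m), mid, "-"))
  attr(plan, "source") <- max.col(-d, ties.method = "first")
  class(plan) <- c("window_plan", "data.frame")
  plan
}

# 3 x M likelihood matrix for the HMM (missing columns become constant)
gl_to_matrix <- function(gl) {
  stopifnot(inherits(gl, "gl_matrix"))
  lik <- gl$lik
  bad <- colSums(lik) == 0 & !gl$missing
  if (any(bad)) stop("GL triple all zero at site ", which(bad)[1])
  lik[, gl$missing] <- 1
  lik
}

new_imputed <- function(q) {
  gp <- rbind(q[1L, ], q[2L, ] + q[3L, ], q[4L, ])
  best <- max.col(t(gp), ties.method = "first") - 1L
  structure(list(gp = gp, q = q,
                 dosage = gp[2L, ] + 2 * gp[3L, ],
                 best_gt = best,
                 max_gp = gp[cbind(best + 1L, seq_len(ncol(gp)))]),
            class = "imputed_genotypes")
}

#' Impute one individual against a phased panel
#'
#' Runs the diploid Li-Stephens forward-backward over the `K^2` ordered-pair
#' state grid (uniform initial distribution, per-step rescaling) and returns
#' per-site posterior genotype probabilities. Sites flagged missing in the
#' genotype likelihoods get a constant emission and are imputed purely from
#' flanking haplotype structure. Marker sets longer than `segment_size` are
#' processed in overlapping windows (see [plan_windows()]).
#'
#' @param gl a `gl_matrix` defined on the panel's markers.
#' @param panel a `haplotype_panel` (or any K x M 0/1 matrix in
#'   `panel$haplotypes` form).
#' @param params an [hmm_params()]; defaults to panel-derived `tau` and
#'   `theta = 1e-3`.
#' @param segment_size,overlap windowing controls.
#' @return An `imputed_genotypes`: `gp` (3 x M posterior genotype triple,
#'   columns sum to 1), `dosage` (`GP1 + 2 GP2`), `best_gt`, `max_gp`, and
#'   `q` (4 x M posterior over the ordered true-allele pair, used for
#'   phasing in joint mode).
#' @export
impute_individual <- function(gl, panel, params = NULL,
                              segment_size = 50000L, overlap = 25000L) {
  H <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
  if (is.null(dim(H)) || nrow(H) < 1L) stop("reference panel is empty")
  if (is.null(params)) params <- hmm_params(panel)
  likmat <- gl_to_matrix(gl)
  M <- ncol(H)
  stopifnot(ncol(likmat) == M)

  plan <- plan_windows(M, segment_size, overlap)
  q <- matrix(0, 4L, M)
  src <- attr(plan, "source")
  for (w in seq_len(nrow(plan))) {
    idx <- plan$start[w]:plan$end[w]
    tau_w <- if (length(idx) > 1L) params$tau[idx[-length(idx)]] else numeric(0)
    qw <- ls_diploid_fb(H[, idx, drop = FALSE],
                        likmat[, idx, drop = FALSE], tau_w, params$theta)
    take <- idx[src[idx] == w]
    q[, take] <- qw[, match(take, idx), drop = FALSE]
  }
  new_imputed(q)
}

#' Exact posterior genotype probabilities by path enumeration
#'
#' Independent oracle for [impute_individual()]: sums over every state path of
#' the diploid copying HMM (feasible only for tiny instances, at most 1e7
#' paths). Shares the model definition but none of the forward-backward code
#' path.
#'
#' @inheritParams impute_individual
#' @return An `imputed_genotypes` with exact posteriors.
#' @export
brute_force_posteriors <- function(gl, panel, params = NULL) {
  H <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
  if (is.null(params)) params <- hmm_params(panel)
  K <- nrow(H)
  M <- ncol(H)
  n_paths <- (K^2)^M
  if (n_paths > 1e7) stop("instance too large for brute-force enumeration")
  likmat <- gl_to_matrix(gl)
  theta <- params$theta

  flip <- function(a, x) ifelse(a == x, 1 - theta, theta)
  # emission and allele-pair tables per state (ordered pairs j, k)
  states <- expand.grid(j = seq_len(K), k = seq_len(K))
  emis <- matrix(0, K^2, M)
  A <- array(0, c(K^2, M, 3))
  for (s in seq_len(K^2)) {
    hj <- H[states$j[s], ]
    hk <- H[states$k[s], ]
    p1 <- flip(hj, 1)
    p2 <- flip(hk, 1)
    A[s, , 1] <- (1 - p1) * (1 - p2)
    A[s, , 2] <- p1 * (1 - p2) + (1 - p1) * p2
    A[s, , 3] <- p1 * p2
    emis[s, ] <- A[s, , 1] * likmat[1, ] + A[s, , 2] * likmat[2, ] +
      A[s, , 3] * likmat[3, ]
  }
  trans_pair <- function(tau) {
    T1 <- matrix(tau / K, K, K)
    diag(T1) <- diag(T1) + (1 - tau)
    T1 %x% T1  # ordered-pair transition (kronecker over the two copies)
  }

  paths <- as.matrix(expand.grid(rep(list(seq_len(K^2)), M)))
  w <- emis[paths[, 1L], 1L] / K^2
  if (M > 1) {
    for (m in 2:M) {
      Tp <- trans_pair(params$tau[m - 1L])
      w <- w * Tp[cbind(paths[, m - 1L], paths[, m])] * emis[paths[, m], m]
    }
  }
  q <- matrix(0, 4L, M)
  for (m in seq_len(M)) {
    s <- paths[, m]
    for (x1 in 0:1) {
      for (x2 in 0:1) {
        p1 <- flip(H[cbind(states$j[s], m)], x1)
        p2 <- flip(H[cbind(states$k[s], m)], x2)
        contrib <- w * p1 * p2 * likmat[x1 + x2 + 1L, m] / emis[s, m]
        q[2L * x1 + x2 + 1L, m] <- sum(contrib)
      }
    }
    q[, m] <- q[, m] / sum(q[, m])
  }
  new_imputed(q)
}

# Phased best-guess haplotypes from the ordered-pair posterior: per site take
# the maximum-posterior ordered allele pair; exact ties between the two
# heterozygous orderings keep the previous orientation (switch-minimising).
phased_haplotypes <- function(imp) {
  q <- imp$q
  M <- ncol(q)
  best <- max.col(t(q), ties.method = "first")
  tie <- abs(q[2L, ] - q[3L, ]) < 1e-12 & (best == 2L | best == 3L)
  if (any(tie)) {
    orient <- 2L  # orientation carried through het sites, switch-minimising
    for (m in seq_len(M)) {
      if (best[m] %in% c(2L, 3L)) {
        if (tie[m]) best[m] <- orient else orient <- best[m]
      }
    }
  }
  h1 <- as.integer(best >= 3L)
  h2 <- as.integer(best %in% c(2L, 4L))
  rbind(h1, h2)
}

#' Joint imputation of a study sample by iterative panel augmentation
#'
#' Iteration 1 imputes every individual against the phased panel alone; each
#' later iteration re-imputes each individual against the panel augmented
#' with the phased best-guess haplotypes of all *other* study individuals
#' from the previous iteration, letting low-coverage individuals inform one
#' another as in joint study-sample imputation.
#'
#' @param gls list of `gl_matrix`, one per study individual.
#' @param panel a `haplotype_panel`.
#' @param params an [hmm_params()]; defaults to panel-derived values.
#' @param iterations number of passes (1 = independent single-sample mode).
#' @param segment_size,overlap windowing controls.
#' @return A list of `imputed_genotypes`, one per individual (final
#'   iteration).
#' @export
impute_joint <- function(gls, panel, params = NULL, iterations = 2L,
                         segment_size = 50000L, overlap = 25000L) {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (is.null(params)) params <- hmm_params(panel)
  n <- length(gls)
  res <- lapply(gls, impute_individual, panel = panel, params = params,
                segment_size = segment_size, overlap = overlap)
  if (iterations == 1L || n == 1L) return(res)
  for (it in 2:iterations) {
    phased <- lapply(res, phased_haplotypes)
    res <- lapply(seq_len(n), function(i) {
      aug <- rbind(panel$haplotypes, do.call(rbind, phased[-i]))
      impute_individual(gls[[i]], aug, params = params,
                        segment_size = segment_size, overlap = overlap)
    })
  }
  res
}
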
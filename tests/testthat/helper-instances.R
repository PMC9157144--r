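# Small constructors for hand-built objects, and an independent dense
# forward-backward used as a second oracle for mid-size HMM instances.

make_gl <- function(lik, missing = NULL) {
  lik <- sweep(lik, 2L, colSums(lik), "/")
  if (is.null(missing)) missing <- rep(FALSE, ncol(lik))
  lik[, missing] <- 1 / 3
  structure(list(lik = lik, missing = missing), class = "gl_matrix")
}

make_panel <- function(H, rho = NULL, pops = NULL) {
  M <- ncol(H)
  if (is.null(rho)) rho <- rep(0.02, max(M - 1L, 0L))
  if (is.null(pops)) pops <- rep("main", nrow(H))
  structure(list(markers = NULL, haplotypes = H, interval_rho = rho,
                 pop_labels = pops),
            class = "haplotype_panel")
}

make_markers <- function(ref, alt, maf = NULL) {
  m <- length(ref)
  data.frame(chrom = "1", pos = seq_len(m) * 1000L, ref = ref, alt = alt,
             maf = if (is.null(maf)) rep(0.2, m) else maf,
             stringsAsFactors = FALSE)
}

make_pileup <- function(n_ref, n_alt) {
  if (is.null(dim(n_ref))) n_ref <- matrix(n_ref, nrow = 1L)
  if (is.null(dim(n_alt))) n_alt <- matrix(n_alt, nrow = 1L)
  structure(list(n_ref = n_ref, n_alt = n_alt,
                 realized_coverage = rowMeans(n_ref + n_alt)),
            class = "pileup_columns")
}

make_truth <- function(haplotypes) {
  n2 <- nrow(haplotypes)
  gt <- haplotypes[seq(1L, n2, 2L), , drop = FALSE] +
    haplotypes[seq(2L, n2, 2L), , drop = FALSE]
  structure(list(haplotypes = haplotypes, genotypes = gt,
                 divergence_rate = 0),
            source_alleles = haplotypes, class = "study_truth")
}

random_tiny_instance <- function() {
  K <- sample(2:3, 1L)
  M <- sample(1:4, 1L)
  H <- matrix(rbinom(K * M, 1L, 0.5), K, M)
  lik <- matrix(runif(3L * M), 3L, M)
  missing <- if (M > 1L && runif(1) < 0.3) {
    seq_len(M) %in% sample(M, 1L)
  } else rep(FALSE, M)
  rho <- if (runif(1) < 0.2) rep(0, max(M - 1L, 0L)) else
    rexp(max(M - 1L, 0L), 10)
  theta <- if (runif(1) < 0.2) 0 else runif(1, 0, 0.2)
  list(panel = make_panel(H, rho = rho),
       gl = make_gl(lik, missing),
       params = hmm_params(tau = 1 - exp(-rho), theta = theta))
}

# dense-matrix diploid forward-backward, sharing no code with the package
# engine: full K^2 x K^2 transition via Kronecker-structured products
ref_diploid_fb <- function(H, lik, tau, theta) {
  K <- nrow(H)
  M <- ncol(H)
  fl <- function(a, x) ifelse(a == x, 1 - theta, theta)
  emis <- function(m) {
    p1 <- fl(H[, m], 1)
    outer(1 - p1, 1 - p1) * lik[1, m] +
      (outer(p1, 1 - p1) + outer(1 - p1, p1)) * lik[2, m] +
      outer(p1, p1) * lik[3, m]
  }
  Tm <- function(t) {
    T1 <- matrix(t / K, K, K)
    diag(T1) <- diag(T1) + 1 - t
    T1
  }
  al <- array(0, c(K, K, M))
  a <- emis(1) / K^2
  a <- a / sum(a)
  al[, , 1] <- a
  if (M > 1) {
    for (m in 2:M) {
      T1 <- Tm(tau[m - 1])
      a <- (t(T1) %*% a %*% T1) * emis(m)
      a <- a / sum(a)
      al[, , m] <- a
    }
  }
  q <- matrix(0, 4, M)
  b <- matrix(1, K, K)
  for (m in M:1) {
    em <- emis(m)
    w <- al[, , m] * b / em
    w[em == 0] <- 0
    p1 <- fl(H[, m], 1)
    for (x1 in 0:1) {
      for (x2 in 0:1) {
        F1 <- if (x1 == 1) p1 else 1 - p1
        F2 <- if (x2 == 1) p1 else 1 - p1
        q[2 * x1 + x2 + 1, m] <- sum(w * outer(F1, F2)) * lik[x1 + x2 + 1, m]
      }
    }
    q[, m] <- q[, m] / sum(q[, m])
    if (m > 1) {
      T1 <- Tm(tau[m - 1])
      b <- T1 %*% (em * b) %*% t(T1)
      b <- b / sum(b)
    }
  }
  q
}
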
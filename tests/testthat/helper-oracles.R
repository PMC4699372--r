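# Independent oracles and small fixture builders used across the suite.

# O(n^2) pairwise-difference Gini (population estimator); brute-force oracle
# for the sorted-vector implementation.
gini_brute <- function(v) {
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / (2 * n^2 * mean(v))
}

# Penalized observed-data mixture NB log-likelihood, written independently
# of the package internals (scalar loops, direct dnbinom/dpois calls).
oracle_penalized_loglik <- function(beta, x, d, sf, alpha, prior, lambda) {
  N <- nrow(x); J <- ncol(x); R <- ncol(d)
  b0 <- beta[seq_len(N)]
  bc <- if (R > 0) beta[N + seq_len(R)] else numeric()
  total <- 0
  for (i in seq_len(N)) {
    l1 <- 0; l0 <- 0
    for (j in seq_len(J)) {
      eta1 <- b0[i] + if (R > 0) sum(d[j, ] * bc) else 0
      mu1 <- sf[j] * exp(eta1)
      mu0 <- sf[j] * exp(b0[i])
      lp <- function(mu) {
        if (alpha[i] == 0) dpois(x[i, j], mu, log = TRUE)
        else dnbinom(x[i, j], size = 1 / alpha[i], mu = mu, log = TRUE)
      }
      l1 <- l1 + lp(mu1)
      l0 <- l0 + lp(mu0)
    }
    p <- prior[i]
    total <- total + if (p >= 1) l1 else if (p <= 0) l0 else {
      a <- log(p) + l1; b <- log(1 - p) + l0
      m <- max(a, b); m + log(exp(a - m) + exp(b - m))
    }
  }
  total - lambda / 2 * sum(beta^2)
}

# Generic numerical maximizer of the penalized mixture log-likelihood
# (BFGS with a Nelder-Mead polish), the reference the EM/IRLS path is
# checked against on small instances.
oracle_fit <- function(x, d, sf, alpha, prior, lambda) {
  N <- nrow(x); R <- ncol(d)
  init <- c(log(rowMeans(sweep(x, 2, sf, "/")) + 1), rep(0, R))
  nll <- function(b) -oracle_penalized_loglik(b, x, d, sf, alpha, prior, lambda)
  o <- optim(init, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  o$par
}

# Mann-Whitney AUC of scores for separating a positive from a negative class.
auc_score <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Random small fit instance (N <= 2 guides, J <= 3 samples, one condition)
# for oracle-equivalence checks; default priors (all guides efficient).
random_small_instance <- function() {
  N <- sample(1:2, 1)
  J <- sample(2:3, 1)
  dcol <- c(0, rep(1, J - 1))          # baseline + treated samples
  d <- crisprmle::screen_design(matrix(dcol, J, 1),
                                sample_ids = paste0("s", 1:J),
                                condition_ids = "c1")
  alpha <- sample(c(0, 0.05, 0.2), 1)
  mu <- matrix(exp(runif(N * J, log(10), log(500))), N, J)
  x <- matrix(if (alpha == 0) rpois(N * J, mu)
              else rnbinom(N * J, size = 1 / alpha, mu = mu), N, J)
  rownames(x) <- paste0("sg", 1:N)
  list(x = x, d = d, sf = exp(runif(J, -0.2, 0.2)),
       alpha = rep(alpha, N), prior = rep(1, N))
}

# Library of n guides with distinct fixed spacers (deterministic).
tiny_library <- function(n = 3, genes = NULL, L = 20) {
  bases <- c("A", "C", "G", "T")
  spacers <- vapply(seq_len(n), function(i) {
    set.seed(1000 + i)
    paste(sample(bases, L, replace = TRUE), collapse = "")
  }, "")
  if (is.null(genes)) genes <- paste0("gene", ceiling(seq_len(n) / 2))
  crisprmle::sgrna_library(paste0("sg", seq_len(n)), genes, spacers)
}
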
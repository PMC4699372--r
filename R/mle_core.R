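## ---------------------------------------------------------------------------
## Per-gene negative binomial GLM with a latent knockout-efficiency mixture.
##
## For gene g with N guides in J samples under R conditions the stacked
## relative abundances follow  log(q) = D' beta  where D' is the binary
## extended design matrix (N baseline columns, then R condition columns) and
## the stacking order is guide-fastest: (q_11, q_21, ..., q_N1, ..., q_NJ).
## Counts are NB(mu, alpha) with mu = s_j * q. An efficient guide (pi = 1)
## feels the condition terms; an inefficient one (pi = 0) keeps only its
## baseline. EM alternates the posterior efficiency e_i (E step) with an
## iteratively reweighted ridge regression for beta (M step).
## ---------------------------------------------------------------------------

LINPRED_CLIP <- 30

#' Build the extended design matrix for one gene
#'
#' @param design a [screen_design()] (or plain binary J x R matrix).
#' @param n_sgrnas number of guides N in the gene.
#' @return binary (N*J) x (N+R) matrix; rows in guide-fastest order, first
#'   N columns are per-guide baselines, remaining R columns repeat the
#'   design row of the corresponding sample.
#' @export
build_extended_design <- function(design, n_sgrnas) {
  d <- unclass(as.matrix(design))
  J <- nrow(d); R <- ncol(d); N <- as.integer(n_sgrnas)
  if (N < 1L) stop_validation("need at least one sgRNA")
  base_block <- kronecker(matrix(1, J, 1L), diag(N))
  cond_block <- if (R > 0L) kronecker(d, matrix(1, N, 1L)) else
    matrix(0, N * J, 0L)
  out <- cbind(base_block, cond_block)
  colnames(out) <- c(paste0("baseline_", seq_len(N)),
                     if (R > 0L) colnames(d))
  out
}

#' Negative binomial log-likelihood
#'
#' Log-probability of count `x` under mean `mu` and over-dispersion
#' `alpha` (variance `mu + alpha * mu^2`); `alpha = 0` is the Poisson
#' limit. Vectorized with recycling.
#'
#' @param x non-negative integer counts.
#' @param mu positive means.
#' @param alpha non-negative dispersions.
#' @return log-probabilities.
#' @export
nb_loglik <- function(x, mu, alpha) {
  n <- max(length(x), length(mu), length(alpha))
  x <- rep_len(x, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  if (any(mu <= 0)) stop_validation("nb_loglik requires mu > 0")
  if (any(alpha < 0)) stop_validation("nb_loglik requires alpha >= 0")
  out <- numeric(n)
  pois <- alpha == 0
  if (any(pois)) out[pois] <- dpois(x[pois], mu[pois], log = TRUE)
  if (any(!pois)) {
    out[!pois] <- dnbinom(x[!pois], size = 1 / alpha[!pois],
                          mu = mu[!pois], log = TRUE)
  }
  out
}

#' Prior knockout-efficiency probabilities from library scores
#'
#' Raw spacer scores in \[-2, 2\] are rescaled linearly to \[0, 1\] as
#' `(v + 2) / 4`; scores already on the probability scale pass through;
#' guides without a score get prior 1 (assumed efficient).
#'
#' @param library an [sgrna_library()].
#' @return named numeric vector of priors in \[0, 1\].
#' @export
initial_efficiency <- function(library) {
  v <- library$efficiency_score
  scale <- attr(library, "efficiency_scale")
  p <- if (identical(scale, "ssc")) (v + 2) / 4 else v
  p[is.na(p)] <- 1
  setNames(pmin(pmax(p, 0), 1), library$sgrna_id)
}

## per-guide log-likelihood sums under the efficient / inefficient models
component_logliks <- function(x, design, beta, alpha, sf) {
  N <- nrow(x); J <- ncol(x); R <- ncol(design)
  b0 <- beta[seq_len(N)]
  bc <- if (R > 0L) beta[N + seq_len(R)] else numeric()
  cond_shift <- if (R > 0L) as.vector(unclass(design) %*% bc) else numeric(J)
  h1 <- outer(b0, cond_shift, "+")      # N x J
  h0 <- matrix(b0, N, J)
  clip <- function(h) pmin(pmax(h, -LINPRED_CLIP), LINPRED_CLIP)
  mu1 <- sweep(exp(clip(h1)), 2L, sf, "*")
  mu0 <- sweep(exp(clip(h0)), 2L, sf, "*")
  av <- matrix(alpha, N, J)
  list(l1 = rowSums(matrix(nb_loglik(as.vector(x), as.vector(mu1),
                                     as.vector(av)), N, J)),
       l0 = rowSums(matrix(nb_loglik(as.vector(x), as.vector(mu0),
                                     as.vector(av)), N, J)))
}

#' E step: posterior knockout efficiency
#'
#' Posterior probability that each guide is efficient, combining its prior
#' with the likelihood of its counts across all samples under the
#' condition-responsive model versus the baseline-only model; computed in
#' log space. Degenerate priors 0 and 1 are pinned (no update).
#'
#' @param x N x J count matrix for the gene (guides x samples).
#' @param design binary J x R design matrix.
#' @param beta coefficient vector of length N + R.
#' @param prior_e per-guide prior efficiency in \[0, 1\].
#' @param alpha per-guide over-dispersion.
#' @param sf per-sample size factors (aligned to the columns of `x`).
#' @return per-guide posterior vector in \[0, 1\].
#' @export
e_step <- function(x, design, beta, prior_e, alpha, sf) {
  ll <- component_logliks(x, design, beta, alpha, sf)
  e <- prior_e
  free <- prior_e > 0 & prior_e < 1
  if (any(free)) {
    lo <- log(prior_e[free]) + ll$l1[free]
    l0 <- log1p(-prior_e[free]) + ll$l0[free]
    e[free] <- 1 / (1 + exp(l0 - lo))
  }
  e
}

#' Penalized observed-data log-likelihood of the mixture model
#'
#' Sum over guides of the log mixture density (prior-weighted efficient and
#' inefficient components) minus the ridge penalty
#' `lambda/2 * ||beta||^2`. This is the objective whose monotone increase
#' the EM driver guarantees.
#'
#' @inheritParams e_step
#' @param lambda ridge penalty.
#' @return scalar log-likelihood.
#' @export
gene_penalized_loglik <- function(x, design, beta, prior_e, alpha, sf, lambda) {
  ll <- component_logliks(x, design, beta, alpha, sf)
  per <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    p <- prior_e[i]
    per[i] <- if (p >= 1) ll$l1[i]
    else if (p <= 0) ll$l0[i]
    else {
      a <- log(p) + ll$l1[i]; b <- log1p(-p) + ll$l0[i]
      m <- max(a, b); m + log(exp(a - m) + exp(b - m))
    }
  }
  sum(per) - lambda / 2 * sum(beta^2)
}

#' M step: iteratively reweighted ridge regression
#'
#' Solves for the coefficient vector at fixed posterior efficiencies by the
#' weighted ridge update
#' `beta <- (D'^T W D' + lambda I)^-1 D'^T W z` with working weights
#' `w = e / (1/mu + alpha)` and working residuals
#' `z = h + e (x - mu) / mu`, where `h = D' beta` and `mu = s exp(h)`
#' (clipped at |h| = 30 to guard against overflow on degenerate input).
#'
#' @param x N x J count matrix.
#' @param Dp extended design matrix from [build_extended_design()].
#' @param e fixed per-guide efficiency weights.
#' @param alpha per-guide over-dispersion.
#' @param sf per-sample size factors.
#' @param beta starting coefficient vector (length N + R).
#' @param cfg a [fit_config()] (uses `ridge_lambda`, `irls_tol`,
#'   `max_irls_iters`).
#' @return list with `beta`, `w` (final working weights on the stacked
#'   observations), `converged`, `n_iterations`.
#' @export
m_step_irls <- function(x, Dp, e, alpha, sf, beta, cfg = fit_config()) {
  N <- nrow(x); J <- ncol(x)
  xv <- as.vector(x)                 # guide-fastest stacking
  sv <- rep(sf, each = N)
  ev <- rep(e, times = J)
  av <- rep(alpha, times = J)
  lambda <- cfg$ridge_lambda
  P <- ncol(Dp)
  conv <- FALSE
  it <- 0L
  w <- NULL
  for (it in seq_len(cfg$max_irls_iters)) {
    h <- as.vector(Dp %*% beta)
    if (any(abs(h) > LINPRED_CLIP)) {
      h <- pmin(pmax(h, -LINPRED_CLIP), LINPRED_CLIP)
    }
    mu <- sv * exp(h)
    w <- ev / (1 / mu + av)
    z <- h + ev * (xv - mu) / mu
    A <- crossprod(Dp, Dp * w) + diag(lambda, P)
    rhs <- crossprod(Dp, w * z)
    beta_new <- tryCatch(as.vector(solve(A, rhs)),
                         error = function(err) {
                           stop("IRLS system not solvable: ",
                                conditionMessage(err))
                         })
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < cfg$irls_tol) { conv <- TRUE; break }
  }
  h <- pmin(pmax(as.vector(Dp %*% beta), -LINPRED_CLIP), LINPRED_CLIP)
  mu <- sv * exp(h)
  list(beta = beta, w = ev / (1 / mu + av), mu = mu,
       converged = conv, n_iterations = it)
}

align_sf <- function(sf, sample_ids) {
  if (is.null(names(sf))) {
    if (length(sf) != length(sample_ids)) {
      stop_validation("size factors do not match the samples")
    }
    return(sf)
  }
  miss <- setdiff(sample_ids, names(sf))
  if (length(miss)) stop_validation("size factors missing for: ",
                                    paste(miss, collapse = ", "))
  unname(sf[sample_ids])
}

init_beta <- function(x, sf, R) {
  norm_mean <- rowMeans(sweep(x, 2L, sf, "/"))
  c(log(norm_mean + 1), rep(0, R))
}

#' Fit the mixture NB-GLM for one gene by EM
#'
#' Alternates the posterior-efficiency E step with the IRLS-ridge M step
#' from a null start (baselines at the log mean normalized count + 1,
#' condition coefficients at 0) until `max |delta beta|` falls below
#' `cfg$convergence_tol` or `cfg$max_em_iters` is reached. After each M
#' step the penalized observed-data log-likelihood is checked; a step that
#' would decrease it is contracted toward the previous iterate
#' (step-halving), which keeps the EM trace monotone without altering the
#' update direction. Genes whose counts are all zero are flagged
#' not-estimable (`converged = NA`) with zero condition coefficients.
#'
#' @param x N x J count matrix (rownames = guide ids).
#' @param design binary J x R design (a [screen_design()] row-aligned to
#'   the columns of `x`).
#' @param sf per-sample size factors.
#' @param alpha per-guide over-dispersion vector.
#' @param prior_e per-guide prior efficiency (default all 1).
#' @param cfg a [fit_config()].
#' @param gene_id label stored in the fit.
#' @param Dp optional precomputed [build_extended_design()] matrix.
#' @return list of class `gene_fit`: `gene_id`, `sgrna_ids`,
#'   `beta_conditions`, `beta_baselines`, `efficiency_posterior`,
#'   `prior_e`, `converged`, `n_iterations`, `loglik_trace`, `w`,
#'   `mu_matrix`, plus empty significance slots filled later.
#' @export
fit_gene <- function(x, design, sf, alpha, prior_e = NULL,
                     cfg = fit_config(), gene_id = "gene", Dp = NULL) {
  x <- as.matrix(x)
  N <- nrow(x); J <- ncol(x); R <- ncol(design)
  if (N < 1L) stop_validation("gene has no sgRNAs")
  if (is.null(prior_e)) prior_e <- rep(1, N)
  if (is.null(Dp)) Dp <- build_extended_design(design, N)
  cond_names <- colnames(design)
  sg_names <- if (!is.null(rownames(x))) rownames(x) else paste0("sg", seq_len(N))

  if (all(x == 0)) {
    return(structure(list(
      gene_id = gene_id, sgrna_ids = sg_names,
      beta_conditions = setNames(rep(0, R), cond_names),
      beta_baselines = setNames(rep(0, N), sg_names),
      efficiency_posterior = setNames(prior_e, sg_names),
      prior_e = setNames(prior_e, sg_names),
      converged = NA, n_iterations = 0L,
      loglik_trace = numeric(),
      w = rep(0, N * J),
      mu_matrix = matrix(NA_real_, N, J, dimnames = dimnames(x)),
      se = setNames(rep(NA_real_, R), cond_names),
      wald_z = setNames(rep(NA_real_, R), cond_names),
      wald_p = setNames(rep(NA_real_, R), cond_names),
      perm_p = setNames(rep(NA_real_, R), cond_names)),
      class = "gene_fit"))
  }

  beta <- init_beta(x, sf, R)
  lambda <- cfg$ridge_lambda
  pll <- function(b) gene_penalized_loglik(x, design, b, prior_e, alpha, sf,
                                           lambda)
  ll_cur <- pll(beta)
  trace <- ll_cur
  e <- prior_e
  converged <- FALSE
  last_m <- NULL
  it <- 0L
  for (it in seq_len(cfg$max_em_iters)) {
    e <- e_step(x, design, beta, prior_e, alpha, sf)
    m <- m_step_irls(x, Dp, e, alpha, sf, beta, cfg)
    beta_new <- m$beta
    ll_new <- pll(beta_new)
    halvings <- 0L
    while (ll_new < ll_cur - 1e-10 && halvings < 30L) {
      beta_new <- (beta_new + beta) / 2
      ll_new <- pll(beta_new)
      halvings <- halvings + 1L
    }
    if (ll_new < ll_cur - 1e-10) {   # no admissible step; stay put
      beta_new <- beta
      ll_new <- ll_cur
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_cur <- ll_new
    trace <- c(trace, ll_cur)
    last_m <- m
    if (delta < cfg$convergence_tol) { converged <- TRUE; break }
  }
  e <- e_step(x, design, beta, prior_e, alpha, sf)
  # final weights / fitted means at the accepted beta
  h <- pmin(pmax(as.vector(Dp %*% beta), -LINPRED_CLIP), LINPRED_CLIP)
  mu <- rep(sf, each = N) * exp(h)
  w <- rep(e, times = J) / (1 / mu + rep(alpha, times = J))
  structure(list(
    gene_id = gene_id, sgrna_ids = sg_names,
    beta_conditions = setNames(beta[N + seq_len(R)], cond_names),
    beta_baselines = setNames(beta[seq_len(N)], sg_names),
    efficiency_posterior = setNames(e, sg_names),
    prior_e = setNames(prior_e, sg_names),
    converged = converged, n_iterations = it,
    loglik_trace = trace,
    w = w,
    mu_matrix = matrix(mu, N, J, dimnames = dimnames(x)),
    se = setNames(rep(NA_real_, R), cond_names),
    wald_z = setNames(rep(NA_real_, R), cond_names),
    wald_p = setNames(rep(NA_real_, R), cond_names),
    perm_p = setNames(rep(NA_real_, R), cond_names)),
    class = "gene_fit")
}

#' Fit every gene in a screen
#'
#' Genes are fit independently (order-invariant); the extended design is
#' cached per gene size.
#'
#' @param counts a [count_matrix()] whose columns match the design rows
#'   (use [align_design()] first).
#' @param library an [sgrna_library()] covering every count row.
#' @param design a [screen_design()].
#' @param sf per-sample size factors.
#' @param alpha per-sgRNA dispersion vector (named or in library order).
#' @param prior_e optional per-sgRNA prior efficiencies (default: from
#'   [initial_efficiency()]).
#' @param cfg a [fit_config()].
#' @param progress log one line per 500 genes to stderr.
#' @return named list of `gene_fit` objects, one per gene.
#' @export
fit_all <- function(counts, library, design, sf, alpha, prior_e = NULL,
                    cfg = fit_config(), progress = FALSE) {
  if (!identical(colnames(counts), rownames(design))) {
    stop_validation("count samples and design samples disagree; ",
                    "call align_design() first")
  }
  miss <- setdiff(rownames(counts), library$sgrna_id)
  if (length(miss)) {
    stop_validation("count rows missing from library: ",
                    paste(utils::head(miss, 5), collapse = ", "))
  }
  if (is.null(prior_e)) prior_e <- initial_efficiency(library)
  if (is.null(names(alpha))) names(alpha) <- library$sgrna_id
  if (is.null(names(prior_e))) names(prior_e) <- library$sgrna_id
  sgrnas <- rownames(counts)
  genes <- library$gene_id[match(sgrnas, library$sgrna_id)]
  split_idx <- split(seq_along(sgrnas), genes)
  # preserve first-appearance order of genes
  split_idx <- split_idx[unique(genes)]
  dp_cache <- new.env(parent = emptyenv())
  sfv <- align_sf(sf, colnames(counts))
  fits <- vector("list", length(split_idx))
  names(fits) <- names(split_idx)
  for (k in seq_along(split_idx)) {
    idx <- split_idx[[k]]
    N <- length(idx)
    key <- as.character(N)
    if (is.null(dp_cache[[key]])) {
      dp_cache[[key]] <- build_extended_design(design, N)
    }
    ids <- sgrnas[idx]
    fits[[k]] <- fit_gene(counts[idx, , drop = FALSE], design, sfv,
                          alpha = unname(alpha[ids]),
                          prior_e = unname(prior_e[ids]),
                          cfg = cfg, gene_id = names(split_idx)[k],
                          Dp = dp_cache[[key]])
    if (progress && k %% 500L == 0L) {
      message("fitted ", k, "/", length(split_idx), " genes")
    }
  }
  fits
}
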
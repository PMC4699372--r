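## ---------------------------------------------------------------------------
## Significance of condition beta scores: a Wald test using the ridge
## sandwich covariance (A + lambda I)^-1 A (A + lambda I)^-1 with
## A = D'^T W D', and a permutation test that refits pseudo-genes assembled
## from guides drawn at random across the whole library.
## ---------------------------------------------------------------------------

#' Wald test for the condition coefficients of one gene fit
#'
#' Standard errors come from the sandwich covariance of the ridge estimate,
#' `Cov = (D'^T W D' + lambda I)^-1 (D'^T W D') (D'^T W D' + lambda I)^-1`,
#' evaluated at the converged working weights; `z = beta / SE` is compared
#' to the standard normal, two-sided.
#'
#' @param fit a `gene_fit` from [fit_gene()].
#' @param design the [screen_design()] used for the fit.
#' @param cfg the [fit_config()] used (for `ridge_lambda`).
#' @return the fit with `se`, `wald_z`, `wald_p` filled in.
#' @export
wald_test <- function(fit, design, cfg = fit_config()) {
  R <- ncol(design)
  if (R == 0L) return(fit)
  if (is.na(fit$converged)) return(fit)   # not estimable
  N <- length(fit$sgrna_ids)
  Dp <- build_extended_design(design, N)
  A <- crossprod(Dp, Dp * fit$w)
  M <- A + diag(cfg$ridge_lambda, ncol(Dp))
  Minv <- solve(M)
  covb <- Minv %*% A %*% Minv
  idx <- N + seq_len(R)
  se <- sqrt(pmax(diag(covb)[idx], 0))
  beta <- unname(fit$beta_conditions)
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), ifelse(beta == 0, 1, 0))
  if (any(se == 0 & beta != 0)) {
    warning("zero standard error with nonzero beta for gene ", fit$gene_id)
  }
  fit$se <- setNames(se, names(fit$beta_conditions))
  fit$wald_z <- setNames(z, names(fit$beta_conditions))
  fit$wald_p <- setNames(p, names(fit$beta_conditions))
  fit
}

#' Wald tests for a list of gene fits
#' @param fits list from [fit_all()].
#' @inheritParams wald_test
#' @return the list with Wald slots filled.
#' @export
wald_all <- function(fits, design, cfg = fit_config()) {
  lapply(fits, wald_test, design = design, cfg = cfg)
}

#' Permutation test of condition beta scores
#'
#' Builds an empirical null by repeatedly assembling pseudo-genes of each
#' observed gene size from guides drawn uniformly (without replacement
#' within a draw) across the whole library, refitting their condition
#' coefficients with the guides' observed dispersion and efficiency
#' posteriors held fixed, and comparing observed `|beta|` against the null
#' draws. Two-sided with the add-one rule, so
#' `perm_p in [1/(B+1), 1]`. Null draws are shared across all genes of the
#' same size.
#'
#' @param fits list of `gene_fit` objects with converged betas.
#' @param counts,design,sf the aligned inputs used for the observed fit.
#' @param alpha per-sgRNA dispersion vector (named).
#' @param cfg a [fit_config()]; `n_permutations = "auto"` resolves to twice
#'   the number of genes, and `rng_seed` fixes the draws.
#' @return the fits with `perm_p` filled (all `NA` when `n_permutations`
#'   is 0).
#' @export
permutation_test <- function(fits, counts, design, sf, alpha,
                             cfg = fit_config()) {
  R <- ncol(design)
  if (R == 0L || length(fits) == 0L) return(fits)
  B <- if (identical(cfg$n_permutations, "auto")) 2L * length(fits)
       else cfg$n_permutations
  if (B == 0L) return(fits)
  sgrnas <- rownames(counts)
  n <- length(sgrnas)
  if (is.null(names(alpha))) names(alpha) <- sgrnas
  # observed posterior efficiency per guide, gathered across gene fits
  e_obs <- setNames(rep(1, n), sgrnas)
  for (f in fits) e_obs[f$sgrna_ids] <- f$efficiency_posterior
  sfv <- align_sf(sf, colnames(counts))
  sizes <- sort(unique(vapply(fits, function(f) length(f$sgrna_ids), 0L)))
  set.seed(cfg$rng_seed)
  null_by_size <- list()
  for (N in sizes) {
    Dp <- build_extended_design(design, N)
    nulls <- matrix(NA_real_, B, R)
    for (b in seq_len(B)) {
      idx <- sample.int(n, N)
      xb <- counts[idx, , drop = FALSE]
      if (all(xb == 0)) { nulls[b, ] <- 0; next }
      m <- m_step_irls(xb, Dp, e = unname(e_obs[idx]),
                       alpha = unname(alpha[sgrnas[idx]]), sf = sfv,
                       beta = init_beta(unclass(xb), sfv, R), cfg = cfg)
      nulls[b, ] <- m$beta[N + seq_len(R)]
    }
    null_by_size[[as.character(N)]] <- abs(nulls)
  }
  for (g in seq_along(fits)) {
    f <- fits[[g]]
    if (is.na(f$converged)) next
    nulls <- null_by_size[[as.character(length(f$sgrna_ids))]]
    obs <- abs(unname(f$beta_conditions))
    p <- vapply(seq_len(R), function(r) {
      (1 + sum(nulls[, r] >= obs[r])) / (1 + B)
    }, 0.0)
    fits[[g]]$perm_p <- setNames(p, names(f$beta_conditions))
  }
  fits
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return step-up adjusted q-values.
#' @export
adjust_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Full screen analysis: normalize, fit dispersion, fit genes, test
#'
#' Convenience driver chaining [size_factors()], [fit_dispersion()] (unless
#' a dispersion vector is supplied), [fit_all()], [wald_all()],
#' [permutation_test()] and [gene_results_table()].
#'
#' @param counts a [count_matrix()].
#' @param library an [sgrna_library()].
#' @param design a [screen_design()] (samples matched to counts by name).
#' @param cfg a [fit_config()].
#' @param alpha optional per-sgRNA dispersion vector; when `NULL` the
#'   mean-variance model is fit first.
#' @param permute run the permutation test.
#' @return list of class `screen_fit` with `results` (a `gene_results`
#'   table), `fits`, `size_factors`, `dispersion`, `config`.
#' @export
screen_mle <- function(counts, library, design, cfg = fit_config(),
                       alpha = NULL, permute = TRUE) {
  al <- align_design(design, counts)
  sf <- size_factors(al$counts, mode = cfg$size_factor_mode,
                     control_ids = cfg$control_sgrna_ids)
  dispersion <- NULL
  if (is.null(alpha)) {
    dispersion <- fit_dispersion(al$counts, sf, al$design, library, cfg)
    alpha <- dispersion$alpha
  }
  if (is.null(names(alpha))) names(alpha) <- rownames(al$counts)
  fits <- fit_all(al$counts, library, al$design, sf, alpha = alpha,
                  cfg = cfg)
  fits <- wald_all(fits, al$design, cfg)
  if (permute) {
    fits <- permutation_test(fits, al$counts, al$design, sf, alpha, cfg)
  }
  structure(list(results = gene_results_table(fits),
                 fits = fits, size_factors = sf,
                 dispersion = dispersion, config = cfg),
            class = "screen_fit")
}
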
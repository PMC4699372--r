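## ---------------------------------------------------------------------------
## Median-ratio size factors and the over-dispersion model. The size factor
## of sample j is the median over eligible guides of x_ij / xhat_i, where
## xhat_i is the geometric mean of guide i's counts across samples; only
## guides nonzero in every sample (xhat > 0) contribute. Dispersion is fit
## by a first-pass EM with fixed alpha, then a log-log regression of excess
## residual variance on the fitted mean:  sigma^2 = mu + k * mu^b, giving
## alpha_i = (sigma_f^2 - mu) / mu^2.
## ---------------------------------------------------------------------------

#' Median-ratio size factors
#'
#' @param counts a [count_matrix()].
#' @param mode `"all"` uses every guide with a positive geometric mean;
#'   `"control"` restricts the median to a predefined control-guide set
#'   (useful when most genes in the library are expected to be essential).
#' @param control_ids control sgRNA ids for `mode = "control"`.
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, mode = c("all", "control"),
                         control_ids = NULL) {
  mode <- match.arg(mode)
  x <- unclass(counts)
  if (mode == "control") {
    if (is.null(control_ids) || !length(control_ids)) {
      stop_validation("control mode requires control_ids")
    }
    miss <- setdiff(control_ids, rownames(x))
    if (length(miss)) {
      stop_validation("control sgRNAs absent from counts: ",
                      paste(utils::head(miss, 5), collapse = ", "))
    }
    x <- x[control_ids, , drop = FALSE]
  }
  # geometric means in log space; rows with any zero are ineligible
  eligible <- rowSums(x == 0) == 0L
  if (!any(eligible)) {
    stop_validation("no sgRNA has positive counts in every sample; ",
                    "consider control-mode size factors or prefiltering")
  }
  lx <- log(x[eligible, , drop = FALSE])
  lref <- rowMeans(lx)
  s <- apply(exp(lx - lref), 2L, median)
  if (any(s <= 0)) stop_validation("non-positive size factor computed")
  s
}

#' Divide counts by their size factors
#' @param counts a [count_matrix()].
#' @param sf named size factors from [size_factors()].
#' @return numeric matrix of normalized counts.
#' @export
normalized_counts <- function(counts, sf) {
  sweep(unclass(counts), 2L, sf[colnames(counts)], "/")
}

#' Fit the over-dispersion model
#'
#' Runs the full per-gene EM fit with the over-dispersion held at
#' `cfg$dispersion_prefit_alpha` and computes fitted means and squared
#' residuals for every guide/sample cell. Each guide's residual variance is
#' the mean of its squared residuals across samples, rescaled by the
#' per-gene residual degrees of freedom (`NJ / (NJ - N - R)` for a gene
#' with `N` guides, `J` samples and `R` condition terms) so that the
#' mean-variance points are approximately unbiased. The trend
#' `sigma^2 = mu + k * mu^b` is learned by regressing
#' `log(sigma_i^2 - mu_i)` on `log(mu_i)` over guides with excess
#' variance, and the smoothed variance is converted back to a per-guide
#' dispersion `alpha_i = (sigma_f^2 - mu_i) / mu_i^2 = k * mu_i^(b-2)`,
#' floored at `cfg$alpha_floor`.
#'
#' @param counts a [count_matrix()].
#' @param sf size factors.
#' @param design a [screen_design()] aligned to the counts.
#' @param library an [sgrna_library()].
#' @param cfg a [fit_config()].
#' @return list of class `dispersion_model` with `k`, `b`, `alpha` (named
#'   per-sgRNA vector), `fitted_means` and `residual_variances` (matrices),
#'   and `fallback` flag.
#' @export
fit_dispersion <- function(counts, sf, design, library, cfg = fit_config()) {
  al <- align_design(design, counts)
  prefit <- fit_all(al$counts, library, al$design, sf,
                    alpha = rep(cfg$dispersion_prefit_alpha, nrow(al$counts)),
                    prior_e = NULL, cfg = cfg, progress = FALSE)
  J <- ncol(al$counts); R <- ncol(al$design)
  mu <- matrix(NA_real_, nrow(al$counts), ncol(al$counts),
               dimnames = dimnames(al$counts))
  dfc <- setNames(rep(NA_real_, nrow(al$counts)), rownames(al$counts))
  for (f in prefit) {
    mu[f$sgrna_ids, ] <- f$mu_matrix
    N <- length(f$sgrna_ids)
    dfc[f$sgrna_ids] <- (N * J) / max(N * J - N - R, 1L)
  }
  resid2 <- (unclass(al$counts) - mu)^2
  mu_i <- rowMeans(mu)
  sig2_i <- rowMeans(resid2) * dfc
  excess <- sig2_i - mu_i
  use <- which(is.finite(excess) & excess > 0 & mu_i > 0)
  fallback <- length(use) < 2L
  if (fallback) {
    warning("fewer than 2 sgRNAs with excess variance; ",
            "falling back to the prefit dispersion for all sgRNAs")
    alpha <- rep(cfg$dispersion_prefit_alpha, nrow(al$counts))
    k <- NA_real_; b <- NA_real_
  } else {
    fit <- lm(log(excess[use]) ~ log(mu_i[use]))
    k <- exp(unname(coef(fit)[1]))
    b <- unname(coef(fit)[2])
    alpha <- k * mu_i^(b - 2)
  }
  alpha <- pmax(alpha, cfg$alpha_floor)
  names(alpha) <- rownames(al$counts)
  structure(list(k = k, b = b, alpha = alpha, fitted_means = mu,
                 residual_variances = resid2, fallback = fallback),
            class = "dispersion_model")
}
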
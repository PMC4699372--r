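test_that("extended design matrix follows the stacked guide-fastest layout", {
  d <- screen_design(matrix(c(0, 1), 2, 1), sample_ids = c("s1", "s2"),
                     condition_ids = "c1")
  Dp <- build_extended_design(d, 2)
  expect_equal(unname(Dp),
               rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 1), c(0, 1, 1)))
  # degenerate: one guide, no conditions -> all-ones baseline column
  d0 <- screen_design(matrix(numeric(), 3, 0), sample_ids = paste0("s", 1:3))
  expect_equal(unname(build_extended_design(d0, 1)), matrix(1, 3, 1))
  # each row: one baseline indicator + the active conditions of its sample
  d2 <- screen_design(matrix(c(0, 1, 1, 0, 1, 1), 3, 2),
                      sample_ids = paste0("s", 1:3))
  Dp2 <- build_extended_design(d2, 3)
  expect_equal(unname(rowSums(Dp2)),
               1 + rep(unname(rowSums(unclass(d2))), each = 3))
})

test_that("NB log-likelihood hits the Poisson limit and normalizes", {
  expect_equal(nb_loglik(2, 2, 0), log(2) - 2)
  expect_equal(nb_loglik(0, 3.5, 0), -3.5)
  for (case in list(c(5, 4, 0.3), c(0, 10, 0.05), c(17, 8, 1))) {
    total <- sum(exp(nb_loglik(0:2000, case[2], case[3])))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_error(nb_loglik(1, -1, 0.1), class = "crisprmle_validation_error")
})

test_that("efficiency priors rescale raw scores and default to 1", {
  lib <- sgrna_library(paste0("sg", 1:4), rep("g", 4),
                       c("AAAA", "CCCC", "GGGG", "TTTT"),
                       efficiency_score = c(0, 2, -2, NA),
                       efficiency_scale = "ssc")
  expect_equal(unname(initial_efficiency(lib)), c(0.5, 1, 0, 1))
  plain <- sgrna_library("sg1", "g", "ACGT")
  expect_equal(unname(initial_efficiency(plain)), 1)
  expect_error(sgrna_library("a", "g", "ACGT", efficiency_score = 3,
                             efficiency_scale = "ssc"),
               class = "crisprmle_validation_error")
})

test_that("E step computes calibrated posteriors and pins degenerate priors", {
  d <- screen_design(matrix(c(0, 0, 1, 1), 4, 1),
                     sample_ids = paste0("s", 1:4), condition_ids = "c1")
  sf <- rep(1, 4)
  # flat counts while beta_c = 2 strongly favours the inefficient model
  x <- matrix(rep(100L, 4), 1, 4)
  beta <- c(log(100), 2)
  e <- e_step(x, d, beta, prior_e = 0.5, alpha = 0.1, sf = sf)
  expect_lt(e, 0.5)
  # degenerate priors are pinned regardless of data
  expect_equal(e_step(x, d, beta, prior_e = 1, alpha = 0.1, sf = sf), 1)
  expect_equal(e_step(x, d, beta, prior_e = 0, alpha = 0.1, sf = sf), 0)
  # equal component likelihoods with prior 0.5 -> posterior 0.5
  e0 <- e_step(x, d, c(log(100), 0), prior_e = 0.5, alpha = 0.1, sf = sf)
  expect_equal(e0, 0.5)
})

test_that("IRLS reaches the saturated Poisson solution and kills no-signal betas", {
  d <- screen_design(matrix(c(0, 1), 2, 1), sample_ids = c("s1", "s2"),
                     condition_ids = "c1")
  Dp <- build_extended_design(d, 1)
  cfg <- fit_config(ridge_lambda = 1e-8)
  m <- m_step_irls(matrix(c(10, 40), 1, 2), Dp, e = 1, alpha = 0,
                   sf = c(1, 1), beta = c(log(10), 0), cfg = cfg)
  expect_equal(m$beta, c(log(10), log(4)), tolerance = 1e-6)
  # identical counts in all samples: condition coefficient goes to zero
  m0 <- m_step_irls(matrix(c(25, 25, 25), 1, 3),
                    build_extended_design(screen_design(matrix(c(0, 1, 1), 3, 1),
                      sample_ids = paste0("s", 1:3)), 1),
                    e = 1, alpha = 0, sf = rep(1, 3),
                    beta = c(log(25), 0), cfg = cfg)
  expect_lt(abs(m0$beta[2]), 1e-6)
})

test_that("EM/IRLS agrees with a generic optimizer on small instances", {
  set.seed(101)
  cfg <- fit_config(convergence_tol = 1e-6, irls_tol = 1e-8,
                    max_irls_iters = 200)
  for (k in 1:8) {
    inst <- random_small_instance()
    fit <- fit_gene(inst$x, inst$d, inst$sf, inst$alpha,
                    prior_e = inst$prior, cfg = cfg)
    ref <- oracle_fit(inst$x, unclass(inst$d), inst$sf, inst$alpha,
                      inst$prior, cfg$ridge_lambda)
    got <- c(unname(fit$beta_baselines), unname(fit$beta_conditions))
    expect_lt(max(abs(got - ref)), 1e-3)
  }
})

test_that("per-gene EM recovers effects and identifies inefficient guides", {
  d <- baseline_design("treat", n_replicates = 2)
  sf <- rep(1, 3)
  set.seed(55)
  # true beta = 1, 4 efficient guides
  mu0 <- exp(runif(4, log(100), log(1000)))
  x <- matrix(rnbinom(12, size = 1 / 0.05,
                      mu = outer(mu0, c(1, exp(1), exp(1)))), 4, 3)
  fit <- fit_gene(x, d, sf, alpha = rep(0.05, 4))
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$beta_conditions) - 1), 0.3)
  # two of four guides generated from the baseline-only model, priors 0.5
  x2 <- x
  x2[3:4, ] <- matrix(rnbinom(6, size = 1 / 0.05,
                              mu = outer(mu0[3:4], c(1, 1, 1))), 2, 3)
  fit2 <- fit_gene(x2, d, sf, alpha = rep(0.05, 4), prior_e = rep(0.5, 4))
  post <- unname(fit2$efficiency_posterior)
  expect_gt(mean(post[1:2]), mean(post[3:4]))
  # single guide with prior 1: EM collapses to the IRLS fixed point
  fit1 <- fit_gene(x[1, , drop = FALSE], d, sf, alpha = 0.05)
  m1 <- m_step_irls(x[1, , drop = FALSE], build_extended_design(d, 1),
                    e = 1, alpha = 0.05, sf = sf,
                    beta = c(log(mean(x[1, ]) + 1), 0))
  expect_equal(unname(c(fit1$beta_baselines, fit1$beta_conditions)),
               m1$beta, tolerance = 1e-4)
})

test_that("all-zero genes are flagged not-estimable instead of failing", {
  d <- baseline_design("treat", n_replicates = 1)
  fit <- fit_gene(matrix(0L, 2, 2), d, sf = c(1, 1), alpha = rep(0.1, 2),
                  prior_e = c(0.8, 0.8))
  expect_true(is.na(fit$converged))
  expect_equal(unname(fit$beta_conditions), 0)
  expect_equal(unname(fit$efficiency_posterior), c(0.8, 0.8))
})

test_that("fit_all is gene-order invariant and validates alignment", {
  sim <- simulate_counts(n_genes = 10, rng_seed = 23)
  al <- align_design(sim$design, sim$counts)
  sf <- size_factors(al$counts)
  alpha <- rep(0.1, nrow(al$counts))
  fits <- fit_all(al$counts, sim$library, al$design, sf, alpha = alpha)
  expect_length(fits, 10L)
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  # permute sgRNA rows (keeping gene blocks intact under their labels)
  perm <- rev(seq_len(nrow(al$counts)))
  fits2 <- fit_all(al$counts[perm, ], sim$library, al$design, sf,
                   alpha = setNames(alpha, rownames(al$counts))[perm])
  g <- "gene3"
  expect_equal(fits2[[g]]$beta_conditions, fits[[g]]$beta_conditions,
               tolerance = 1e-8)
  shuffled <- al$counts[, rev(colnames(al$counts))]
  expect_error(fit_all(shuffled, sim$library, al$design, sf, alpha = alpha),
               class = "crisprmle_validation_error")
})

test_that("ridge shrinkage is monotone in lambda", {
  set.seed(77)
  inst <- random_small_instance()
  betas <- vapply(c(0.01, 0.1, 1, 10), function(l) {
    f <- fit_gene(inst$x, inst$d, inst$sf, inst$alpha,
                  cfg = fit_config(ridge_lambda = l))
    abs(unname(f$beta_conditions))
  }, 0.0)
  expect_true(all(diff(betas) <= 1e-8))
})

test_that("saturated Poisson design reproduces sample means", {
  # all guides efficient, alpha 0, near-zero ridge, one condition per sample
  J <- 3
  d <- screen_design(cbind(s2 = c(0, 1, 0), s3 = c(0, 0, 1)),
                     sample_ids = paste0("s", 1:J))
  x <- matrix(c(12, 30, 7), 1, J)
  f <- fit_gene(x, d, sf = rep(1, J), alpha = 0,
                cfg = fit_config(ridge_lambda = 1e-9))
  mu_hat <- exp(unname(f$beta_baselines) +
                c(0, unname(f$beta_conditions)))
  expect_equal(mu_hat, as.vector(x), tolerance = 1e-5)
})
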
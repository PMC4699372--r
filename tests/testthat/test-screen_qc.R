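test_that("gini matches closed forms and the O(n^2) brute force", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(0, 0, 0, 1)), 0.75)
  expect_error(gini_index(c(0, 0)), class = "crisprmle_validation_error")
  set.seed(42)
  for (k in 1:20) {
    v <- rexp(50, rate = runif(1, 0.1, 5))
    expect_equal(gini_index(v), gini_brute(v), tolerance = 1e-12)
    # scale invariance and shift monotonicity
    expect_equal(gini_index(3.7 * v), gini_index(v), tolerance = 1e-12)
    expect_lt(gini_index(v + 1), gini_index(v))
  }
})

test_that("per-sample QC counts zeros and uses log-scaled Gini", {
  cm <- count_matrix(matrix(c(0, 0, 10, 10,
                              0, 0, 0, 1000,
                              5, 5, 5, 5), 4, 3,
        dimnames = list(paste0("sg", 1:4), c("a", "b", "c"))))
  qc <- sample_qc(cm)
  expect_equal(qc$zero_sgrnas, c(2L, 3L, 0L))
  expect_equal(qc$zero_fraction, c(0.5, 0.75, 0))
  # single-owner on the log scale reduces to the (n-1)/n closed form
  expect_equal(qc$gini[2], 0.75)
  expect_equal(qc$gini[3], 0)
  # all-zero sample is reported NA, not an error
  z <- count_matrix(matrix(c(0, 0, 1, 2), 2, 2,
        dimnames = list(c("x", "y"), c("s1", "s2"))))
  expect_true(is.na(sample_qc(z)$gini[1]))
})

test_that("sample correlations behave under duplication, scaling, reversal", {
  set.seed(7)
  base <- sort(rpois(100, 200), decreasing = TRUE)
  mat <- cbind(s1 = base, s2 = base, s3 = 2L * base, s4 = rev(base))
  rownames(mat) <- paste0("sg", 1:100)
  cm <- count_matrix(mat)
  r <- sample_correlations(cm, size_factors = setNames(rep(1, 4), colnames(cm)))
  expect_equal(r["s1", "s2"], 1)
  expect_gt(r["s1", "s3"], 0.999)       # log shift, affine invariance
  expect_lt(r["s1", "s4"], 0)
  expect_equal(r, t(r))
  expect_true(all(eigen(r, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  # constant sample propagates NA, not an error
  cmat <- cbind(s1 = rep(5L, 10), s2 = rpois(10, 50))
  rownames(cmat) <- paste0("sg", 1:10)
  expect_true(is.na(sample_correlations(count_matrix(cmat))["s1", "s2"]))
})

test_that("PCA separates constructed groups and zero-fills degenerate axes", {
  set.seed(11)
  a <- rpois(200, 100); b <- rpois(200, 100)
  jitter2 <- function(v) pmax(0L, v + rpois(200, 2) - rpois(200, 2))
  mat <- cbind(a1 = a, a2 = jitter2(a), b1 = b, b2 = jitter2(b))
  rownames(mat) <- paste0("sg", 1:200)
  cm <- count_matrix(mat)
  pc <- pca_projection(cm)
  within <- c(abs(pc["a1", 1] - pc["a2", 1]), abs(pc["b1", 1] - pc["b2", 1]))
  between <- abs(mean(pc[c("a1", "a2"), 1]) - mean(pc[c("b1", "b2"), 1]))
  expect_true(all(within < between))
  # identical samples: zero coordinates; 2 samples: PC3 column zero
  same <- cbind(s1 = a, s2 = a); rownames(same) <- paste0("sg", 1:200)
  expect_true(all(pca_projection(count_matrix(same)) == 0))
  two <- cbind(s1 = a, s2 = b); rownames(two) <- paste0("sg", 1:200)
  expect_true(all(pca_projection(count_matrix(two))[, 3] == 0))
})

test_that("threshold flags reproduce the documented pass/warn outcomes", {
  report <- list(
    n_sgrnas = 1000L,
    sample_qc = data.frame(
      sample_id = c("plasmid", "sel"),
      total_count = c(3e5, 3e5),
      zero_sgrnas = c(5L, 20L),
      zero_fraction = c(0.005, 0.02),
      gini = c(0.05, 0.19)),
    mapping_stats = list(
      plasmid = list(sample_id = "plasmid", total_reads = 5e5,
                     mapped_reads = 3e5, percent_mapped = 60),
      sel = list(sample_id = "sel", total_reads = 4e5,
                 mapped_reads = 3.2e5, percent_mapped = 80)),
    sequence_qc = NULL,
    correlation_matrix = matrix(c(1, 0.79, 0.79, 1), 2, 2,
      dimnames = list(c("plasmid", "sel"), c("plasmid", "sel"))))
  flags <- evaluate_thresholds(report,
    roles = c(plasmid = "plasmid", sel = "negative_selection"),
    replicate_groups = list(c("plasmid", "sel")))
  get <- function(metric, sample) {
    flags$status[flags$metric == metric & flags$sample == sample]
  }
  expect_equal(get("percent_mapped", "plasmid"), "warn")  # 60 < 65
  expect_equal(get("percent_mapped", "sel"), "pass")
  expect_equal(get("gini", "plasmid"), "pass")            # 0.05 <= 0.1
  expect_equal(get("gini", "sel"), "pass")                # 0.19 <= 0.2
  expect_equal(get("zero_sgrnas", "plasmid"), "pass")     # 0.5% <= 1%
  expect_equal(get("zero_sgrnas", "sel"), "warn")         # 2% > 1%
  expect_equal(get("mapped_reads", "plasmid"), "pass")    # 3e5 >= 300*1000
  expect_equal(get("replicate_correlation", "plasmid|sel"), "warn")  # 0.79
  expect_error(evaluate_thresholds(report, roles = c(plasmid = "mystery")),
               "unknown sample role", class = "crisprmle_validation_error")
})

test_that("rank-based depletion enrichment detects a depleted gene set", {
  set.seed(3)
  scores <- setNames(rnorm(200), paste0("g", 1:200))
  scores[1:20] <- scores[1:20] - 2          # strongly depleted set
  hit <- gene_set_depletion(scores, paste0("g", 1:20))
  expect_lt(hit$p_value, 1e-4)
  null <- gene_set_depletion(scores, paste0("g", 101:120))
  expect_gt(null$p_value, 0.01)
})

test_that("qc_report assembles metrics, clustering and flags", {
  sim <- simulate_counts(n_genes = 30, rng_seed = 5)
  rep_ <- qc_report(sim$counts, size_factors = size_factors(sim$counts),
                    roles = setNames(c("initial", rep("other", 4)),
                                     colnames(sim$counts)))
  expect_s3_class(rep_$flags, "data.frame")
  expect_setequal(rep_$cluster_order, colnames(sim$counts))
  expect_equal(dim(rep_$pca_coordinates), c(5L, 3L))
  p <- withr::local_tempfile(fileext = ".json")
  write_qc_json(rep_, p)
  expect_true(jsonlite::validate(paste(readLines(p), collapse = "\n")))
})
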
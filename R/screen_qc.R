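## ---------------------------------------------------------------------------
## Count-level and sample-level screen QC: zero-count guides, Gini index of
## the log-scaled count distribution, pairwise sample correlations, PCA,
## correlation clustering, a rank-based negative-selection enrichment, and
## pass/warn evaluation against configurable expectations.
## ---------------------------------------------------------------------------

#' Gini index of a non-negative vector
#'
#' Population (uncorrected) estimator
#' \eqn{G = \sum_{i,j} |v_i - v_j| / (2 n^2 \bar v)}, computed via the
#' sorted-vector O(n log n) identity. `G` lies in `[0, (n-1)/n]`; 0 means
#' perfectly even representation.
#'
#' @param values non-negative numeric vector with at least one positive
#'   entry.
#' @return the Gini index.
#' @export
gini_index <- function(values) {
  if (any(is.na(values)) || any(values < 0)) {
    stop_validation("gini_index requires non-negative, non-missing values")
  }
  n <- length(values)
  tot <- sum(values)
  if (n == 0L || tot == 0) {
    stop_validation("gini_index undefined for an all-zero vector")
  }
  v <- sort(values)
  sum((2 * seq_len(n) - n - 1) * v) / (n * tot)
}

#' Per-sample count-level QC
#'
#' Counts exact-zero guides per sample and computes the Gini index of the
#' log-scaled counts, `log2(count + 1)`. An all-zero sample gets `NA` Gini
#' and is flagged rather than raising an error.
#'
#' @param counts a [count_matrix()].
#' @return data.frame with columns `sample_id`, `total_count`,
#'   `zero_sgrnas`, `zero_fraction`, `gini`.
#' @export
sample_qc <- function(counts) {
  n <- nrow(counts)
  res <- lapply(colnames(counts), function(s) {
    x <- counts[, s]
    g <- if (sum(x) == 0) NA_real_ else gini_index(log2(x + 1))
    data.frame(sample_id = s, total_count = sum(x),
               zero_sgrnas = sum(x == 0L), zero_fraction = sum(x == 0L) / n,
               gini = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

log_normalized <- function(counts, sf) {
  s <- if (is.null(sf)) rep(1, ncol(counts)) else sf[colnames(counts)]
  log2(sweep(unclass(counts), 2L, s, "/") + 1)
}

#' Pairwise Pearson correlations of log normalized counts
#'
#' @param counts a [count_matrix()].
#' @param size_factors optional named size-factor vector from
#'   [size_factors()]; omitted means no depth adjustment.
#' @return symmetric correlation matrix (diagonal 1); pairs involving a
#'   constant sample are `NA`.
#' @export
sample_correlations <- function(counts, size_factors = NULL) {
  if (ncol(counts) < 2L) stop_validation("need at least two samples")
  lc <- log_normalized(counts, size_factors)
  r <- suppressWarnings(cor(lc, method = "pearson"))
  diag(r) <- 1
  r
}

#' Project samples onto the first three principal components
#'
#' PCA of the sample-by-guide matrix of centred log normalized counts.
#' Component signs are canonicalized so the largest-magnitude loading of
#' each component is positive; components beyond the matrix rank are
#' zero-filled.
#'
#' @inheritParams sample_correlations
#' @return samples x 3 coordinate matrix (columns PC1..PC3).
#' @export
pca_projection <- function(counts, size_factors = NULL) {
  if (ncol(counts) < 2L) stop_validation("need at least two samples")
  lc <- t(log_normalized(counts, size_factors))
  lc <- sweep(lc, 2L, colMeans(lc))
  out <- matrix(0, nrow = nrow(lc), ncol = 3L,
                dimnames = list(rownames(lc), paste0("PC", 1:3)))
  if (all(abs(lc) < 1e-12)) return(out)
  p <- prcomp(lc, center = FALSE, scale. = FALSE)
  k <- min(3L, ncol(p$x))
  for (j in seq_len(k)) {
    if (p$sdev[j] < 1e-12) break
    flip <- sign(p$rotation[which.max(abs(p$rotation[, j])), j])
    out[, j] <- p$x[, j] * flip
  }
  out
}

#' Sample ordering from correlation clustering
#'
#' Average-linkage hierarchical clustering on the distance `1 - r`.
#' @param correlations matrix from [sample_correlations()].
#' @return character vector of sample ids in dendrogram order.
#' @export
correlation_clustering <- function(correlations) {
  d <- 1 - correlations
  d[is.na(d)] <- 2
  hc <- hclust(as.dist(d), method = "average")
  rownames(correlations)[hc$order]
}

#' Rank-based negative-selection enrichment of a gene set
#'
#' Tests whether a gene set (for example ribosomal genes, expected to drop
#' out in a working negative-selection screen) ranks lower on a per-gene
#' selection score than the remaining genes, by a one-sided Mann-Whitney
#' test.
#'
#' @param scores named numeric vector of per-gene scores (beta scores; more
#'   negative = stronger depletion).
#' @param gene_set character vector of gene ids expected to be depleted.
#' @return list with `p_value`, `n_set`, `n_background`.
#' @export
gene_set_depletion <- function(scores, gene_set) {
  inset <- names(scores) %in% gene_set
  if (sum(inset) == 0L || sum(!inset) == 0L) {
    stop_validation("gene set and background must both be non-empty")
  }
  wt <- wilcox.test(scores[inset], scores[!inset],
                    alternative = "less", exact = FALSE)
  list(p_value = wt$p.value, n_set = sum(inset), n_background = sum(!inset))
}

#' Default QC expectations
#'
#' The defaults encode the standard screen expectations: at least 65%
#' mapped reads, at least 300 mapped reads per library guide, at most 1%
#' zero-count guides, Gini of the log-scaled counts at most 0.1 for plasmid
#' or initial-state samples and 0.2 for negative-selection samples,
#' replicate correlation at least 0.8, and median base quality at least 25.
#' All are overridable; violations produce warnings, never hard failures.
#'
#' @param ... named overrides of the defaults.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(...) {
  th <- list(min_percent_mapped = 65,
             min_reads_per_sgrna = 300,
             max_zero_fraction = 0.01,
             max_gini_initial = 0.1,
             max_gini_negative_selection = 0.2,
             min_replicate_correlation = 0.8,
             min_median_base_quality = 25)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) stop_validation("unknown thresholds: ",
                                       paste(unknown, collapse = ", "))
  th[names(dots)] <- dots
  th
}

known_roles <- c("plasmid", "initial", "negative_selection",
                 "positive_selection", "other")

#' Evaluate QC metrics against thresholds
#'
#' @param report a QC report from [qc_report()].
#' @param thresholds a [qc_thresholds()] list.
#' @param roles named character vector mapping sample id to one of
#'   `"plasmid"`, `"initial"`, `"negative_selection"`,
#'   `"positive_selection"`, `"other"`. Gini expectations apply only to the
#'   first three roles.
#' @param replicate_groups optional list of character vectors of sample ids
#'   that are replicates of each other.
#' @return data.frame with columns `metric`, `sample`, `value`,
#'   `threshold`, `status` (`"pass"`/`"warn"`).
#' @export
evaluate_thresholds <- function(report, thresholds = qc_thresholds(),
                                roles = NULL, replicate_groups = NULL) {
  if (!is.null(roles)) {
    bad <- setdiff(unique(roles), known_roles)
    if (length(bad)) stop_validation("unknown sample role(s): ",
                                     paste(bad, collapse = ", "))
  }
  rows <- list()
  add <- function(metric, sample, value, threshold, ok) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, sample = sample, value = value, threshold = threshold,
      status = if (isTRUE(ok)) "pass" else "warn", stringsAsFactors = FALSE)
  }
  n_sgrna <- report$n_sgrnas
  for (s in report$sample_qc$sample_id) {
    row <- report$sample_qc[report$sample_qc$sample_id == s, ]
    add("zero_sgrnas", s, row$zero_fraction, thresholds$max_zero_fraction,
        row$zero_fraction <= thresholds$max_zero_fraction)
    role <- if (!is.null(roles) && s %in% names(roles)) roles[[s]] else "other"
    gmax <- switch(role,
                   plasmid = thresholds$max_gini_initial,
                   initial = thresholds$max_gini_initial,
                   negative_selection = thresholds$max_gini_negative_selection,
                   NA_real_)
    if (!is.na(gmax)) {
      add("gini", s, row$gini, gmax, !is.na(row$gini) && row$gini <= gmax)
    }
    ms <- report$mapping_stats[[s]]
    if (!is.null(ms)) {
      add("percent_mapped", s, ms$percent_mapped, thresholds$min_percent_mapped,
          ms$percent_mapped >= thresholds$min_percent_mapped)
      add("mapped_reads", s, ms$mapped_reads,
          thresholds$min_reads_per_sgrna * n_sgrna,
          ms$mapped_reads >= thresholds$min_reads_per_sgrna * n_sgrna)
    }
    sq <- report$sequence_qc[[s]]
    if (!is.null(sq) && ncol(sq$base_quality_by_position) > 0L) {
      medq <- median(sq$base_quality_by_position["median", ])
      add("median_base_quality", s, medq, thresholds$min_median_base_quality,
          medq >= thresholds$min_median_base_quality)
    }
  }
  if (!is.null(replicate_groups) && !is.null(report$correlation_matrix)) {
    for (grp in replicate_groups) {
      grp <- intersect(grp, rownames(report$correlation_matrix))
      if (length(grp) < 2L) next
      prs <- utils::combn(grp, 2L)
      for (k in seq_len(ncol(prs))) {
        r <- report$correlation_matrix[prs[1, k], prs[2, k]]
        add("replicate_correlation", paste(prs[, k], collapse = "|"),
            r, thresholds$min_replicate_correlation,
            !is.na(r) && r >= thresholds$min_replicate_correlation)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(metric = character(), sample = character(),
                      value = numeric(), threshold = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assemble the full QC report for a screen
#'
#' @param counts a [count_matrix()].
#' @param size_factors optional named size factors.
#' @param mapping_stats optional named list (by sample) of mapping stats
#'   from [quantify_sample()].
#' @param sequence_qc optional named list (by sample) from [sequence_qc()].
#' @param thresholds a [qc_thresholds()] list.
#' @param roles,replicate_groups see [evaluate_thresholds()].
#' @return list of class `qc_report` with elements `n_sgrnas`, `sample_qc`,
#'   `mapping_stats`, `sequence_qc`, `correlation_matrix`,
#'   `pca_coordinates`, `cluster_order`, `flags`.
#' @export
qc_report <- function(counts, size_factors = NULL, mapping_stats = NULL,
                      sequence_qc = NULL, thresholds = qc_thresholds(),
                      roles = NULL, replicate_groups = NULL) {
  rep_ <- list(n_sgrnas = nrow(counts),
               sample_qc = sample_qc(counts),
               mapping_stats = mapping_stats,
               sequence_qc = sequence_qc)
  if (ncol(counts) >= 2L) {
    rep_$correlation_matrix <- sample_correlations(counts, size_factors)
    rep_$pca_coordinates <- pca_projection(counts, size_factors)
    rep_$cluster_order <- correlation_clustering(rep_$correlation_matrix)
  }
  rep_$flags <- evaluate_thresholds(rep_, thresholds, roles, replicate_groups)
  class(rep_) <- "qc_report"
  rep_
}

#' Serialize a QC report to JSON
#' @param report a [qc_report()].
#' @param path output path.
#' @export
write_qc_json <- function(report, path) {
  out <- unclass(report)
  out$correlation_matrix <- if (!is.null(out$correlation_matrix)) {
    as.data.frame(out$correlation_matrix)
  }
  out$pca_coordinates <- if (!is.null(out$pca_coordinates)) {
    as.data.frame(out$pca_coordinates)
  }
  out$sequence_qc <- lapply(out$sequence_qc, function(sq) {
    sq$base_quality_by_position <- as.data.frame(sq$base_quality_by_position)
    sq
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
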
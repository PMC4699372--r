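## ---------------------------------------------------------------------------
## Synthetic screens with known ground truth. Counts follow the generative
## model of the fit: NB(mu, alpha) with mu = s_j exp(beta_i0 + sum_r d_jr
## beta_gr) for efficient guides and mu = s_j exp(beta_i0) for inefficient
## ones. Baseline abundances are drawn log-uniform over about two orders of
## magnitude, mimicking real library unevenness. A FASTQ emitter provides
## the round-trip oracle for the exact-match quantifier.
## ---------------------------------------------------------------------------

random_spacers <- function(n, length = 20L) {
  repeat {
    sp <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, "")
    if (!anyDuplicated(sp)) return(sp)
  }
}

#' A baseline + condition-replicate design
#'
#' One initial-state sample (all-zero design row) followed by
#' `n_replicates` samples per condition; the standard multi-condition
#' screen layout.
#'
#' @param conditions character vector of condition names.
#' @param n_replicates replicates per condition.
#' @return a [screen_design()].
#' @export
baseline_design <- function(conditions = c("treatA", "treatB"),
                            n_replicates = 2L) {
  R <- length(conditions)
  rows <- rbind(matrix(0, 1L, R),
                do.call(rbind, lapply(seq_len(R), function(r) {
                  m <- matrix(0, n_replicates, R); m[, r] <- 1; m
                })))
  ids <- c("baseline",
           unlist(lapply(conditions, function(cn)
             paste0(cn, "_rep", seq_len(n_replicates)))))
  screen_design(rows, sample_ids = ids, condition_ids = conditions)
}

#' Simulate a pooled CRISPR screen with known truth
#'
#' @param n_genes number of genes.
#' @param sgrnas_per_gene guides per gene.
#' @param design a [screen_design()]; defaults to [baseline_design()].
#' @param effect_spec either a gene x condition matrix of true beta scores,
#'   or a function `function(n_genes, n_conditions)` returning one; the
#'   default draws each beta from {-1, 0, +1} with equal probability.
#' @param inefficient_fraction fraction of guides simulated from the
#'   baseline-only (inefficient) model.
#' @param alpha_true over-dispersion of the generated counts (0 = Poisson).
#' @param depth_spec per-sample true size factors (recycled), default all 1.
#' @param baseline_log_range range of the log-uniform baseline abundances
#'   `exp(beta_i0)`.
#' @param rng_seed integer seed; identical seeds give identical screens.
#' @return list with `counts` ([count_matrix()]), `library`
#'   ([sgrna_library()]), `design`, and `truth` (list: `beta_conditions`
#'   gene x condition matrix, `beta_baselines`, `efficient` logical,
#'   `size_factors_true`, `alpha_true`, `rng_seed`).
#' @export
simulate_counts <- function(n_genes = 100L, sgrnas_per_gene = 4L,
                            design = baseline_design(),
                            effect_spec = NULL,
                            inefficient_fraction = 0,
                            alpha_true = 0.1,
                            depth_spec = 1,
                            baseline_log_range = log(c(50, 5000)),
                            rng_seed = 1L) {
  if (inefficient_fraction < 0 || inefficient_fraction > 1) {
    stop_validation("inefficient_fraction must lie in [0, 1]")
  }
  if (alpha_true < 0) stop_validation("alpha_true must be >= 0")
  set.seed(rng_seed)
  J <- nrow(design); R <- ncol(design)
  N <- n_genes * sgrnas_per_gene
  genes <- rep(paste0("gene", seq_len(n_genes)), each = sgrnas_per_gene)
  sgrnas <- paste0(genes, "_sg", rep(seq_len(sgrnas_per_gene), n_genes))
  lib <- sgrna_library(sgrnas, genes, random_spacers(N))
  beta_g <- if (is.null(effect_spec)) {
    matrix(sample(c(-1, 0, 1), n_genes * R, replace = TRUE), n_genes, R)
  } else if (is.function(effect_spec)) {
    effect_spec(n_genes, R)
  } else {
    as.matrix(effect_spec)
  }
  dimnames(beta_g) <- list(unique(genes), colnames(design))
  beta0 <- runif(N, baseline_log_range[1], baseline_log_range[2])
  efficient <- runif(N) >= inefficient_fraction
  s_true <- rep_len(depth_spec, J)
  cond_shift <- unclass(design) %*% t(beta_g)     # J x n_genes
  gene_of <- rep(seq_len(n_genes), each = sgrnas_per_gene)
  mu <- matrix(0, N, J)
  for (j in seq_len(J)) {
    shift <- ifelse(efficient, cond_shift[j, gene_of], 0)
    mu[, j] <- s_true[j] * exp(beta0 + shift)
  }
  draw <- if (alpha_true == 0) {
    function(m) rpois(length(m), m)
  } else {
    function(m) rnbinom(length(m), size = 1 / alpha_true, mu = m)
  }
  x <- matrix(draw(mu), N, J)
  counts <- count_matrix(x, sgrna_ids = sgrnas, sample_ids = rownames(design))
  list(counts = counts, library = lib, design = design,
       truth = list(beta_conditions = beta_g,
                    beta_baselines = setNames(beta0, sgrnas),
                    efficient = setNames(efficient, sgrnas),
                    size_factors_true = setNames(s_true, rownames(design)),
                    alpha_true = alpha_true,
                    rng_seed = rng_seed))
}

#' Emit a FASTQ with exact per-guide read counts
#'
#' Writes `counts[i]` reads containing spacer `i` at the offset given by
#' the read layout (5' flank + spacer + 3' fill to `read_length`), plus an
#' optional fraction of unmappable junk reads, all with constant quality.
#' Serves as the round-trip oracle for [quantify_sample()].
#'
#' @param counts named non-negative integer vector, one entry per library
#'   guide.
#' @param library the [sgrna_library()].
#' @param path output path (`.gz` suffix gzips).
#' @param offset number of flanking bases before the spacer.
#' @param read_length total read length.
#' @param junk_fraction fraction of additional reads guaranteed not to
#'   match any spacer at any scanned offset.
#' @param quality_char constant Phred+33 quality character.
#' @param rng_seed seed for flank/junk generation.
#' @return the path, invisibly.
#' @export
simulate_fastq <- function(counts, library, path, offset = 4L,
                           read_length = 36L, junk_fraction = 0,
                           quality_char = "I", rng_seed = 1L) {
  L <- nchar(library$spacer[1])
  if (offset + L > read_length) {
    stop_validation("offset + spacer length exceeds read length")
  }
  set.seed(rng_seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  n_reads <- sum(counts)
  seqs <- character(0)
  if (n_reads > 0) {
    idx <- rep(seq_along(counts), counts)
    seqs <- vapply(idx, function(i) {
      paste0(rand_seq(offset), library$spacer[i],
             rand_seq(read_length - offset - L))
    }, "")
  }
  n_junk <- round(junk_fraction * n_reads)
  if (n_junk > 0) {
    spacer_set <- library$spacer
    junk <- character(n_junk)
    for (k in seq_len(n_junk)) {
      repeat {
        cand <- rand_seq(read_length)
        kmers <- substring(cand, 1:(read_length - L + 1), L:read_length)
        if (!any(kmers %in% spacer_set)) { junk[k] <- cand; break }
      }
    }
    seqs <- c(seqs, junk)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(seqs)) {
    qual <- strrep(quality_char, read_length)
    recs <- paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n", qual)
    writeLines(recs, con)
  }
  invisible(path)
}
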
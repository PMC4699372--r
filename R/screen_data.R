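## ---------------------------------------------------------------------------
## Domain containers: sgRNA library, count matrix, design matrix, fit config.
## All are light S3 wrappers with strict validators; readers accept both TSV
## and CSV (auto-detected), writers always emit TSV.
## ---------------------------------------------------------------------------

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("crisprmle_validation_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("crisprmle_format_error", "error")))
}

#' Construct an sgRNA library
#'
#' A library maps each guide to its target gene and spacer sequence, with an
#' optional knockout-efficiency score. Scores may be on one of two scales:
#' a raw spacer score in \[-2, 2\] (rescaled linearly to a prior probability
#' by [initial_efficiency()]) or a ready prior probability in \[0, 1\].
#'
#' @param sgrna_id character vector of unique guide identifiers.
#' @param gene_id character vector, one gene per guide.
#' @param spacer character vector of equal-length spacer sequences over
#'   A/C/G/T (case-insensitive; stored upper-case).
#' @param efficiency_score optional numeric vector (NA allowed).
#' @param efficiency_scale `"prior"` (scores already in \[0,1\]) or `"ssc"`
#'   (raw scores in \[-2,2\]).
#' @return A `data.frame` of class `sgrna_library`.
#' @export
sgrna_library <- function(sgrna_id, gene_id, spacer,
                          efficiency_score = NULL,
                          efficiency_scale = c("prior", "ssc")) {
  efficiency_scale <- match.arg(efficiency_scale)
  sgrna_id <- as.character(sgrna_id)
  gene_id <- as.character(gene_id)
  spacer <- toupper(as.character(spacer))
  if (length(sgrna_id) == 0L) stop_validation("library has no sgRNAs")
  if (anyDuplicated(sgrna_id)) {
    dup <- unique(sgrna_id[duplicated(sgrna_id)])
    stop_validation("duplicate sgRNA ids: ", paste(dup, collapse = ", "))
  }
  bad <- grep("[^ACGT]", spacer)
  if (length(bad)) {
    stop_validation("non-ACGT character in spacer of row ", bad[1],
                    " (sgRNA ", sgrna_id[bad[1]], ")")
  }
  if (length(unique(nchar(spacer))) != 1L) {
    stop_validation("spacers must all have the same length; found lengths ",
                    paste(sort(unique(nchar(spacer))), collapse = ", "))
  }
  if (anyDuplicated(spacer)) {
    dup <- unique(spacer[duplicated(spacer)])
    stop_validation("duplicate spacer sequences (exact matching cannot ",
                    "disambiguate them): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (is.null(efficiency_score)) {
    efficiency_score <- rep(NA_real_, length(sgrna_id))
  } else {
    efficiency_score <- as.numeric(efficiency_score)
    ok <- !is.na(efficiency_score)
    if (efficiency_scale == "ssc" &&
        any(efficiency_score[ok] < -2 | efficiency_score[ok] > 2)) {
      stop_validation("raw efficiency scores must lie in [-2, 2]")
    }
    if (efficiency_scale == "prior" &&
        any(efficiency_score[ok] < 0 | efficiency_score[ok] > 1)) {
      stop_validation("prior efficiency scores must lie in [0, 1]")
    }
  }
  out <- data.frame(sgrna_id = sgrna_id, gene_id = gene_id, spacer = spacer,
                    efficiency_score = efficiency_score,
                    stringsAsFactors = FALSE)
  attr(out, "efficiency_scale") <- efficiency_scale
  class(out) <- c("sgrna_library", "data.frame")
  out
}

#' Read an sgRNA library table
#'
#' Expects columns identifying the sgRNA, its gene, and the spacer sequence
#' (column names `sgRNA`/`sgrna`/`guide`, `gene`/`gene_id`, and
#' `sequence`/`spacer`, case-insensitive), plus an optional
#' `efficiency`/`efficiency_score` column. TSV or CSV, auto-detected.
#'
#' @param path path to the delimited file.
#' @inheritParams sgrna_library
#' @return An [sgrna_library()].
#' @export
read_library <- function(path, efficiency_scale = c("prior", "ssc")) {
  if (!file.exists(path)) stop_format("library file not found: ", path)
  tab <- data.table::fread(path, data.table = FALSE, colClasses = "character")
  pick <- function(cands) {
    hit <- which(tolower(names(tab)) %in% cands)
    if (length(hit)) hit[1] else NA_integer_
  }
  i_id <- pick(c("sgrna", "sgrna_id", "guide", "guide_id"))
  i_gene <- pick(c("gene", "gene_id"))
  i_seq <- pick(c("sequence", "spacer", "seq"))
  i_eff <- pick(c("efficiency", "efficiency_score", "score"))
  if (is.na(i_id) || is.na(i_gene) || is.na(i_seq)) {
    stop_format("library table must have sgRNA, gene and sequence columns; ",
                "found: ", paste(names(tab), collapse = ", "))
  }
  eff <- if (is.na(i_eff)) NULL else suppressWarnings(as.numeric(tab[[i_eff]]))
  sgrna_library(tab[[i_id]], tab[[i_gene]], tab[[i_seq]],
                efficiency_score = eff,
                efficiency_scale = match.arg(efficiency_scale))
}

#' Construct a count matrix
#'
#' @param counts non-negative integer matrix, rows = sgRNAs, cols = samples.
#' @param sgrna_ids,sample_ids optional dimension names (taken from
#'   `dimnames(counts)` when omitted).
#' @return An integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts, sgrna_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sgrna_ids) || is.null(sample_ids)) {
    stop_validation("count matrix needs sgRNA and sample ids")
  }
  if (any(is.na(counts))) stop_validation("count matrix contains missing values")
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (any(counts != round(counts))) stop_validation("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(as.character(sgrna_ids), as.character(sample_ids))
  if (anyDuplicated(rownames(counts))) stop_validation("duplicate sgRNA ids in counts")
  if (anyDuplicated(colnames(counts))) stop_validation("duplicate sample ids in counts")
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Read an sgRNA count table
#'
#' First column identifies the sgRNA, an optional second column the gene,
#' and the remaining columns one sample each. Sample order is preserved from
#' the header. TSV or CSV, auto-detected.
#'
#' @param path path to the delimited file.
#' @param library optional [sgrna_library()]; when given, a `gene` column in
#'   the table must agree with the library and rows are reordered to match.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, library = NULL) {
  if (!file.exists(path)) stop_format("count file not found: ", path)
  tab <- tryCatch(
    data.table::fread(path, data.table = FALSE, fill = FALSE),
    error = function(e) stop_format("malformed count table: ", conditionMessage(e)))
  if (ncol(tab) < 2L) stop_format("count table needs an id column and >= 1 sample")
  low <- tolower(names(tab))
  gene_col <- if (length(tab) >= 2L && low[2] %in% c("gene", "gene_id")) 2L else NA_integer_
  first_sample <- if (is.na(gene_col)) 2L else 3L
  if (first_sample > ncol(tab)) stop_format("count table has no sample columns")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, first_sample:ncol(tab), drop = FALSE])
  if (!is.numeric(vals)) stop_validation("non-numeric count entries present")
  cm <- count_matrix(vals, sgrna_ids = ids,
                     sample_ids = names(tab)[first_sample:ncol(tab)])
  if (!is.null(library)) {
    miss <- setdiff(rownames(cm), library$sgrna_id)
    if (length(miss)) {
      stop_validation("count rows absent from library: ",
                      paste(utils::head(miss, 5), collapse = ", "))
    }
    if (!is.na(gene_col)) {
      lib_gene <- library$gene_id[match(ids, library$sgrna_id)]
      bad <- which(as.character(tab[[gene_col]]) != lib_gene)
      if (length(bad)) {
        stop_validation("gene column disagrees with library for sgRNA ",
                        ids[bad[1]])
      }
    }
    cm <- cm[match(intersect(library$sgrna_id, rownames(cm)), rownames(cm)), ,
             drop = FALSE]
    class(cm) <- c("count_matrix", "matrix", "array")
  }
  cm
}

#' Write a count matrix as TSV
#'
#' @param counts a [count_matrix()].
#' @param path output path.
#' @param library optional library supplying the `gene` column.
#' @export
write_counts <- function(counts, path, library = NULL) {
  df <- data.frame(sgRNA = rownames(counts), stringsAsFactors = FALSE)
  if (!is.null(library)) {
    df$gene <- library$gene_id[match(df$sgRNA, library$sgrna_id)]
  }
  df <- cbind(df, as.data.frame(unclass(counts), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample-by-condition design matrix
#'
#' Binary indicators `d[j, r] = 1` when sample `j` is affected by condition
#' `r`. A sample with an all-zero row represents the initial state (plasmid
#' or day 0); no such row is required.
#'
#' @param entries binary matrix, rows = samples, cols = conditions.
#' @param sample_ids,condition_ids optional dimension names.
#' @return A binary matrix of class `screen_design`.
#' @export
screen_design <- function(entries, sample_ids = rownames(entries),
                          condition_ids = colnames(entries)) {
  entries <- as.matrix(entries)
  if (is.null(sample_ids)) stop_validation("design needs sample ids")
  if (is.null(condition_ids)) {
    condition_ids <- if (ncol(entries) == 0L) character() else
      paste0("condition", seq_len(ncol(entries)))
  }
  if (any(is.na(entries)) || !all(entries %in% c(0, 1))) {
    stop_validation("design entries must all be 0 or 1")
  }
  storage.mode(entries) <- "double"
  dimnames(entries) <- list(as.character(sample_ids), as.character(condition_ids))
  if (anyDuplicated(rownames(entries))) stop_validation("duplicate sample ids in design")
  class(entries) <- c("screen_design", class(entries))
  entries
}

#' Read a design matrix
#'
#' Rows are samples (first column holds the sample id), columns conditions,
#' entries 0/1. TSV or CSV, auto-detected.
#'
#' @param path path to the delimited file.
#' @return A [screen_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_format("design file not found: ", path)
  tab <- data.table::fread(path, data.table = FALSE)
  if (ncol(tab) < 2L) stop_format("design table needs sample id + >= 1 condition")
  screen_design(as.matrix(tab[, -1, drop = FALSE]),
                sample_ids = as.character(tab[[1]]),
                condition_ids = names(tab)[-1])
}

#' Align a design matrix to a count matrix by sample name
#'
#' Samples are matched by id, never by position; design samples must be a
#' subset of the count samples.
#' @param design a [screen_design()].
#' @param counts a [count_matrix()].
#' @return list with `counts` (columns restricted and ordered as the design)
#'   and `design`.
#' @export
align_design <- function(design, counts) {
  miss <- setdiff(rownames(design), colnames(counts))
  if (length(miss)) {
    stop_validation("design samples absent from counts: ",
                    paste(miss, collapse = ", "))
  }
  list(counts = counts[, rownames(design), drop = FALSE], design = design)
}

#' Fitting configuration
#'
#' @param ridge_lambda ridge penalty on the full coefficient vector (the
#'   zero-centred normal prior); must be > 0.
#' @param max_em_iters,max_irls_iters iteration caps for the outer EM loop
#'   and the inner IRLS solve.
#' @param convergence_tol max absolute change in beta declaring EM converged.
#' @param irls_tol inner IRLS convergence tolerance.
#' @param dispersion_prefit_alpha fixed over-dispersion used for the
#'   first-pass fit that feeds the mean-variance regression.
#' @param alpha_floor smallest admissible per-sgRNA over-dispersion.
#' @param n_permutations number of permutation rounds, or `"auto"` for
#'   twice the number of genes.
#' @param rng_seed integer seed driving the permutation draws.
#' @param size_factor_mode `"all"` or `"control"` (median ratios over a
#'   predefined control-guide set).
#' @param control_sgrna_ids control guide ids for `size_factor_mode =
#'   "control"`.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(ridge_lambda = 0.1,
                       max_em_iters = 100L,
                       max_irls_iters = 50L,
                       convergence_tol = 1e-4,
                       irls_tol = 1e-6,
                       dispersion_prefit_alpha = 0.01,
                       alpha_floor = 1e-6,
                       n_permutations = "auto",
                       rng_seed = 1L,
                       size_factor_mode = c("all", "control"),
                       control_sgrna_ids = NULL) {
  if (!is.numeric(ridge_lambda) || ridge_lambda <= 0) {
    stop_validation("ridge_lambda must be > 0 (the normal prior is always active)")
  }
  if (convergence_tol <= 0) stop_validation("convergence_tol must be > 0")
  if (dispersion_prefit_alpha <= 0) stop_validation("dispersion_prefit_alpha must be > 0")
  if (alpha_floor <= 0) stop_validation("alpha_floor must be > 0")
  if (!identical(n_permutations, "auto")) {
    n_permutations <- as.integer(n_permutations)
    if (is.na(n_permutations) || n_permutations < 0) {
      stop_validation("n_permutations must be a non-negative integer or \"auto\"")
    }
  }
  structure(list(ridge_lambda = ridge_lambda,
                 max_em_iters = as.integer(max_em_iters),
                 max_irls_iters = as.integer(max_irls_iters),
                 convergence_tol = convergence_tol,
                 irls_tol = irls_tol,
                 dispersion_prefit_alpha = dispersion_prefit_alpha,
                 alpha_floor = alpha_floor,
                 n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed),
                 size_factor_mode = match.arg(size_factor_mode),
                 control_sgrna_ids = control_sgrna_ids),
            class = "fit_config")
}

## -- gene result tables ------------------------------------------------------

result_columns <- c("beta", "se", "wald_z", "wald_p", "wald_fdr",
                    "perm_p", "perm_fdr")

#' Write the per-gene results table
#'
#' One row per gene; for every condition the columns
#' `<condition>.beta/.se/.wald_z/.wald_p/.wald_fdr/.perm_p/.perm_fdr`,
#' plus `converged` and `n_iterations`. Always TSV.
#'
#' @param results a `gene_results` data.frame as produced by
#'   [gene_results_table()].
#' @param path output path.
#' @export
write_gene_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-gene results table written by [write_gene_results()]
#' @param path path to the TSV.
#' @return data.frame of class `gene_results`.
#' @export
read_gene_results <- function(path) {
  if (!file.exists(path)) stop_format("results file not found: ", path)
  out <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Assemble per-gene fits into a flat results table
#'
#' @param fits list of per-gene fits from [fit_all()] (with significance
#'   columns filled in by [wald_all()] / [permutation_test()]).
#' @param fdr when TRUE, append Benjamini-Hochberg adjusted columns per
#'   condition for both Wald and permutation p values.
#' @return data.frame of class `gene_results`, one row per gene.
#' @export
gene_results_table <- function(fits, fdr = TRUE) {
  if (length(fits) == 0L) {
    out <- data.frame(gene = character(), converged = logical(),
                      n_iterations = integer())
    class(out) <- c("gene_results", "data.frame")
    return(out)
  }
  conds <- lapply(fits, function(f) names(f$beta_conditions))
  if (length(unique(conds)) != 1L) {
    stop_validation("all gene fits must share the same condition set")
  }
  conds <- conds[[1]]
  out <- data.frame(gene = vapply(fits, `[[`, "", "gene_id"),
                    converged = vapply(fits, `[[`, TRUE, "converged"),
                    n_iterations = vapply(fits, `[[`, 0L, "n_iterations"),
                    stringsAsFactors = FALSE)
  grab <- function(field, cond) {
    vapply(fits, function(f) {
      v <- f[[field]]
      if (is.null(v) || is.null(v[cond]) || !cond %in% names(v)) NA_real_
      else unname(v[cond])
    }, 0.0)
  }
  for (cond in conds) {
    out[[paste0(cond, ".beta")]] <- grab("beta_conditions", cond)
    out[[paste0(cond, ".se")]] <- grab("se", cond)
    out[[paste0(cond, ".wald_z")]] <- grab("wald_z", cond)
    wp <- grab("wald_p", cond)
    out[[paste0(cond, ".wald_p")]] <- wp
    if (fdr) out[[paste0(cond, ".wald_fdr")]] <- adjust_fdr(wp)
    pp <- grab("perm_p", cond)
    out[[paste0(cond, ".perm_p")]] <- pp
    if (fdr) {
      out[[paste0(cond, ".perm_fdr")]] <-
        if (all(is.na(pp))) pp else adjust_fdr(pp)
    }
  }
  class(out) <- c("gene_results", "data.frame")
  out
}
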
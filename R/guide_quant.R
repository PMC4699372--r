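## ---------------------------------------------------------------------------
## Exact-match sgRNA quantification from FASTQ plus sequence-level QC.
## Reads are mapped to library spacers with no mismatches tolerated; the
## spacer is located either at a fixed 5' offset or by scanning the first
## positions of the read (first exact hit wins).
## ---------------------------------------------------------------------------

#' Read a FASTQ file into its components
#'
#' Minimal strict reader for 4-line FASTQ records (plain or gzip); used by
#' the quantifier and the sequence QC. Malformed records raise a format
#' error naming the record index. Phred+33 qualities assumed.
#'
#' @param path path to FASTQ (.fastq or .fastq.gz).
#' @return list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_format("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(list(id = character(), seq = character(), qual = character()))
  if (n %% 4L != 0L) {
    stop_format("truncated FASTQ: record ", n %/% 4L + 1L, " is incomplete")
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  seps <- lines[idx + 2L]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) stop_format("malformed FASTQ: record ", bad[1],
                               " header does not start with '@'")
  bad <- which(!startsWith(seps, "+"))
  if (length(bad)) stop_format("malformed FASTQ: record ", bad[1],
                               " separator does not start with '+'")
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) stop_format("malformed FASTQ: record ", bad[1],
                               " sequence/quality length mismatch")
  list(id = sub("^@", "", heads), seq = seqs, qual = quals)
}

#' Trim specification for spacer extraction
#'
#' @param mode `"scan"` slides a window over offsets `0..max_offset` and
#'   takes the first exact library hit; `"fixed"` extracts at `offset` only.
#' @param offset fixed 5' offset (bases before the spacer) for mode
#'   `"fixed"`.
#' @param max_offset largest offset tried in scan mode.
#' @param revcomp also try the reverse complement of the read.
#' @return list of class `trim_spec`.
#' @export
trim_spec <- function(mode = c("scan", "fixed"), offset = 0L,
                      max_offset = 10L, revcomp = FALSE) {
  mode <- match.arg(mode)
  if (offset < 0 || max_offset < 0) stop_validation("offsets must be >= 0")
  structure(list(mode = mode, offset = as.integer(offset),
                 max_offset = as.integer(max_offset),
                 revcomp = isTRUE(revcomp)),
            class = "trim_spec")
}

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

match_reads <- function(reads, spacers, trim) {
  L <- nchar(spacers[1])
  n <- length(reads)
  hit <- rep(NA_integer_, n)
  offs <- if (trim$mode == "fixed") trim$offset else 0:trim$max_offset
  up <- toupper(reads)
  for (off in offs) {
    open <- which(is.na(hit) & nchar(up) >= off + L)
    if (!length(open)) break
    km <- substr(up[open], off + 1L, off + L)
    m <- match(km, spacers)
    found <- !is.na(m)
    hit[open[found]] <- m[found]
  }
  hit
}

#' Quantify one sample by exact spacer matching
#'
#' Each read increments exactly one sgRNA's count iff the L-mer extracted
#' according to the trim spec matches a library spacer exactly
#' (case-insensitive, no mismatches tolerated); all other reads are
#' unmapped. Reads shorter than offset + L are unmapped, never an error.
#'
#' @param fastq path to a FASTQ file, or a list as returned by
#'   [read_fastq()].
#' @param library an [sgrna_library()].
#' @param trim a [trim_spec()].
#' @param sample_id label used in the mapping statistics.
#' @return list with `counts` (named integer vector, one entry per library
#'   sgRNA) and `stats` (`sample_id`, `total_reads`, `mapped_reads`,
#'   `percent_mapped`).
#' @export
quantify_sample <- function(fastq, library, trim = trim_spec(),
                            sample_id = "sample") {
  if (!inherits(library, "sgrna_library") || nrow(library) == 0L) {
    stop_validation("a non-empty sgrna_library is required")
  }
  fq <- if (is.character(fastq)) read_fastq(fastq) else fastq
  spacers <- library$spacer
  hit <- match_reads(fq$seq, spacers, trim)
  if (trim$revcomp && anyNA(hit)) {
    open <- which(is.na(hit))
    hit[open] <- match_reads(reverse_complement(fq$seq[open]), spacers, trim)
  }
  counts <- tabulate(hit, nbins = length(spacers))
  names(counts) <- library$sgrna_id
  total <- length(fq$seq)
  mapped <- sum(!is.na(hit))
  list(counts = counts,
       stats = list(sample_id = sample_id,
                    total_reads = total,
                    mapped_reads = mapped,
                    percent_mapped = if (total == 0L) 0 else 100 * mapped / total))
}

#' Sequence-level QC of a FASTQ sample
#'
#' Computes the per-read GC content histogram (101 integer-percent bins),
#' per-cycle base-quality quartiles, and the histogram of per-read mean
#' qualities. Phred+33 encoding.
#'
#' @inheritParams quantify_sample
#' @return list with `sample_id`, `total_reads`, `gc_histogram` (named
#'   vector, bins "0".."100"), `base_quality_by_position` (matrix with rows
#'   q25/median/q75), and `mean_read_quality_histogram`.
#' @export
sequence_qc <- function(fastq, sample_id = "sample") {
  fq <- if (is.character(fastq)) read_fastq(fastq) else fastq
  n <- length(fq$seq)
  gc_hist <- setNames(integer(101L), 0:100)
  if (n > 0L) {
    len <- nchar(fq$seq)
    gc <- nchar(gsub("[^GCgc]", "", fq$seq))
    pct <- as.integer(round(100 * gc / pmax(len, 1L)))
    tab <- table(factor(pct, levels = 0:100))
    gc_hist[] <- as.integer(tab)
  }
  maxlen <- if (n > 0L) max(nchar(fq$qual)) else 0L
  qmat <- matrix(NA_real_, nrow = n, ncol = maxlen)
  for (k in seq_len(n)) {
    ph <- utf8ToInt(fq$qual[k]) - 33L
    qmat[k, seq_along(ph)] <- ph
  }
  if (maxlen > 0L) {
    quart <- apply(qmat, 2L, quantile, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
    rownames(quart) <- c("q25", "median", "q75")
  } else {
    quart <- matrix(numeric(), nrow = 3L, ncol = 0L,
                    dimnames = list(c("q25", "median", "q75"), NULL))
  }
  mean_q <- if (n > 0L) as.integer(round(rowMeans(qmat, na.rm = TRUE))) else integer()
  mq_hist <- table(factor(mean_q, levels = 0:93))
  list(sample_id = sample_id,
       total_reads = n,
       gc_histogram = gc_hist,
       base_quality_by_position = quart,
       mean_read_quality_histogram = setNames(as.integer(mq_hist), 0:93))
}
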
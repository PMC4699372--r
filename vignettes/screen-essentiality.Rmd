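---
title: "Modelling gene essentiality in pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene essentiality in pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprmle)
```

## The problem

A pooled CRISPR screen infects a cell population with a library of single
guide RNAs (sgRNAs), each directing Cas9 to knock out one gene, and reads
out the abundance of every guide by sequencing at one or more later time
points and conditions. Genes whose loss impairs growth are *negatively
selected* (their guides are depleted); genes whose loss confers an
advantage under a treatment are *positively selected*. Two features make
the inference harder than a two-sample comparison:

* screens routinely span several conditions — time points, drug arms,
  cell lines — that should be modelled jointly, and
* guides differ in *knockout efficiency*: an sgRNA that fails to disrupt
  its target behaves like a neutral passenger and dilutes the gene-level
  signal.

`crisprmle` addresses both with a negative binomial generalized linear
model whose per-gene selection coefficients are estimated jointly across
all samples while each guide's efficiency is treated as a latent mixture
indicator.

## The count model

The read count \(x_{ij}\) of sgRNA \(i\) in sample \(j\) is modelled as
negative binomial,

\[ x_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
   \operatorname{Var}(x_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2 , \]

with \(\alpha_i \to 0\) recovering the Poisson. The mean factorizes into a
per-sample sequencing-depth size factor \(s_j\) and a relative abundance
\(q_{ij}\): \(\mu_{ij} = s_j q_{ij}\). Size factors are median-ratio
estimates: \(s_j = \operatorname{median}_i \, x_{ij} / \hat x_i\), where
\(\hat x_i\) is the geometric mean of guide \(i\) across samples; only
guides nonzero in every sample define the reference, and the median can
instead be restricted to a user-supplied negative-control guide set when
most of the library is expected to respond.

For an *efficient* guide (\(\pi_i = 1\)),

\[ \log q_{ij} = \beta_{i0} + \sum_r d_{jr} \beta_{gr}, \]

where \(\beta_{i0}\) is the guide's baseline (initial-state) abundance,
\(d_{jr} \in \{0,1\}\) is the sample-by-condition design matrix, and
\(\beta_{gr}\) — the *beta score* — measures selection of gene \(g\) under
condition \(r\) (positive = enrichment, negative = depletion, on the
natural-log scale of relative abundance). For an *inefficient* guide
(\(\pi_i = 0\)) the condition terms vanish and \(\log q_{ij} =
\beta_{i0}\). A sample with an all-zero design row represents the plasmid
or day-0 state; no such row is required by the fit.

Stacking the \(N\) guides of a gene over the \(J\) samples
(guide-fastest order) gives \(\log \vec q = D' \vec\beta\) with the binary
*extended design matrix* \(D'\): \(N\) baseline indicator columns followed
by the \(R\) condition columns repeated per sample
(`build_extended_design()`).

## Estimation: EM with an IRLS-ridge M step

The per-gene parameters maximize the observed-data mixture likelihood

\[ \sum_i \log\!\big[ p_i \textstyle\prod_j P(x_{ij}\mid \pi_i=1) +
   (1-p_i) \prod_j P(x_{ij}\mid \pi_i=0) \big]
   \; - \; \tfrac{\lambda}{2}\lVert\vec\beta\rVert^2 , \]

where \(p_i\) is the prior efficiency of guide \(i\) and the quadratic
penalty is a zero-centred normal prior on all coefficients that keeps
\(\vec\beta\) finite when counts are degenerate or guides are mostly
inefficient.

* **Priors.** A raw spacer-design score in \([-2, 2]\) is rescaled
  linearly to \((v+2)/4\); scores already in \([0,1]\) pass through;
  guides without scores get \(p_i = 1\) (`initial_efficiency()`).
* **E step.** The posterior efficiency \(e_i\) combines the prior with the
  product over samples of the two component likelihoods, computed in log
  space; degenerate priors 0 and 1 are pinned.
* **M step.** Iteratively reweighted ridge regression:
  \(\vec\beta \leftarrow (D'^{T} W D' + \lambda I)^{-1} D'^{T} W \vec z\)
  with working weights \(w = e_i / (1/\mu + \alpha_i)\) and working
  residuals \(z = h + e_i (x - \mu)/\mu\), where \(h = D'\vec\beta\) and
  \(\mu = s\, e^{h}\).

Iteration alternates E and M steps from a null start (baselines at the log
mean normalized count plus one pseudo-count, condition coefficients at 0)
until the largest coefficient change falls below `convergence_tol`.

### Numerical choices

* **Monotonicity safeguard.** The published update weighs the working
  residuals by \(e_i\) inside both \(W\) and \(z\); with fractional
  efficiencies its fixed point is not exactly the stationary point of the
  mixture Q-function, so a raw step can occasionally overshoot. After each
  M step the driver evaluates the penalized observed-data log-likelihood
  and contracts the step toward the previous iterate (step-halving) if it
  would decrease; the safeguard only shortens a step, never redirects it,
  and is inactive in the common all-priors-1 case. The per-iteration
  likelihood trace is stored on every fit and asserted non-decreasing in
  the test suite.
* **Overflow guard.** The linear predictor is clipped at \(\pm 30\), so
  degenerate inputs (all-zero guides under large design blocks) cannot
  overflow `exp`.
* **Defaults.** \(\lambda = 0.1\) over the full coefficient block (the
  penalty is weak relative to typical per-condition information, which is
  two orders of magnitude larger, but guarantees a solvable system even
  under collinear designs); EM tolerance \(10^{-4}\) with at most 100
  iterations; inner IRLS tolerance \(10^{-6}\) with at most 50 iterations.
  These were chosen so that on small instances the EM/IRLS solution agrees
  with a generic numerical maximizer of the same objective to
  \(|\Delta\beta| < 10^{-3}\) (asserted in the tests).
* **Degenerate input.** Genes with all-zero counts are flagged
  not-estimable (beta 0, posterior = prior) rather than fitted; all-zero
  samples propagate flagged `NA` QC metrics rather than errors; duplicate
  spacers and rank-deficient designs are rejected or ridge-stabilized with
  a warning.

## Over-dispersion

\(\alpha_i\) is estimated from a mean–variance trend. A first pass of the
full EM fit is run with \(\alpha\) fixed at a small value
(`dispersion_prefit_alpha`, default 0.01). Squared residuals
\((x_{ij} - \hat\mu_{ij})^2\) are averaged per guide across samples and
rescaled by the per-gene residual degrees of freedom
\(NJ/(NJ - N - R)\); averaging before taking logs matters, because
regressing the log of single-observation squared residuals systematically
underestimates the trend intercept (the log of a \(\chi^2_1\)-scale
variable is biased low by more than unity), which we verified drives the
recovered \(\alpha\) several-fold below truth. The trend
\(\hat\sigma^2 = \hat\mu + k \hat\mu^{\,b}\) is then learned by ordinary
least squares of \(\log(\hat\sigma_i^2 - \hat\mu_i)\) on
\(\log \hat\mu_i\) over guides with excess variance, and each guide gets
\(\alpha_i = k \hat\mu_i^{\,b-2}\), floored at `alpha_floor`
(\(10^{-6}\); the NB requires \(\alpha > 0\)). If fewer than two guides
show excess variance the pre-fit value is used for all guides with a
warning. The recovered medians remain mildly conservative
(biased toward smaller \(\alpha\)) and are monotone in the simulated
truth, which the test suite checks over \(\alpha \in \{0.01, 0.1, 0.5\}\).

## Significance

* **Wald.** Standard errors come from the sandwich covariance of the
  ridge estimate, \((D'^TWD' + \lambda I)^{-1} (D'^TWD') (D'^TWD' +
  \lambda I)^{-1}\), at the converged weights; \(z = \beta/\mathrm{SE}\)
  is referred to the standard normal, two-sided. On fully null synthetic
  screens with few replicates the rejection rate at \(p < 0.05\) runs
  slightly above nominal (about 0.07 in our validation runs) — the usual
  finite-sample behaviour of Wald tests with a handful of residual degrees
  of freedom — and this is asserted to stay within \([0.02, 0.08]\).
* **Permutation.** Pseudo-genes of each observed gene size are assembled
  by drawing guides uniformly without replacement across the whole
  library and refitting their condition coefficients, with each guide's
  observed dispersion and efficiency posterior held fixed (a documented
  approximation that avoids nested EM). The default number of rounds is
  twice the number of genes; null draws are shared across genes of the
  same size, which keeps the cost linear. P-values are two-sided on
  \(|\beta|\) with the add-one rule, so they live in \([1/(B+1), 1]\) and
  are never zero.
* **FDR.** Benjamini–Hochberg per condition, separately for Wald and
  permutation p-values.

## Quality control

Per sample: total/mapped reads and percent mapped (exact spacer matching,
no mismatches tolerated), the number and fraction of zero-count guides,
and the Gini index of \(\log_2(\mathrm{count}+1)\) — the population
estimator computed by the sorted-vector identity, equal to the
\(O(n^2)\) pairwise mean difference normalized by twice the mean. The
pseudo-count keeps zeros defined; "log-scaled" is taken as base 2.
Across samples: Pearson correlations of log normalized counts, PCA of the
centred sample profiles (top three components, signs canonicalized so the
largest-magnitude loading is positive), and average-linkage clustering on
\(1 - r\). Default expectations — at least 65% mapped, 300 mapped reads
per guide, at most 1% zero guides, Gini at most 0.1 for plasmid/initial
and 0.2 for negative-selection samples, replicate correlation at least
0.8, median base quality at least 25 — produce `pass`/`warn` flags only;
the pipeline never hard-fails on a QC expectation, since they encode
experience, not theorems. Gene-level negative-selection QC is a one-sided
rank (Mann–Whitney) test of a user-supplied gene set (for example
ribosomal subunits) against the fitted beta ranking, performed locally
rather than through an external enrichment service.

Guide quantification extracts the spacer either at a fixed 5' offset or by
scanning offsets 0–10 (first exact hit wins; vector and adapter lengths
vary between preps, and for a library of unique spacers at most one offset
can match). Reverse-complement matching is off by default. Phred+33 only.

## The simulator

`simulate_counts()` draws screens from exactly the generative model above:
log-uniform baseline abundances spanning roughly two orders of magnitude
(mimicking real library unevenness, and making size-factor and Gini tests
non-degenerate), Bernoulli efficiency indicators, NB (or Poisson) counts,
and a default design of one initial-state sample plus replicated condition
arms. `simulate_fastq()` emits reads with the spacer at a known offset
plus an optional fraction of reads guaranteed unmappable, providing an
exact round-trip oracle for the quantifier. What the simulator does *not*
emulate: sequencing error inside reads, PCR duplicates, batch effects,
copy-number artefacts, or guide–guide correlation beyond shared gene
effects — so passing tests demonstrate correctness of the estimator under
its own model, not robustness to every failure mode of real screens.

## Validation problem sizes

The test suite and the acceptance script exercise: 20 random one-gene
instances (at most 2 guides, 3 samples) against a generic
penalized-likelihood maximizer; 200-gene screens (4 guides per gene, one
baseline plus two conditions in duplicate, \(\alpha = 0.1\)) for beta
recovery, sign agreement and mixture identification; a 2000-gene fully
null screen for Wald and permutation calibration; and 100-gene screens at
three dispersion levels for the mean–variance fit. All randomness is
seeded; every reported quantity is recomputed at run time.

## Known limitations

* Dispersion estimates are moderately biased toward zero at small
  replicate numbers (see above); only the trend substitution is applied,
  with no empirical-Bayes shrinkage of individual guides toward it.
* The permutation null holds dispersions and efficiency posteriors fixed
  at observed values.
* Gene fits are independent: no information sharing across genes beyond
  the global size factors and mean–variance trend.
* Exact matching only — a sequencing error inside the spacer loses the
  read; there is no mismatch-tolerant mode, UMI handling, or paired-end
  logic.
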
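---
title: "Quantifying newly transcribed RNA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying newly transcribed RNA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newrna)
library(dplyr)
```

## The measurement

Metabolic labeling with 4-thiouridine (4sU) marks RNA transcribed during a
short labeling window: incorporated 4sU is chemically alkylated so that
reverse transcription misreads the position, and the sequenced read shows a
T-to-C mismatch at that site (A-to-G in reference coordinates for genes on
the minus strand). A read covering `n` convertible positions therefore
carries a conversion count `k` whose distribution depends on whether the
read derives from RNA made during the window ("new") or before it
("pre-existing"). Everything in this package is built on that single
read-level observation.

Two probabilities govern the counts: the error probability `p_e` (a
convertible position misread for technical reasons) and the conversion
probability `p_c` (the additional rate induced by 4sU on labeled
molecules). A pre-existing read converts each position with probability
`p_e`; a labeled read with probability `p_c + p_e`. The probability of
observing `k` conversions over `n` positions for a gene whose read
population is a fraction `pi` new is the two-component binomial mixture

    P(k) = pi * B(k; n, p_c + p_e) + (1 - pi) * B(k; n, p_e)

implemented in `mixture_pmf()` (log-space throughout).

## Rate estimation

`p_e` is estimated without 4sU-negative controls from mismatch classes that
the labeling chemistry cannot produce: the specific conversion class
observed on the opposite strand (`estimate_pe_opposite_strand()`, the
mini-bulk default), or the mean of the complementary C-to-T and G-to-A
rates (`estimate_pe_complementary()`, the single-cell default). `p_c` and
the global new fraction come from an expectation-maximization fit of the
mixture across all reads of a treatment (`em_rates()`), with `p_e` held
fixed. Fixing `p_e` rather than re-estimating it inside EM avoids the
identifiability cliff at low labeled fractions, where the two components
are nearly indistinguishable. Initialization uses the pooled conversion
rate among reads with at least two mismatches - at realistic error rates a
two-mismatch read is almost surely labeled - floored at ten times `p_e`.
Convergence is declared when the log-likelihood moves by less than 1e-8
(at most 1000 iterations), and the log-likelihood is asserted to be
non-decreasing at every step.

## The per-gene posterior

For each gene in each sample the new fraction `pi` gets a Bayesian
treatment with a uniform prior: the joint log-likelihood sums the log
mixture mass over the gene's reads, and the posterior is explored by two
interchangeable backends.

* `posterior_grid()` evaluates the likelihood on a uniform grid of 10,001
  points, normalizes by log-sum-exp, and reports the posterior mean and
  the equal-tailed 95% interval from interpolated quantiles. It is exact
  up to grid resolution (1e-4) and completely deterministic, so it serves
  as the package's oracle.
* `posterior_mcmc()` is a one-chain random-walk Metropolis sampler on the
  logit of `pi` with the Jacobian correction, so the uniform prior is
  respected without boundary trickery. Defaults are 1000 burn-in and 5000
  kept iterations with the initial value at 0.1. The proposal scale adapts
  toward a 0.44 acceptance rate during burn-in only; after burn-in the
  kernel is fixed, so the kept draws form a valid chain and a fixed seed
  reproduces it exactly. We chose this sampler over Hamiltonian schemes
  because the target is one-dimensional and cheap to evaluate; the
  contract any sampler must meet here is agreement with the grid oracle
  (posterior means within 0.01, interval endpoints within 0.02, enforced
  by tests), and convergence is checked by that agreement rather than by
  multi-chain diagnostics.

`estimate_pi()` wraps either backend with the two data rules applied
upstream of inference: genes with more than 5,000 reads are downsampled to
5,000 (uniformly, without replacement, seeded from the sample and gene
identifiers so partial reruns reproduce the same subsample), and genes
with no converted read at all short-circuit to exactly zero - the
posterior would otherwise report a small positive mean for every silent
gene. Reads with `n = 0` carry no information and are dropped.

The equal-tailed (2.5/97.5 percentile) interval is our reading of "95%
credible interval"; a highest-density interval would differ near the
boundaries but the equal-tailed form is what the interval-width QC rule
expects. Under prior-matched simulation the 95% interval covers the truth
at the nominal rate - this calibration, and the fact that estimation error
shrinks with read depth, are asserted in the test suite.

## Molecule-level calls in single cells

Single-cell data assigns each UMI-stitched molecule individually: the
null says the molecule's conversions arose from errors
(`rate = p_e`), the alternative that it is labeled (`rate = p_c`). Because
the likelihood ratio is monotone in `k`, the α = 0.05 test is a threshold
rule, and `critical_k()` returns the smallest rejection count with null
tail mass at most α. The non-randomized form is deliberately conservative
(size at most α, typically well below it for small `p_e`); molecules with
no convertible positions are called old and bookkept separately. Note the
molecule test uses `p_c` as the alternative rate while the mixture model
uses `p_c + p_e` for labeled reads; each convention is applied in its own
context and the difference is negligible whenever `p_e` is an order of
magnitude below `p_c`.

## Sample QC

Mini-bulk conditions pass when total reads are at least 200,000, at least
45% of mapped reads are exonic, and the signal-to-noise ratio `p_c / p_e`
strictly exceeds 10 (`qc_minibulk()`; a zero error rate counts as infinite
SNR and passes). Dose-panel samples additionally require one million
reads and a median credible-interval width below 0.4, and a drug is
dropped outright when fewer than three of its samples survive
(`qc_mcf7()`). These thresholds are the tool's defaults and are all
configurable.

## Differential expression at three replicates

With three treated replicates per compound, per-gene variance estimates
are unreliable, so `de_compound()` compares each compound against ten
DMSO controls drawn without replacement (seeded per compound) using a
Welch t-test whose group variances are floored at a mean-variance trend
fitted across genes (`variance_floor()`, lowess with span 0.3 by default;
a linear fit is available). The trend is fitted on the drawn control
pool's per-gene means and variances - the controls are the only group
with enough replicates to estimate dispersion - and applied to each group
at its own mean. Flooring can only increase a variance, hence only shrink
|t|: the adjustment is uniformly conservative, which the tests assert
gene-wise. Welch rather than pooled variance is used because the 3-vs-10
design is strongly unbalanced.

Multiple testing uses the two-stage linear step-up procedure
(`two_stage_fdr()`): a first Benjamini-Hochberg pass at level
α/(1+α) estimates the number of true nulls m0, and the second pass
rescales by m0/m. The returned q-values are BH-adjusted p-values times
m0/m with m0 floored at one, so a lone test is returned unchanged.

Expression enters the tests as `log2(CPM + 1)` of the new-RNA layer
(`normalize_log2_cpm()`, `new_expression()`); the new layer is the total
abundance times the posterior-mean fraction.

## Dose-response fits and response clustering

For the dose panel (five doses spanning 1 nM to 10 uM plus untreated
controls) `dose_response_fit()` regresses log2 new expression on log10
dose. The functional form is linear in log dose - the simplest monotone
summary with a slope in interpretable units (log2 change per decade).
Untreated controls enter at a pseudo-dose one decade below the lowest
treated dose (0.1 nM); placing them further away would inflate slopes,
omitting them would discard the only anchor at baseline. Genes need at
least three distinct dose levels. `cluster_responses()` correlates drugs
by their slope vectors (Pearson), clusters with average linkage on
`1 - r`, and cuts at `r = 0.33`.

## Promoter enrichment and GO tests

`promoter_windows()` spans 1000 bp upstream to 100 bp downstream of the
TSS in transcription direction; internally all intervals are 0-based
half-open (BED convention), giving complete windows of width 1100, and
every reader documents its conversion at the boundary (GTF positions are
1-based inclusive). `factor_enrichment()` compares peak occurrence between
up- and down-regulated genes with a two-sided Fisher exact test per
factor (two-sided meaning the sum of all table probabilities no larger
than the observed table's - the convention of `stats::fisher.test`,
verified in tests against direct hypergeometric enumeration), fold change
as the ratio of peak-containing fractions, and BH adjustment at 5%.
`gene_regions()` adds gene-body (TSS+100 to TES) and downstream (TES to
TES+1kb) windows; those two region bounds are this package's own
definitions and are configurable.

GO overrepresentation (`go_overrepresentation()`) uses a chi-square test
without continuity correction when all four expected counts exceed ten
and Fisher's exact test otherwise, with two-stage FDR across terms.
Because expression strength confounds gene-set membership,
`expression_matched_background()` builds a background matched on average
expression: genes are ranked, and each input gene takes the nearest
unused non-input neighbor, alternating up and down the ranking, giving up
beyond a rank distance of 100; if more than 10% of the input is
unmatchable the matching aborts with a warning and returns the partial
map. Obsolete ontology terms are excluded from the universe. Where only
"Benjamini-Hochberg" applies (factor enrichment, bursting comparisons)
plain BH is used; the two-stage variant is bound to the DE, dose and GO
families. An exploratory FDR of 50% is sometimes appropriate for GO
scans; the level is a parameter with default 5%.

## Bursting kinetics from labeled counts

Transcription is modeled by the telegraph process: a promoter switches
between OFF and ON at rates `k_on` and `k_off` (per hour), synthesizes at
`k_syn` only while ON, and transcripts decay at `k_deg`. Burst frequency
is `1/(1/k_on + 1/k_off)` and burst size `k_syn / k_off`. Labeled counts
over a window of length `t` start at zero, with the promoter at its
stationary occupancy - the physically sensible state at labeling onset.
`k_off` is held at 100/h (few datasets carry enough cells to identify
it; the off-rate is also the less variable parameter across genes), and
`k_deg` is a dataset-level constant derived from the median per-cell new
fraction via `derive_kdeg()` (about 0.065/h at one hour of labeling).

The likelihood is the transient solution of the chemical master equation
on the truncated state space (promoter state x labeled count), computed
by sparse matrix exponential (`labeled_count_distribution()`). The
truncation is reflecting, grown until the boundary holds less than 1e-8
probability; the returned distribution must sum to one within 1e-6.
Tests verify it against an independent exact stochastic simulation
(`simulate_telegraph_labeled()`, an event-driven Gillespie implementation
in C++) at total-variation distance below 0.02 on 100,000 cells.

`fit_kinetics()` maximizes this likelihood over `(k_on, k_syn)` with
bounded quasi-Newton on log rates, initialized by moments
(`moment_kinetics()`): `k_syn` from the exact mean relation
`E[count] = k_syn * occupancy * (1 - exp(-k_deg t)) / k_deg`, and `k_on`
by inverting the zero fraction through
`P(0) ~ (1 - occupancy) * exp(-k_on t)`, the probability that the
promoter never fires during the window - the dominant source of zeros in
the bursty regime. These fast estimates also drive
`compare_kinetics()`: the between-condition difference in moment-based
burst frequency and size is compared against a permutation null (1000
permutations by default, add-one p-values so no p is zero), BH-corrected
at 5% separately per metric, and significant genes are re-fit by full
maximum likelihood and kept only when the direction of change survives
refinement.

## What the generators emulate - and what they do not

`simulate_reads()` draws from exactly the mixture the estimators assume,
with convertible-position counts uniform on [20, 200] by default - the
plausible T-content range of 100-150 bp reads; the distribution is
configurable. `simulate_minibulk_screen()` produces log2-scale expression
with gene means uniform on [2, 12] and a monotone decreasing noise trend
`sd(mu) = 0.1 + 1.5 exp(-mu/3)`, emulating the inflated relative noise of
lowly expressed genes; effects are clean location shifts in treated
replicates. `simulate_telegraph_labeled()` is an exact simulation of the
model itself. All generators take an explicit seed, never touch the
caller's RNG state, and are byte-reproducible.

Passing tests on these fixtures therefore demonstrates internal
correctness - estimators recover the parameters of their own generative
model at the stated accuracy - not robustness to what real libraries add:
position-specific error profiles, UMI collapsing artifacts, SNPs
masquerading as conversions (a VCF blacklist hook exists but no masking
is on by default), dropout, or cell-to-cell labeling-efficiency
variation. Alignment, UMI stitching and transcript assignment are
upstream of this package and consumed as inputs.

## Numerical choices and problem sizes

All likelihoods collapse reads to unique `(n, k)` pairs with weights, so
cost scales with distinct pairs, not reads. The grid backend uses 10,001
points; quantiles are interpolated, which leaves a half-grid-step
(5e-5) discretization offset on interval endpoints. EM tolerance is 1e-8
on the log-likelihood. The master-equation truncation starts at three
times the predicted mean plus a margin and doubles until the tail
criterion holds. Simulation-backed test sizes (100,000 cells for
distribution agreement, 2,000 cells for kinetic recovery, 20 seeds for
error-control checks, 500 genes for interval calibration) were chosen so
each check's Monte-Carlo error sits well inside the tolerance it
enforces.

## A worked example

```{r example}
reads <- simulate_reads(n_genes = 6, reads_per_gene = 800,
                        pi = c(0, 0.05, 0.1, 0.3, 0.6, 0.9),
                        p_c = 0.02, p_e = 0.001, seed = 1)
fit <- em_rates(reads, p_e = 0.001)
glance(fit)

est <- estimate_pi(reads, fit)
dplyr::inner_join(est, dplyr::distinct(reads, gene_id, true_pi), by = "gene_id") |>
  dplyr::select(gene_id, true_pi, pi_mean, ci_low, ci_high, zero_shortcut)
```

The zero-fraction gene is reported as exactly zero through the
zero-conversion shortcut; every other interval should cover its truth at
the nominal rate.

## Known limitations

The posterior treats reads as independent given `pi`, ignoring shared
molecules across reads (mini-bulk data should be molecule-collapsed
upstream). The moment-based `k_on` estimator saturates when zeros are
absent (capped at 1e4/h), so constitutive-like genes get an
uninformative fast estimate and rely on the ML step. The permutation
comparison inherits the usual resolution floor `1/(n_perm + 1)` on
p-values. GO testing treats terms independently - no ontology-graph
propagation is performed, by design.
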
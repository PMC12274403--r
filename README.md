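# newrna

Quantification of newly transcribed RNA from 4sU metabolic-labeling
sequencing, for transcriptomics groups mapping the *direct* transcriptional
effects of chemical or genetic perturbations. Standard RNA-seq after a short
treatment is dominated by pre-existing transcripts; labeling new RNA with
4-thiouridine (4sU) and reading out the induced T→C conversions (A→G for
minus-strand genes) lets the newly made fraction be measured per gene within
minutes-to-hours of a perturbation, in single cells or in "mini-bulk" wells
of 10–100k cells.

## The model

A read covering *n* convertible positions carries *k* specific mismatches.
With error probability *p*<sub>e</sub> and 4sU conversion probability
*p*<sub>c</sub>, reads from a gene whose read population is a fraction
π<sub>g</sub> new follow the two-component binomial mixture

> P(k) = π<sub>g</sub>·B(k; n, p<sub>c</sub>+p<sub>e</sub>) +
> (1−π<sub>g</sub>)·B(k; n, p<sub>e</sub>)

The package provides:

* **Conversion counting** from aligned reads (SAM/BAM with MD tags and a
  per-read gene tag): `count_conversions()`, with a 12-type mismatch profile
  stratified by gene strand.
* **Rate estimation**: strand-based error-rate estimators
  (`estimate_pe_opposite_strand()`, `estimate_pe_complementary()`) and an
  EM fit of the mixture for *p*<sub>c</sub> (`em_rates()`).
* **Per-gene new-RNA fractions**: Bayesian posterior for π<sub>g</sub>
  under a uniform prior, via a deterministic grid oracle
  (`posterior_grid()`) or a seeded Monte-Carlo sampler
  (`posterior_mcmc()`), wrapped by `estimate_pi()` with the 5,000-read
  downsampling cap and the zero-conversion shortcut.
* **Single-cell molecule calls**: the binomial likelihood-ratio new/old
  test at α = 0.05 (`critical_k()`, `classify_molecules()`,
  `cell_new_fraction()`).
* **Sample QC** with the published thresholds (`qc_minibulk()`,
  `qc_mcf7()`).
* **Differential expression** for 3-replicate mini-bulk designs:
  variance-floored Welch t-tests against sampled DMSO controls
  (`de_compound()`, `variance_floor()`) with two-stage FDR
  (`two_stage_fdr()`); dose-response slopes and drug clustering
  (`dose_response_fit()`, `cluster_responses()`).
* **Promoter / region enrichment** of ChIP peaks (`promoter_windows()`,
  `peak_in_promoter()`, `factor_enrichment()`, `gene_regions()`) and GO
  overrepresentation with expression-matched backgrounds
  (`expression_matched_background()`, `go_overrepresentation()`).
* **Bursting kinetics**: telegraph-model inference from labeled
  single-cell counts with fixed k<sub>off</sub> = 100/h
  (`fit_kinetics()`, `labeled_count_distribution()`, `burst_metrics()`,
  `compare_kinetics()`).
* **Synthetic data** for all of the above (`simulate_reads()`,
  `simulate_minibulk_screen()`, `simulate_telegraph_labeled()`), so the
  whole pipeline is testable without sequencing data.

All user-facing functions take and return tibbles and compose with the
pipe; fitted objects have `tidy()`/`glance()` methods and result types have
`autoplot()` methods.

## Worked example

```r
library(newrna)

reads <- simulate_reads(n_genes = 4, reads_per_gene = 1000,
                        pi = c(0, 0.05, 0.3, 0.8),
                        p_c = 0.02, p_e = 0.001, seed = 1)
fit <- em_rates(reads, p_e = 0.001)
glance(fit)
#>      p_c   p_e   snr pi_bar logLik iterations converged unidentifiable n_reads
#> 1 0.0207 0.001  20.7  0.281 -4353.         23 TRUE      FALSE             4000

estimate_pi(reads, fit) |>
  dplyr::inner_join(dplyr::distinct(reads, gene_id, true_pi), by = "gene_id") |>
  dplyr::select(gene_id, true_pi, pi_mean, ci_low, ci_high)
#>   gene_id true_pi pi_mean ci_low  ci_high
#> 1 g0001      0    0.00167 0       0.00621
#> 2 g0002      0.05 0.0419  0.0262  0.0602
#> 3 g0003      0.3  0.313   0.278   0.349
#> 4 g0004      0.8  0.771   0.735   0.806
```

The EM recovers the generative conversion probability (0.0207 vs 0.02) and
a sample-level new fraction near the mean of the four gene fractions; the
per-gene posteriors bracket their true values, and the silent gene is
reported as (essentially) zero. Molecule-level classification of the same
reads at the fitted rates calls 788 of 4,000 molecules new — the labeled
molecules that carry at least the critical number of conversions for their
length.

A command-line wrapper for the common batch steps (simulate, count, rates,
pi, classify, qc) is installed at `exec/newrna` inside the package
directory.

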
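---
title: "Models and methods behind tlabelbench"
author: "tlabelbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tlabelbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlabelbench)
```

## The measurement problem

4-thiouridine (4sU) metabolic labeling marks RNA synthesized during a
labeling pulse: incorporated 4sU is chemically converted so that it reads
as C at reference-T positions in sequencing. In single-cell RNA-seq each
captured molecule is identified by a (cell barcode, UMI, gene) triple, so
the number of T-to-C substitutions among the covered reference-T positions
of one UMI is the per-molecule labeling signal. Three complications stand
between that signal and biology:

1. **Incomplete conversion.** A new molecule converts each of its `n`
   reference-T positions independently with probability `p_c` well below
   one, so many new molecules show zero conversions.
2. **Background.** Old (pre-existing) molecules still show conversions at
   a background rate `p_e` (sequencing/RT errors, intrinsic mismatches).
3. **Genomic variants.** A germline SNP at a reference-T position reads
   as C in every molecule of every cell and, left in place, masquerades
   as ubiquitous labeling for its gene.

The package implements the full computational chain for this measurement
— simulation with ground truth, per-UMI consensus counting with quality
and SNP filtering, a binomial mixture separating new from old molecules,
maternal/zygotic gene classification, half-life estimation, and
benchmark-level complexity summaries — as plain R functions with a thin
CLI (`tlabelbench_main()`).

## The binomial mixture model

For a UMI with `n` covered reference-T positions and `k` T-to-C consensus
conversions,

$$ k \mid \text{old} \sim \mathrm{Binom}(n, p_e), \qquad
   k \mid \text{new} \sim \mathrm{Binom}(n, p_c), $$

and with `pi` the fraction of new molecules the marginal likelihood is
`(1 - pi) Binom(k; n, p_e) + pi Binom(k; n, p_c)`. The background `p_e`
is estimated first, on an unconverted control after SNP masking, as the
pooled binomial MLE (`estimate_background()`), and then held fixed.
`fit_binomial_mixture()` maximizes the likelihood over `(pi, p_c)` by EM
and is the package's model-fitting core: it returns a classed object
(`binmix`) with `print`, `summary`, `coef`, `logLik`, `predict`
(posterior probability of being new), `simulate` and `plot` methods.

Numerical choices:

* E-steps run on the log scale; the likelihood is evaluated on collapsed
  unique `(k, n)` pairs, so cost is independent of the UMI count beyond
  the collapse.
* Initialisation is `pi = 0.5`, `p_c = max(2 p_e, 0.02)`; two additional
  starting values for `p_c` (0.1, 0.3) are tried and the best final
  log-likelihood wins. Multi-start is cheap on collapsed data and guards
  against local maxima on small samples.
* Convergence: relative log-likelihood change below `1e-8` or 1000
  iterations; the trace is recorded and is non-decreasing within a start.
* UMIs with `n = 0` carry no information about conversion; they are
  excluded from the likelihood and carried as unlabeled downstream.
  (The standalone `posterior_new()` formula returns `pi` at `n = 0`;
  `estimate_layers()` deliberately assigns such molecules 0 instead.)
* If every `k` is zero, the likelihood is maximized at the boundary
  `pi = 0` for any `p_c >= p_e`, and that exact boundary MLE is returned
  directly. If the fitted rate fails to exceed `p_e`, the fit is flagged
  non-identifiable and `pi` is reported missing rather than guessed.

`estimate_layers()` runs the estimation strategy used for gene-level
analyses: `p_c` is a chemistry property, so it is fitted once on all
pooled UMIs; `pi` is then re-fitted per gene (default; per cell is
available) with both rates fixed, and each UMI's posterior probability of
being new is summed into a real-valued estimated-new matrix.
Genes with fewer than `min_gene_umis` (default 10) informative UMIs get
missing estimated layers — per-gene-per-cell fits would be hopelessly
sparse, which is why `pi` pools cells within a gene. Estimated-new plus
estimated-old equals total by construction; no rounding is applied.

### Posterior calibration caveat

At the headline parameters (`p_e = 0.002`, `p_c = 0.08`, T content
~ Poisson(15)) the posterior band around 0.5 is essentially empty: a UMI
with `k = 0` has posterior below `pi`, and `k = 1` reaches 0.5 only at
`n ≈ 41`, which Poisson(15) essentially never produces. Calibration of
mid-range posteriors is therefore exercised in tests at a higher
background (`p_e = 0.02`), where single-conversion UMIs are genuinely
ambiguous.

## Quantification: consensus, quality, SNPs, rates

Reads sharing a (barcode, UMI, gene) triple derive from one molecule.
`umi_consensus()` takes a per-position plurality vote across those reads;
ties fall to the reference base, which is conservative — a tied position
is never counted as a conversion — and a tie between two non-reference
bases falls to the alphabetically first. Content (coverage) is the union
of positions seen in any read; whether the union or intersection is the
right convention is not externally fixed, and union was chosen because
dropping positions seen in only some reads would discard real coverage.

`quality_filter()` runs before consensus: a mismatch with Phred quality
at or below 27 (strictly `> 27` survives) is reverted to the reference,
so it still contributes content but not conversions — the filter
deliberately applies to substitution evidence, not to coverage.

`detect_snps()` masks positions whose conversion fraction across control
UMIs reaches the threshold (default 0.5) **and** that are covered by at
least `min_coverage = 3` control UMIs. The coverage floor matters: at
background rates, a position covered once with a chance conversion has
fraction 1 and would be masked, and because such maskings select exactly
the positions carrying conversions they bias the background estimate
downward. `apply_snp_mask()` removes masked positions entirely (content
and conversions): a genomic variant position is uninformative, not
reference-matching. Note that the measured conversion rate after quality
filtering sits slightly below the molecular rate (a fraction of genuine
conversions is reverted); analyses that need the molecular background
rate should measure it on data whose qualities clear the cutoff.

`cell_rates()` reports, per cell, each of the 12 substitution-type rates
as summed conversions over summed content of the reference base — a base
with zero content yields `NA`, never 0 — plus the labeled-UMI fraction
(UMIs with at least one T-to-C conversion), detected genes, UMIs, and
mitochondrial fraction. `cell_qc()` provides the two benchmark QC
regimes: `zf4` (mito < 10%, 400–4000 genes) and `embryo` (mito < 10%,
at least 800 UMIs and 400 genes).

## Maternal/zygotic classification and kinetics

The new-to-total RNA ratio (NTR) of a gene is its labeled UMIs over total
UMIs, summed over cells; genes under 10 total UMIs are dropped. Retained
genes are split into ten equal bins by NTR (ties broken by gene id so
binning is reproducible; when the division is uneven the lower bins take
the extra gene). A gene is zygotic (Z) if NTR strictly exceeds the
zygotic threshold (0.70 by default, swept over 0.70/0.75/0.80/0.85),
maternal (M) if NTR is strictly below 0.05, and maternal-zygotic (MZ)
otherwise — the band between the two thresholds is interpreted as MZ,
which the classification scheme implies without stating. NTR defaults to
raw labeled counts, with a switch to the model-estimated new counts;
the estimated variant is the right choice when the induced conversion
rate is low enough that raw detection misses a substantial share of new
molecules (at `p_c = 0.08` and 15 T positions, a new molecule is detected
with probability ~0.71, so a fully zygotic gene's raw NTR sits near the
0.70 cutoff while its estimated NTR sits near 1).

Gene-set overlaps are scored with Fisher's exact test: the sample odds
ratio `(a d)/(b c)` (`Inf` when `b c = 0`), and the conventional
two-sided exact p-value summing hypergeometric point probabilities no
larger than the observed one.

RNA half-life assumes first-order decay at steady state: with labeled
fraction `n/r` after a pulse of `t` hours,
`h = ln(2) t / (-ln(1 - n/r))`. A never-labeled gene yields `Inf`
(serialized as an empty field with a flag, never as a large number), a
fully labeled one yields 0. `rank_stability()` flags the shortest and
longest 10% of finite half-lives, ties again broken by gene id.

## Library-complexity prediction

Chemical conversion costs library complexity, so methods are compared at
a fixed sequencing depth: detected genes per cell are fitted against
aligned reads per cell with LOESS (span 0.75, degree 2, plain least
squares, no robustness iterations — `stats::loess` with
`surface = "direct"`, which also makes the fit exactly reproduce global
quadratics at interior points), and UMIs per cell with ordinary least
squares (`stats::lm`). Predictions are evaluated at 10,000 reads for the
cell-line regime and 4,000 for the embryo regime, with an explicit flag
when the query depth lies outside the observed range (extrapolation is
allowed — real benchmarks predict at depths beyond some cells — but
flagged). Cell filters before fitting default to > 100 detected genes
(nGene fit) and > 400 UMIs (nUMI fit). Fold-differences between method
means are rounded half-up to two decimals, matching how such ratios are
conventionally reported.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates read-level observations from a generative
model with known truth:

* **Expression**: per-gene relative weights are log-normal; per-cell
  totals are log-normal (default median 300 UMIs for read-level runs);
  per-gene-per-cell counts are negative binomial (Gamma-Poisson,
  dispersion 0.5) — the standard overdispersion model for scRNA-seq.
* **Kinetics**: per-gene half-lives are log-normal (median 4 h, sdlog
  0.75, a realistic spread for vertebrate mRNA); the fraction of new
  molecules is `1 - 2^(-t/h)` with a 4 h default pulse, and each UMI is
  new with that gene-level probability. In embryo mode the half-life
  distribution is replaced by per-class fraction-new ranges
  (M: 0–0.02, MZ: 0.10–0.60, Z: 0.95–1.00) with a 12/78/10 M/MZ/Z mix,
  the typical composition of genes with detectable new RNA at zygotic
  genome activation.
* **Chemistry**: new molecules convert T positions at `p_c` (presets
  named after the benchmarked methods store each method's observed mean
  rate as an approximate default — an observed raw rate conflates
  `p_c`, `pi` and `p_e`, so these are starting points, not constants);
  old molecules convert at `p_e` (default 0.002).
* **Structure**: each UMI's covered-position count per reference base is
  Poisson(15) independently for A/C/G/T (per-UMI T content distributions
  are not externally documented, so Poisson is a configurable stand-in;
  the other bases are given the same mean). The transcript is a fixed
  4-periodic base layout (`pos mod 4` → A,C,G,T), so a position's
  reference base is consistent across reads and UMIs without modeling
  sequence. Reads per UMI are `1 + Poisson(1)`; per-read qualities put a
  configurable fraction (default 5%) at or below the Phred-27 cutoff.
* **Noise and variants**: sequencing/RT error hits each non-modeled
  substitution type at `seq_error_rate` per covered position, applied on
  the molecule path and inherited by all reads of the UMI. T-to-C is
  reserved to the conversion channel, so the dataset-level T-to-C rate
  has the exact expectation `pi p_c + (1 - pi) p_e`; symmetrically,
  configuring `p_c = p_e = seq_error_rate` makes all 12 substitution
  channels statistically identical, the regime the control-behaviour
  tests use. SNP positions show the alternate base (C at reference-T) in
  every overlapping read.
* **Determinism**: random streams split hierarchically (dataset → cell),
  so identical seed and configuration give byte-identical output and
  adding cells never perturbs earlier cells' draws.

`simulate_umi_dataset()` is the molecule-level fast path: it emits
per-UMI `(k, n)` directly from the same model (the consensus of
error-free full-coverage reads recovers the molecule exactly) and is
used where large UMI counts matter and the read-level machinery is not
under study. Problem sizes in the tests and the acceptance script were
chosen at desk scale: 50,000-UMI mixture recoveries, a 1000-gene/~100k
UMI embryo run, 20-seed read-level control simulations of ~2,000 UMIs
each.

The simulator deliberately does **not** model nucleotide sequences,
alignment artifacts, doublets, ambient RNA, cell-type cluster structure,
per-read coverage variation along the transcript, or FASTQ/BAM output.
Consequences for interpreting green tests: recovery results show the
estimators are correct under the stated generative model, not that real
libraries satisfy that model — in particular real per-UMI T content is
coverage- and 3'-bias-dependent, real sequencing error is per-read (the
consensus machinery is validated against a brute-force oracle on
constructed read tables instead), and real background rates vary by
position and cell.

## Known limitations

* The per-gene `pi` fit pools cells; genuinely per-cell fraction-new
  (e.g. cell-cycle-dependent synthesis) is only available through the
  sparser `per_cell_pi` strategy.
* Multi-rate chemistries, per-position conversion profiles, and
  spliced/unspliced layers are out of scope.
* Steady-state cell selection for half-life estimation is an input mask;
  the package does not cluster cells.
* The half-life formula assumes steady state over the pulse; genes
  induced or repressed during labeling violate it, and the simulator
  does not model such genes.
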
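# tlabelbench

Benchmarking toolkit for **4sU metabolic-labeling single-cell RNA-seq**,
written for people who develop or compare nucleotide-conversion
chemistries and platforms (SLAM-seq / TimeLapse-seq style protocols on
Drop-seq, 10x Genomics or MGI C4) and for people who analyze the
resulting data.

In these experiments, newly transcribed RNA incorporates 4-thiouridine,
which chemical conversion makes read as C at reference-T positions. Per
molecule (UMI), the number of T-to-C substitutions `k` among `n` covered
reference-T positions separates new from pre-existing RNA — but
conversion is incomplete, old molecules show background conversions, and
germline SNPs fake ubiquitous labeling. The package implements the whole
computational chain as tested R functions, driven by a synthetic-data
generator with known ground truth so no sequencing download is needed:

* **simulate** — read-level or UMI-level datasets with known per-gene
  fraction-new, half-lives, conversion rates, SNPs, qualities and depth
  structure (`sim_config()`, `simulate_dataset()`,
  `simulate_umi_dataset()`, `make_embryo_truth()`);
* **quantify** — Phred-quality filtering, per-UMI consensus across
  reads, control-based SNP masking, per-cell substitution-rate profiles
  and cell QC (`quality_filter()`, `umi_consensus()`, `detect_snps()`,
  `apply_snp_mask()`, `cell_rates()`, `cell_qc()`);
* **mixture** — the statistical core: a two-component binomial mixture

  ```
  k ~ (1 - pi) * Binom(n, p_e)  +  pi * Binom(n, p_c)
  ```

  fitted by EM with the background rate `p_e` fixed from a control,
  returning a classed fit with `print`/`summary`/`coef`/`logLik`/
  `predict`/`simulate`/`plot` methods (`fit_binomial_mixture()`), plus
  gene x cell estimated-new/old count layers built from per-UMI
  posteriors (`estimate_layers()`);
* **mzclass** — maternal / maternal-zygotic / zygotic gene
  classification from new-to-total RNA ratios (NTR), decile binning,
  threshold sweeps and Fisher-exact gene-set overlaps;
* **kinetics** — RNA half-lives from labeled fractions,
  `h = ln(2) t / (-ln(1 - n/r))`, with stability ranking;
* **complexity_report** — depth-normalized library-complexity
  prediction (LOESS span 0.75 degree 2 for genes, OLS for UMIs),
  per-method summary tables, fold-differences and pseudobulk
  concordance.

A thin CLI covers the pipeline stages
(`simulate | quantify | estimate | classify | halflife | report`):

```sh
Rscript inst/cli/tlabelbench.R simulate --config cfg.yaml --seed 1 --outdir run1
Rscript inst/cli/tlabelbench.R quantify --reads run1/reads.tsv.gz \
    --control ctl/reads.tsv.gz --min-phred 27 --snp-threshold 0.5 --outdir run1
```

Given a fixed seed and configuration, every stage's output is
byte-identical across runs.

## Worked example

Simulate a 30-cell dataset with the mCPBA/TFEA (pH 7.4) chemistry preset
(induced conversion probability 0.084) and a 0.002 background, then fit
the mixture and build estimated layers:

```r
library(tlabelbench)

cfg <- sim_config(n_cells = 30, n_genes = 300,
                  chemistry = "mcpba_tfea_ph7.4", p_e = 0.002,
                  depth_meanlog = log(800), seed = 1)
sim <- simulate_umi_dataset(cfg)

fit <- fit_binomial_mixture(sim$umis, p_e = cfg$p_e)
fit
#> Binomial mixture of new and old molecules (EM fit)
#>   25305 UMIs (25305 informative, n > 0)
#>   fraction new pi = 0.5215, induced p_c = 0.08472 (background p_e = 0.00200, fixed)
#>   log-likelihood -27934.0861 after 27 iterations (converged)
```

The fitted fraction-new (0.5215) recovers the simulation truth (0.5260,
from `mean(sim$umis$new)`), and the fitted induced rate 0.0847 recovers
the preset 0.084. Per-gene estimation and classification:

```r
layers <- estimate_layers(sim$umis, p_e = cfg$p_e)
rec <- bin_genes(compute_ntr(layers$estimated_new, layers$total,
                             min_umis = 10))
threshold_sweep(rec)
#>   z_threshold M  MZ  Z
#> 1        0.70 3 214 67
#> 2        0.75 3 229 52
#> 3        0.80 3 242 39
#> 4        0.85 3 251 30
```

Each row counts maternal (NTR < 0.05), zygotic (NTR above the sweep
threshold) and intermediate genes; the zygotic count shrinks as the
threshold tightens. Half-life ranks are recovered from the same layers:

```r
hl <- gene_half_lives(layers$estimated_new, layers$total, t = 4)
# Spearman rho between estimated and true half-life,
# genes with >= 50 UMIs: 0.957
```

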
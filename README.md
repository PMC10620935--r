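# midpipe

Analysis of ¹³C stable-isotope tracing metabolomics measured by LC-MS.

When cells are fed a labeled substrate such as U-¹³C-glucose, each
metabolite appears in the mass spectrum as a ladder of *isotopologues*
m+0, m+1, …, m+n (n = number of carbon atoms), and the vector of their
relative fractions — the *mass isotopomer distribution* (MID) — reports
which pathways carried the labeled carbon. Getting from integrated peak
areas to defensible biology requires a chain of corrections that are easy
to get subtly wrong. `midpipe` implements that chain as tested, reusable
functions, for researchers analyzing isotopologue tables exported by
peak-integration software (rows `met_m0`, `met_m1`, …; one column per
sample):

1. **Quantification thresholds** per batch from blank measurements:
   T = blank mean + 2 SD; values below the blank mean are zeroed and
   values in between are mapped linearly onto [0, T).
2. **Natural-abundance correction** (high-resolution mode, carbon only):
   solves M·y = x by non-negative least squares, where
   M[i,j] = C(n−j, i−j) pⁱ⁻ʲ (1−p)ⁿ⁻ⁱ is the binomial convolution of
   natural ¹³C (p = 0.0107) over the unlabeled carbons.
3. **Normalization** between isotopologues (by mean metabolite abundance)
   and between samples (size factors: isotopologue sums weighted by
   inverse squared coefficients of variation, anchored to geometric
   mean 1).
4. **Summaries**: metabolite abundances, MIDs, fractional labeling
   Σ k·π_k / n, and diagnostic ratios (m+3/m+2 anaplerosis marker,
   metabolite pair ratios).
5. **Differential statistics**: log-abundances in a linear mixed model
   (celltype fixed, donor random, REML via lme4) and isotopologue
   fractions in a beta mixed regression with logit link and donor random
   intercept, fit by maximum likelihood with adaptive Gauss–Hermite
   quadrature (authored in this package); Wald contrasts with
   Benjamini–Hochberg adjustment per contrast family.
6. **Synthetic data**: a ground-truthed generator
   (`simulate_experiment()`, presets via `scenario_presets()`) that runs
   the assumed forward model — donor effects, binomial label convolution,
   log-normal LC-MS noise, blank baseline, LOD censoring — so every stage
   is verifiable without instrument data.

See `vignettes/midpipe.Rmd` for the models, parameter meanings, and
design decisions.

## Worked example

Simulate a T cell differentiation experiment (4 subsets × 3 donors × 2
replicates, 16-metabolite glycolysis/TCA panel, naive cells carrying an
enolase block) and run the full pipeline:

```r
library(midpipe)
res <- run_pipeline(list(seed = 42, outdir = "demo",
                         simulate = list(preset = "differentiation")))
print(res$normalized)
#> iso_table [normalized]: 84 isotopologue rows (16 metabolites) x 24 samples
#>   missing cells: 402
```

The 402 missing cells are analyte-group blocks removed by the 1/3
sub-threshold cleaning rule — mostly isotopologues that are genuinely
absent in naive (TN) cells. Differential abundance results (one TSV per
contrast is also written to `demo/`):

```r
ab <- res$diff$abundance
head(ab[order(ab$p), c("analyte", "contrast", "estimate", "se", "p", "padj")], 5)
#>    analyte contrast estimate     se        p     padj
#> 8      lac  TSCM-TN    1.101 0.1055 1.69e-25 2.71e-24
#> 2      g6p  TSCM-TN    0.644 0.0907 1.19e-12 9.49e-12
#> 9      ala  TSCM-TN    0.727 0.1079 1.61e-11 8.58e-11
#> 41     ala  TEM-TCM    0.520 0.1079 1.43e-06 2.29e-05
#> 4     dhap  TSCM-TN    0.659 0.1443 4.95e-06 1.98e-05
```

Estimates are natural-log fold changes: lactate rises ~3-fold
(e^1.10 ≈ 3.0) upon activation, hexose falls, succinate is higher in TN —
the effects the simulation planted, recovered with donor-paired mixed
models. Fractional labeling per subset shows the enolase block (no
labeled carbon below 3-phosphoglycerate in TN) and graded TCA labeling in
the activated subsets:

```r
fl <- fractional_labeling(res$mid)
#        lac   cit   mal
# TN   0.002 0.001 0.002
# TSCM 0.746 0.166 0.178
# TCM  0.749 0.214 0.188
# TEM  0.724 0.131 0.121
```

The anaplerosis marker — the mean m+3/m+2 ratio of TCA-cycle
intermediates in activated cells, contrasting pyruvate-carboxylase entry
(m+3) with acetyl-CoA entry (m+2):

```r
act <- grepl("^(TSCM|TCM|TEM)_", colnames(res$mid$values))
sub <- res$mid; sub$values <- sub$values[, act]
isotopologue_ratio(sub, c("cit","akg","suc","fum","mal"), k_num = 3, k_den = 2)$mean
#> [1] 0.153
```

i.e. anaplerotic flux roughly 15% of oxidative entry (the generating
value is 0.15).

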
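# netmature

Neuron maturation is the process by which newborn neurons acquire their
mature morphology, electrophysiology and molecular identity. `netmature`
identifies **functional modules in a protein–protein interaction (PPI)
network whose expression discriminates mature from immature neurons**, and
trains **neuron maturity index (NMI)** models that score how mature a single
neuron (or purified neuron sample) looks from its transcriptome alone. It is
aimed at computational biologists working with two-class single-cell or
purified-bulk RNA-seq (FPKM-scale) together with an undirected PPI network.

## Method

1. **Expression alteration score.** Per gene,
   `s = log2(f) · (−log10 p)`, where `f` is the (pseudocount-protected)
   fold change of mean FPKM between mature and immature cells and `p` the
   two-group one-way ANOVA p-value. Positive `s` means higher expression in
   mature neurons.
2. **Insulated heat diffusion.** Scores are smoothed over the network with
   `ŝ = F s`, `F = β (I − (1 − β) W)⁻¹`, where `W = A D⁻¹` is the
   column-stochastic walk matrix and `β` (default 0.55) the insulating
   parameter. Each edge is then weighted by smoothed-score concordance,
   `a_ij = 1 − |ŝ_i − ŝ_j| / (2 max(|ŝ_i|, |ŝ_j|)) ∈ [0, 1]`.
3. **Topological overlap and modules.**
   `TOM_ij = (a_ij + Σ_u a_iu a_uj) / (min(k_i, k_j) + 1 − a_ij)` with
   weighted connectivity `k_i = Σ_u a_iu`; average-linkage clustering of
   `d = 1 − TOM` followed by an adaptive dendrogram cut with a minimal
   module size (default 20).
4. **Direction calls.** Per module, a two-sided Wilcoxon signed-rank test
   of member scores against zero; modules at BH-adjusted `p < 0.05` are
   *discriminating*: mature-high (median `s > 0`) or immature-high.
   Opposite-direction module pairs that collapse into one module when edge
   weights are removed are reported as *adversarial pairs*.
5. **Maturity indices.** Per module, an L1-penalized logistic regression on
   standardized expression, `ê = (log10(e+1) − mean_log) / sd_log`, with the
   penalty chosen by 10-fold cross-validation maximizing ROC AUC (mNMI).
   Integrated indices are AUC-weighted means with `w_i = AUC_i − 0.5`:
   **tNMI** (all modules), **dNMI** (discriminating), **NFI** (mature-high).

A synthetic-data generator (planted-partition network plus negative-binomial
expression with module-level directional effects and dropout) provides
ground truth for every stage.

## Worked example

```r
library(netmature)

dat    <- simulate_dataset(synthetic_truth(seed = 1))  # network + expression
scores <- score_expression(dat$expression)
det    <- detect_modules(dat$network, scores, beta = 0.55, min_size = 20)
det$partition
#> nm_partition: 5 modules over 300 genes (12 unassigned)
#>   sizes: min 25, median 36, max 39

calls <- call_direction(det$partition, scores, alpha = 0.05)
calls[, c("module", "n_genes", "median_s", "q_bh", "direction")]
#>   module n_genes      median_s         q_bh     direction
#> 1      1      36  19.435999775 9.204086e-09   mature-high
#> 2      2      35  21.215743361 7.275958e-10   mature-high
#> 3      3      39  -8.427767793 8.306718e-10 immature-high
#> 4      4      36 -12.341491071 1.455192e-10 immature-high
#> 5      5      25   0.006174237 2.751843e-01          none
```

Four modules are called with the directions that were planted (two
mature-high, two immature-high; the fifth, a planted null module, stays
uncalled). Training maturity models on a stratified 75/25 split and scoring
the held-out cells:

```r
sp     <- split_train_test(dat$expression, seed = 1)
bundle <- train_nmi(sp$train, det$partition, calls, seed = 1)
pred   <- predict_nmi(bundle, sp$test)
evaluate_auc(pred$dNMI, sp$test$labels)
#> [1] 1
```

A dNMI of 1 on held-out cells means the discriminating-module index
separates mature from immature neurons perfectly at these effect sizes.
`partition_ari(det$partition, planted_partition(dat$truth))` returns 0.97,
the chance-corrected agreement with the planted modules.

The same pipeline is available from the shell via
`Rscript inst/cli/netmature.R <simulate|score|smooth|modules|stats|train-nmi|predict-nmi|run-all>`,
and `run_all()` drives it from a single YAML config with a provenance
manifest.

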
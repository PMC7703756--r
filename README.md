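# mlcoex — metric learning for co-expression-based gene function prediction

Co-expression across many RNA-seq samples is a classic signal for
guilt-by-association (GBA) function prediction: genes acting in the same
biological process tend to respond together. But in a heterogeneous public
compendium only a *subset* of samples is informative for any one Gene
Ontology (GO) term, and the all-sample Pearson correlation (PCC) dilutes the
signal with irrelevant conditions. `mlcoex` is for computational biologists
who want term-aware co-expression: it learns, per GO term, a non-negative
weight for every expression sample so that the weighted co-expression of
co-annotated gene pairs separates maximally from that of mixed pairs — and
the weights of uninformative samples are driven to exactly zero.

## The model

Expression rows are centred and L2-normalised,
`x̃_i = (x_i − x̄_i) / ‖x_i − x̄_i‖`, so the plain inner product equals the
PCC. The learned similarity is the weighted inner product

    S_w(x_i, x_j) = Σ_m w_m x̃_im x̃_jm ,   w_m ≥ 0.

For a term with label vector `y`, gene pairs are split into positive–positive
(both annotated), positive–negative (exactly one), and negative–negative
pairs (ignored: their co-expression carries no information about this term).
Writing `μ_pp(w), σ²_pp(w)` for the mean and variance of `S_w` over p–p
pairs (and likewise p–n), class separability is the Welch two-sample
t-statistic

    t(w) = (μ_pp − μ_pn) / sqrt(σ²_pp/N_pp + σ²_pn/N_pn),

and the weights solve

    min_w  −α·t(w) + (1−α)·Σ_m w_m ,   s.t. w_m ≥ 0,

by box-constrained L-BFGS from an all-ones start. Because `t` is invariant
to rescaling of `w`, the L1 term both fixes the scale and switches
uninformative samples off. Sufficient statistics (per-sample first moments
and sample×sample second-moment matrices) make `t` and its analytic gradient
computable without enumerating gene pairs. The learned similarity feeds a
k-NN GBA classifier (score = fraction of annotated genes among the k nearest
training genes), evaluated by term-centric ROC AUC under nested
cross-validation, against PCC, per-term-k PCC, Mutual Rank (MR), a global
(non-term-specific) variant, and an MR/MLC hybrid.

## Worked example

```r
library(mlcoex)

## synthetic compendium: 3 terms, each with 50 positive genes correlated
## (rho = 0.7) over its own disjoint block of 100 of 600 samples
ds <- simulate_dataset(simulation_spec(seed = 101))
Xs <- center_scale(ds$expression)

m <- fit_mlc(Xs, ds$labels[, 1], alpha = 0.99)
print(m)
#> mlc_model 'term': alpha = 0.99, t = 621.6, objective = -615.2, 305/600 samples selected

weight_recovery_report(m, ds, 1)
#> weight_recovery_report (1): mean w in-block 0.1668, out-of-block 0.01618
#>   rank-sum p = 1.06e-14; selected 305 samples; enrichment OR = 2.117259 (p = 0.000974)

res <- nested_cv(Xs, ds$labels, methods = c("pcc", "mlc"),
                 alpha_grid = c(0.9, 0.99), seed = 2, maxit = 100)
cv_summary(res)
#>   method  mean_auc       se_auc weighted_auc
#> 1    pcc 1.0000000 0.0000000000          NaN
#> 2    mlc 0.9996484 0.0001758263          NaN
```

The fitted weights concentrate on the ground-truth informative block (ten
times larger on average, with a strongly significant rank-sum test and
Fisher enrichment of selected samples), which is the method's interpretable
output: *which experiments matter for this term*. At this simulation scale
the 100-sample block is strong enough that plain PCC also saturates the AUC;
the weighted metric matches it while using roughly half the samples. Real
compendia (thousands of heterogeneous samples) are where the dilution is
severe and sample selection pays off in AUC as well.

For real data, the same pipeline runs from files:

```r
cfg <- list(counts = "counts.tsv", metadata = "samples.tsv",
            gaf = "annotations.gaf", obo = "go-basic.obo",
            methods = c("pcc", "mr", "mlc", "hybrid"),
            batch_method = "standardize",
            seed = 1, out_dir = "out")
run_pipeline(cfg)   # writes predictions.tsv, evaluation.tsv, summary.json, manifest.tsv
```

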
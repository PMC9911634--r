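# ithsig

Intra-tumor heterogeneity (ITH)-aware immune signatures from multi-region
bulk RNA-seq.

Hepatocellular carcinoma tumors split into *inflamed* (immune-infiltrated,
checkpoint-blockade-responsive) and *non-inflamed* classes, but the call
is usually made from a single biopsy — and different regions of the same
tumor can express immune genes very differently. A signature built from
heterogeneously expressed genes can therefore classify two regions of one
tumor into opposite classes. `ithsig` builds signatures from genes that
are immune-related **and** clonally expressed within tumors, so the
classification is robust to biopsy location, and quantifies that
robustness directly.

The pipeline:

1. **IHS** — a per-gene *integrated heterogeneity score* over a
   multi-region cohort, the rank-average of two components: the
   within-tumor variance share `h1 = 1 − ICC` from the one-way
   random-effects ANOVA estimator

   ICC = (MSB − MSW) / (MSB + (k₀ − 1)·MSW),  k₀ = (N − Σnₚ²/N)/(P − 1),

   and the *subclonal event frequency* E, the fraction of tumors whose
   within-tumor range of the gene exceeds τ (default 1 log2 unit). Low
   IHS = clonal, representative expression.
2. **Immune module** — non-negative matrix factorization (multiplicative
   updates, Frobenius loss, seeded restarts); the factor whose sample
   weights best correlate with an immune marker score (CD8A, GZMB, PRF1,
   IFNG, ...) is the immune module; its top-loading genes (default 500)
   are the immune gene set.
3. **Signature** — immune genes ∩ lowest-IHS genes (default 2000);
   samples scored by mean cohort z-score; inflamed = top tertile of the
   score (quantile 2/3, linear interpolation).
4. **Concordance** — a multi-region tumor is *concordant* if all its
   regions get one class; the cohort discordance rate comes with a
   patient-level bootstrap CI, and paired signature comparisons with a
   sign test.

A synthetic multi-region cohort generator with planted clonal-immune,
subclonal-immune and background genes (known per-patient infiltration
levels θ) makes the whole pipeline testable end to end without patient
data.

## Worked example

```r
library(ithsig)

sim <- simulate_cohort(seed = 1)          # 20 patients x 4 regions, 3000 genes
ihs <- compute_ihs(sim$expr, sim$annot)   # per-gene heterogeneity
fit <- nmf_factorize(sim$expr[ihs$gene_id, ], k = 2, restarts = 5, seed = 1)
cats <- sim$truth$gene_category
sel <- select_immune_factor(fit, marker_score(sim$expr,
         names(cats)[cats == "clonal_immune"][1:20]))
sig <- derive_signature(top_loading_genes(fit, sel$factor_index, 300),
                        select_low_ihs(ihs, 1000))
truth_recovery_report(sim$truth, sig)
#> # A tibble: 1 × 4
#>   precision recall n_signature n_clonal_immune
#>       <dbl>  <dbl>       <int>           <int>
#> 1     0.957  0.747         117             150

classes <- classify_tertile(score_samples(sim$expr, sig))
evaluate_concordance(classes, sim$annot, seed = 2)
#> <concordance_report> 4/20 patients discordant (rate 0.2, 95% CI [0.05, 0.351])
```

The derived 117-gene signature is 95.7% planted clonal-immune genes and
recovers 74.7% of them; classifying every region of every tumor with it
leaves 4 of 20 tumors discordant. (The synthetic cohorts carry exactly
one coherent program above the baseline, hence `k = 2`; see the methods
vignette for rank choice on real cohorts, where the default is 6.)

File-based workflows use `read_expression_tsv()` / `read_annotation_tsv()` /
`read_gmt()`, a YAML config (`read_config_yaml()`), the one-call
`run_pipeline()`, or the thin CLI in `inst/scripts/ith-sig.R`
(`simulate` and `run` subcommands). Result objects have `tidy()`,
`glance()` and `autoplot()` methods.

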
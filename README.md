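# metasig

Discovery and validation of prognostic gene-expression signatures in
small, imbalanced tumour cohorts — the setting of early (UICC I–III)
colorectal carcinoma, where 33 non-recurrent patients stand against 12
who later developed metachronous metastases, and no single gene survives
a univariate differential-expression screen. The package implements the
full multivariate analysis chain as tested R code:

1. **Bootstrap recursive-SVM selection** (`bootstrap_select()`): 100
   stratified bootstrap steps; each runs a recursive elimination ladder
   that retrains a linear SVM and keeps the probes with the largest
   class-separation contribution *f*<sub>j</sub> = *w*<sub>j</sub>
   (*m*<sub>j</sub><sup>+</sup> − *m*<sub>j</sub><sup>−</sup>), saving
   the best 42 probes per step; probes selected at least once form the
   candidate signature.
2. **Hypergeometric gene-set over-representation**
   (`hypergeom_enrich()`), plus `reconstruct_table_params()`, which
   recovers the unprinted selection size *n* and universe size *N* of a
   published enrichment table by integer grid search over the printed
   Expected and Odds-ratio columns.
3. **The below-median count classifier** (`signature_classifier()`):
   a sample is called metastatic when at least ⌈θ⌉ of the 14
   immune-signature probes (MHC class II components, chemokines,
   immunoglobulins; `immune_signature_genes()`) lie strictly below their
   leave-one-out medians; θ is chosen by ROC analysis (Youden's J), with
   θ = 8.5 as the published operating point.
4. **Survival stratification** (`km_fit()`, `logrank_test()`) of the
   predicted groups, and **ΔΔCt qPCR validation** (`delta_delta_ct()`,
   `mann_whitney()` with an exact, tie-capable permutation p-value).
5. A **synthetic cohort generator** (`generate_cohort()`,
   `generate_qpcr()`) that plants a heterogeneously down-regulated
   signature — each metastatic sample down-shifts a random
   Bernoulli(0.7) subset of the 14 genes — so that every stage of the
   pipeline is testable end to end without downloading anything.

See the vignette (`vignettes/metastasis-signature-workflow.Rmd`) for the
models, parameter choices and known limitations.

## Worked example

```r
library(metasig)

co <- generate_cohort(cohort_config(n_probes = 1000, seed = 1))
co
#> Synthetic cohort: 1000 probes x 45 samples (33 non-recurrent, 12 metastatic)
#> Planted signature: 14 probes (delta = 2, penetrance = 0.7, noise sd = 1)
#> Seed: 1

run <- run_pipeline(co$expression, co$metadata, co$probe_annotation,
                    co$genesets,
                    rsvm = rsvm_config(n_bootstrap = 50, keep_per_step = 42,
                                       seed = 1))
run
#> metasig pipeline run
#>   1000 probes x 45 samples (seed 1)
#>   DE screen: 7 probe(s) flagged
#>   Selection: 363 signature probes -> 274 genes with symbols
#>   Top enriched term: GO:0002376 (p = 9.39e-05)
#>   Classifier: 19 probes, cutoff 9.5, AUC 0.968
#>   Log-rank (Mantel-Cox): chi-sq 24.01, p = 9.581e-07
```

Reading the output: the bootstrap selection keeps every probe saved at
least once across the 50 steps (363 here — the union is deliberately
permissive, as in the original 42-per-step → 44-probe design), the
enrichment stage finds the planted immune term GO:0002376 at the top,
the classifier built from the selected genes annotated to that term
separates the outcome groups with AUC 0.97 at a below-median cutoff of
9.5, and the predicted strata differ sharply in disease-free survival.
At this demonstration size (1,000 probes) a few strongly planted probes
also pass the univariate fold-change/FDR screen; at full array scale
(44,000 probes, the generator default) the screen is expected to come up
empty — the motivating null result — while the multivariate chain above
still recovers the signature.

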
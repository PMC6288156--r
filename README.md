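# seedtrace

Multifocal prostate cancer presents a peculiar analysis problem: one
prostate typically harbours several histologically distinct tumour foci,
possibly clonally unrelated, of which at most one seeded any lymph-node
metastasis. `seedtrace` implements, as a tested and reusable R pipeline,
a transcriptome analysis for this setting. From a gene × sample expression
matrix with tissue-type labels — distant/proximal adjacent normal (DAN/PAN,
collapsed to AN), primary tumour foci (CAN), lymph-node metastases (MET)
and benign lymph node (LYMPH) — it:

1. **discovers progression genes** with a monotone selection rule: a gene
   is kept iff |log2FC| ≥ 2 with FDR < 0.05 *in the same direction* in both
   the AN→CAN and the CAN→MET contrast, using a negative-binomial exact
   test on TMM-normalised counts;
2. **scores progression** per sample as `log2(Σ panel expression + 1)`;
3. **infers the metastasis-seeding focus** per patient by hierarchically
   clustering the patient's CAN+MET samples on the 500, 100 and 50 most
   variable transcripts (Euclidean, complete linkage) and requiring the
   same CAN partner of the MET sample at every gene-set size;
4. **builds Cox-weighted prognostic signatures**: panel-gene expression
   weighted by multivariate Cox coefficients against biochemical recurrence
   (BCR), standardised by the fitting cohort's score SD, risk-stratified by
   a cutoff *fraction* chosen in a reference cohort and transferred as the
   same quantile split to other cohorts;
5. **evaluates** signatures with univariate/multivariate Cox (Efron ties,
   stepwise backward elimination at p ≥ 0.05, the score exempt), Harrell's
   C-index with and without the score, Kaplan–Meier + log-rank on the
   transferred risk groups, and Wilcoxon tests against clinicopathological
   variables.

The survival machinery (Cox partial likelihood via Newton–Raphson,
Kaplan–Meier, log-rank, Harrell's C) and the count-based differential
expression (TMM factors, conditional-likelihood dispersion estimation, NB
conditional exact test) are self-contained implementations, cross-checked
in the test suite against `survival` and `edgeR` and against brute-force
oracles. A synthetic-data module generates multifocal count matrices
(default design: ten patients, 10 DAN / 13 PAN / 23 CAN / 9 MET / 2 LYMPH
samples) and survival cohorts with known ground truth, so every stage is
testable without any download.

## The model in brief

Counts are modelled as NB(μ, α) with variance μ + αμ². For two groups with
equalised libraries, gene-wise group totals are compared by the conditional
exact test: `p = Σ P(a | a + b = z) over all splits no more probable than
the observed one`. The Cox model maximises the Efron-corrected partial
likelihood; a signature score for patient *i* is

    score_i = ( Σ_g β_g · x_gi ) / SD(Σ_g β_g · x_g·)

with β from the joint Cox fit of the panel genes, so scores have SD 1 in
the fitting cohort and the univariate hazard ratio is per SD of score.

## Worked example

```r
library(seedtrace)

## discovery: simulate a multifocal cohort, select the progression panel
sim <- gen_multifocal_counts(sim_config(seed = 42))
ann <- collapse_an(qc_filter(sim$annotation))
de  <- lapply(list(c("AN","CAN"), c("CAN","MET")), function(ct) {
  sel <- ann$tissue_type %in% ct
  nb_exact_test(sim$expr[, ann$sample_id[sel]],
                factor(ann$tissue_type[sel], levels = ct))
})
select_monotone(de[[1]], de[[2]])
#> gene panel: 45 genes (45 down, 0 up) — monotone selection |lfc|>=2, fdr<0.05

## seeding focus for a patient with three primary foci
lg <- to_log2(normalize_counts(sim$expr))
call_seeding_focus(lg, sim$annotation, "PT5")
#> seeding call for PT5: resolved (focus CAN3)

## validation: weighted signature in a survival cohort
co <- gen_survival_cohort(300, gene_panel(c("gA","gB","gC")),
                          c(gA = 0.9, gB = -0.6, gC = 0.5),
                          censoring_rate = 0.4, seed = 42, covariate_assoc = 0.5)
model <- fit_weighted_model(co$expr, gene_panel(c("gA","gB","gC")), co$clinical)
sc <- score_patients(model, co$expr)
model$cutoff_fraction <- choose_cutoff_fraction(sc, co$clinical)$fraction
evaluate_model(model, co$expr, co$clinical,
               c("gleason_gt7","stage_pt3","margin_pos"))
#> univariate Cox:
#>      variable    hr ci_lower ci_upper     p cindex
#> 1 gleason_gt7 1.535    1.144    2.060 0.004  0.562
#> 2   stage_pt3 1.501    1.119    2.013 0.007  0.566
#> 3  margin_pos 1.153    0.849    1.565 0.361  0.524
#> 4       score 3.588    2.982    4.317 0.000  0.790
#>
#> final multivariate model: (none) + score
#> ...
#> C-index with score 0.790, without 0.500 (gain 0.290)
#> risk groups (top 30% high): log-rank p = 6.817e-30
```

The 45-of-50 planted progression genes recovered, the resolved seeding
focus matching the planted truth, the score's univariate HR of 3.6 per SD,
and the C-index gain of 0.29 are all read directly off the printed output:
the backward elimination drops Gleason and stage once the score — the only
true carrier of hazard signal in this simulation — enters the model.

A thin command-line wrapper ships in `inst/exec/seedtrace`:

```sh
Rscript inst/exec/seedtrace run --out run1 --seed 3
Rscript inst/exec/seedtrace simulate --out simdir --seed 3
```

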
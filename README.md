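# pdactme

Tumor-microenvironment profiling of pancreatic ductal adenocarcinoma
(PDAC) from single-cell transcriptomes, with a bulk-cohort survival arm.

Solid tumors are mixtures: epithelial tumor cells (ETCs), tumor cells
with epithelial–mesenchymal-transition features (EMT), cancer-associated
fibroblasts (CAFs), tumor-infiltrating lymphocytes (TILs),
tumor-associated macrophages (TAMs), dendritic and endothelial cells.
`pdactme` is for analysts who want to (a) quantify that cellular
composition per patient from droplet scRNA-seq, (b) derive cell-type
marker signatures, and (c) ask whether those signatures predict overall
survival in bulk expression cohorts. A synthetic-data module generates
both data types with planted ground truth, so the entire chain is
testable without any external download.

## The computations

- **QC:** keep cells with total UMI ≥ 1000 and Shannon diversity
  H = −Σ pᵢ ln pᵢ ≥ 3 (natural log; e³ ≈ 20 effective genes).
  Mitochondrial fraction is reported, not filtered.
- **Normalization / embedding:** log1p(10⁴·count/total); trend-
  standardized highly variable genes; scaled values clipped at 10; PCA;
  kNN graph; Louvain clustering.
- **Cell typing:** module score of each marker panel = mean expression
  of panel genes − mean of expression-matched control genes (24 bins,
  100 controls/gene); clusters labeled by the top-scoring panel with a
  0.05 margin, else `Unknown`; ETC+EMT co-signal resolves to EMT.
- **Composition:** per-patient label percentages (rows sum to 100), with
  the `< 0.1` presentation dialect for trace abundances.
- **Signatures:** one-vs-rest Wilcoxon rank-sum (midranks, tie-corrected
  variance, continuity correction; exact enumeration for untied samples
  of combined size ≤ 12), BH adjustment, ranked by p then |ln fold
  change|, top-20 per type; hypergeometric P(X ≥ k) enrichment.
- **Survival:** per gene, patient value = 1 iff expression ≥ cohort
  median; per-patient score = sum over signature genes (0..k); high/low
  = top/bottom ⌈n/4⌉ scores with inclusive boundary ties; Kaplan–Meier
  curves; Mantel–Cox log-rank χ² = (O₁−E₁)²/V; Mantel–Haenszel
  HR = (O₁/E₁)/(O₂/E₂) with CI exp(ln HR ± 1.96·√(1/E₁+1/E₂)); Cox HR
  available as a cross-check.

See `vignettes/pdac-tme-methods.Rmd` for assumptions, parameter
defaults, and design rationale.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads the previous stage's output from `results/`:

```sh
Rscript analysis/01_simulate_data.R   # synthetic sc + bulk inputs
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_cluster_annotate.R
Rscript analysis/04_composition.R
Rscript analysis/05_signatures.R
Rscript analysis/06_subtype_scores.R
Rscript analysis/07_survival.R
```

With the shipped defaults (seed 1) the run prints, among other things:

```
QC kept 2416 / 2500 cells (96.6%); removed 84 for library size, 0 for diversity
Found 13 clusters over 2416 cells
Cluster-level label accuracy against the planted truth: 100.0%
Planted-marker recall in the top-20 signatures:
ETC EMT CAF TIL TAM
  1   1   1   1   1
planted_signature:    chi-square 22.64, p 1.95e-06, HR 2.76 [1.74, 4.39], high n=54 low n=53
background_signature: chi-square 0.00,  p 0.995,    HR 1.00 [0.63, 1.59], high n=51 low n=51
```

Reading: QC removed only the low tail of the planted library-size
distribution; the 13 clusters are the five planted types, with tumor
types split further by patient (the planted patient effect); every
planted marker reappears in its type's derived top-20 signature; the
planted hazardous 20-gene signature separates the extreme score
quartiles (high-score patients die faster, HR ≈ 2.8), while a random
background signature shows no association — the null behaves.

The same chain runs as one call through `run_all(pipeline_config(...),
out_dir)`, which writes per-stage TSVs and a `manifest.json` with
parameters and input checksums; reruns with one seed are byte-identical.

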
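# tsRNAtriage

Circulating tRNA-derived small RNAs (tsRNAs) — tRNA-related fragments
(tRFs) and tRNA halves (tiRNAs) — are abundant, stable constituents of
serum whose levels drop after total-body ionizing-radiation exposure,
which makes a small serum tsRNA panel attractive for minimally invasive
biodosimetry and triage. `tsRNAtriage` is an R/Bioconductor-style
package for the full analysis chain behind such a panel, aimed at
radiation-biology and small-RNA bioinformatics groups:

* **Fragment classification** — hierarchical mapping of 14–40 nt reads
  to mature tRNA, then precursor tRNA, then miRNA references, ungapped
  with at most **1 mismatch**, followed by coordinate-based subtype
  calls (tRF-5a/5b/5c, tiRNA-5/3, tRF-3, tRF-i, tRF-1) against the
  anticodon-loop annotation.
* **Expression screening** — species × sample count matrices with CPM
  normalisation (CPM = count / total aligned reads × 10⁶), a strict
  CPM > 20 abundance filter, and the symmetric 1.5-fold screen: species
  with FC ≥ 1.5 (up) or FC ≤ 1/1.5 (down) versus sham control in
  **every** dose group, with Venn layers and candidate ranking.
* **qPCR validation** — 2^−ΔΔCt relative quantification with exogenous
  spike-in normalisation (ΔCt = Ct(target) − Ct(spike); ΔΔCt referenced
  to the control-group mean), Welch/Student t-tests and one-way ANOVA,
  and dose-response tables with a monotone-suppression flag.
* **Exposure-risk modelling** — ordinal exposure degrees (ED) fitted on
  marker panels by OLS, the linear exposure risk score
  `ERS = β₀ + Σ βᵢxᵢ`, published coefficient fixtures for carbon-ion,
  X-ray and proton exposure, and ROC/AUC triage evaluation (trapezoidal
  AUC = Mann–Whitney concordance; Youden-optimal cutoff) comparing the
  panel against each single marker.
* **Synthetic data** — seeded generators for reference sets, serum read
  libraries, expression matrices and Ct tables with ground-truth
  manifests, emulating serum library structure (length peaks at 19–24
  and 28–32 nt, >75 % mature-tRNA reads, tRF-5c-dominant subtype mix).

## Worked example

Simulate a serum library, classify it, and inspect composition:

```r
library(tsRNAtriage)

refset <- generateReferenceSet(nTRNA = 20, nPre = 5, nMiRNA = 10, seed = 7)
lib    <- simulateReadLibrary(refset, nReads = 10000, seed = 1)
kept   <- lengthFilter(lib$reads)
aln    <- hierarchicalAlign(kept$reads, refset)
calls  <- classifyFragments(aln, refset)
cs     <- summarizeComposition(aln, calls)

round(cs$classProp, 4)
#>    mature precursor     mirna  unmapped
#>    0.7745    0.0090    0.0103    0.2062
round(cs$subtypeProp, 4)
#>  tRF-5a  tRF-5b  tRF-5c tiRNA-5 tiRNA-3   tRF-3   tRF-i
#>  0.0516  0.1450  0.5468  0.0440  0.0000  0.1258  0.0868
```

77 % of reads map to mature tRNAs (the generator planted 78 %; the
remainder is random-sequence noise left unmapped), tRF-5c dominates the
mature fragments and tiRNA-5 sits at 4.4 % — the serum profile the
classifier is built to recover.

Score samples with a published exposure-risk model and evaluate triage:

```r
m <- ersModel("carbon")
m
#> ERSModel (carbon): ERS = 0.646 - 0.149 x [tiRNA-Glu-TTC-003]
#>   + 0.022 x [tRF-Val-AAC-024] - 0.093 x [tRF-Gln-CTG-018]
#>   + 0.139 x [tRF-Lys-CTT-008] - 0.206 x [tRF-Lys-TTT-019]
scoreERS(m, rep(0, 5))   # all markers at zero -> the intercept
#> [1] 0.646

rocCurve(c(0.61, 0.52, 0.66, 0.35, 0.28, 0.31), c(1, 1, 1, 0, 0, 0))
#> ROCResult: AUC 1.0000 | Youden cutoff 0.52 (sens 1.000, spec 1.000), direction: higher
```

The whole chain — simulate, classify, screen, quantify, fit, evaluate —
runs from one config:

```r
res <- runPipeline(pipelineConfig(seed = 1, output_dir = "tsrna-run"))
res$model$comparison   # panel AUC vs each single marker
```

See `vignettes/tsrna-radiation-biodosimetry.Rmd` for the model details,
parameter semantics and design rationale.

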
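---
title: "Serum tsRNA biomarkers for radiation biodosimetry: methods and design"
author: "tsRNAtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum tsRNA biomarkers for radiation biodosimetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsRNAtriage)
```

## The problem

Circulating tRNA-derived small RNAs (tsRNAs) — tRNA-related fragments
(tRFs) and tRNA halves (tiRNAs) — are abundant and stable in serum, and a
subset of them is suppressed after total-body ionizing-radiation
exposure. That makes them candidates for minimally invasive biodosimetry:
measure a small panel of serum tsRNAs by RT-qPCR, combine them into a
single exposure risk score, and triage exposed from unexposed
individuals. `tsRNAtriage` implements that analysis chain end to end:

1. **Classification** — small-RNA reads of 14–40 nt are mapped
   hierarchically to mature tRNA, then precursor tRNA, then miRNA
   references, allowing at most one mismatch, and mature-tRNA fragments
   are assigned a tsRNA subtype from their alignment coordinates.
2. **Screening** — species-level CPM matrices are filtered at CPM > 20
   and screened for a consistent ≥ 1.5-fold change versus sham control
   in every irradiation dose group.
3. **Validation quantification** — qPCR Ct tables with an exogenous
   spike-in (a cel-miR-39 analogue) are converted to relative expression
   by 2^−ΔΔCt, with t-tests and one-way ANOVA versus control.
4. **Risk modelling** — ordinal exposure degrees (ED) are regressed on
   the marker panel by ordinary least squares; the linear exposure risk
   score ERS = β0 + Σ βi·xi is evaluated by ROC/AUC against each single
   marker.

Because no public read or Ct dataset accompanies the study conditions the
package targets, a first-class synthetic-data module generates
references, serum read libraries, expression matrices and Ct tables with
ground-truth manifests, so every stage is testable without downloads.

## Data model and conventions

* All intervals are **0-based half-open** internally; conversion to
  1-based closed coordinates (`toOneBased()`/`toZeroBased()`) happens
  only at text-report boundaries. This keeps the subtype interval
  arithmetic unambiguous.
* Mature tRNA references **include the post-transcriptional 3' CCA**
  (the GtRNAdb mature convention); the synthetic generator appends it.
  3'-fragment calls depend on the true mature terminus, so the choice is
  load-bearing. Whether a real upstream index included CCA is not
  observable from fragment tables, so this convention is a design
  decision, and references from other sources must follow it.
* RNA alphabets are normalised to DNA (U → T) at ingest; one internal
  alphabet everywhere.
* The anticodon-loop coordinates are a separate five-column sidecar
  table rather than being parsed out of structure strings: FASTA stays
  standard and the structural model stays explicit.

## Alignment and subtype calling

Alignment is **ungapped full-length Hamming matching**: a read maps at an
offset if it differs from the reference window in at most one position.
No indels, no soft-clipping, sense strand only (small-RNA libraries are
stranded). Among qualifying placements the best hit prefers fewer
mismatches, then a smaller start coordinate, then the earlier reference
in file order — the data do not dictate a tie order, so one is fixed and
documented to make results deterministic. Reads are deduplicated before
alignment, so classification is a pure per-sequence function and the
output is independent of input order. The window scan itself is a small
C++ kernel; a brute-force pure-R scan serves as the oracle in the test
suite and the two are checked for exact agreement, tie-breaks included.

The hierarchy mirrors the biological prior: mature-tRNA fragments
dominate serum, so the mature tier is tried first, then precursors (for
leader/trailer fragments), then miRNA. A precursor hit that falls
entirely inside the embedded mature interval is re-credited to the
corresponding mature reference with shifted coordinates; how such reads
should be credited is genuinely underdetermined, and crediting the
mature form keeps fragment species unified across tiers.

Subtypes follow the standard tRF/tiRNA nomenclature, evaluated top-down
against the 7-nt anticodon loop `[loopStart, loopEnd)` of the target:
tiRNA-5 (5' end into the loop), tRF-5c (5' end, ends at/before the loop,
≥ 28 nt), tRF-5a (5' end, 14–16 nt), tRF-5b (residual 5' class), tiRNA-3
(loop to the 3' CCA), tRF-3 (3'-anchored otherwise), tRF-i (internal);
precursor fragments overlapping the 3' trailer are reported separately
as tRF-1. The 5a/5b/5c length boundaries (14–16 / 17–27 / ≥ 28 nt) are
the field's usual grades; the ≥ 28 nt floor for tRF-5c matches the
28–32 nt abundance peak that 5'-anchored long fragments produce.

## Quantification and the screen

Species identity is the exact fragment — target tRNA, subtype and
coordinates — not the parent gene, because validated biomarkers are
individual fragments. Abundance is counts per million of total aligned
reads (CPM); the retention rule "CPM **more than** 20" is read strictly
and enforced in **every** sample (a mean-based variant is available).
Fold change per dose group is the ratio of arithmetic group-mean CPM to
control-mean CPM; single-sample (pooled-library) groups are supported,
since pooling serum per dose before sequencing is common practice. The
screen is symmetric on the log scale: up means FC ≥ 1.5, down means
FC ≤ 1/1.5, and the reported intersection holds species passing with a
consistent direction in all dose groups. Candidates for validation are
ranked within each direction by mean control read count (ties broken
lexicographically), taking 4 up- and 6 down-regulated species by
default.

One property of CPM worth stating: it is **compositional**. Fold changes
are changes in library *share*, so if strongly responsive species make
up a large fraction of total abundance, their own fold changes are
diluted and every null species drifts in the opposite direction. The
synthetic defaults therefore keep planted species a modest fraction of
library weight, and the pipeline's planted effects (3-fold up, 3-fold
down at every dose) leave wide margins around the 1.5-fold threshold
after the compositional shift. The acceptance-level matrix simulation
(200 species, 17 up / 9 down at 2-fold, log-normal dispersion 0.05,
3 replicates per dose) recovers the planted sets exactly with ~7σ
margins.

## qPCR relative quantification

Per sample and target, ΔCt = Ct(target) − Ct(spike-in);
ΔΔCt references the **arithmetic mean control ΔCt** per target (a
designated calibrator sample is available as an option), and
RQ = 2^−ΔΔCt. Consequences checked by tests: the control group's
log-mean RQ is exactly zero (geometric mean 1), and adding any constant
to all Ct values of a sample leaves RQ unchanged (spike invariance).
Group summaries are arithmetic mean ± standard error (the common
reporting convention; geometric summaries are an option). Each treated
group is compared to control with a two-sided two-sample t-test — Welch
by default, since equal variances are rarely defensible; the classical
pooled test is a switch — plus a one-way ANOVA across groups per target.
Significance tiers are `*` p < 0.05 and `**` p < 0.01. No
multiple-testing correction is applied across the small panel by
default; a Benjamini–Hochberg column is available.

## Exposure degrees, the risk score, and ROC

Exposure degree (ED) is an ordinal coarsening of absorbed dose with the
sham control isolated: the defaults are ED0 = {0}, ED1 = (0, 0.1] Gy,
ED2 = (0.1, 2] Gy, separating low-dose from higher-dose exposure; the
partition is fully configurable since no canonical break set exists.
The fitted model is **ordinary least squares of numeric ED on marker
RQ** — the printed linear score form is implemented as primary, with a
binary logistic alternative behind a flag. Collinear or constant markers
are rejected by name rather than silently dropped. Published coefficient
sets for carbon-ion, X-ray and proton exposure over the five-marker
serum panel ship as read-only JSON fixtures (`ersModel()`), so scoring
does not require refitting; the X-ray panel uses four of the five
markers.

The ROC sweep thresholds at every observed score (plus sentinels) with
"score ≥ cutoff" predicting exposed; ties contribute half-concordance,
so the trapezoidal AUC equals the Mann–Whitney concordance probability
exactly — this identity is fuzz-tested on 1,000 random instances and
cross-checked against an established ROC implementation. Suppressed
single markers are oriented lower-is-positive so informative markers
score AUC ≥ 0.5. The reported operating point maximises Youden's
J = TPR − FPR (the first maximum along the sweep).

## What the synthetic data emulates — and what it does not

The generator reproduces the statistical structure the analysis depends
on: read lengths of 14–40 nt with peaks at 19–24 and 28–32 nt; ~78% of
reads from mature tRNA fragments, ~1% precursor-specific, ~1% miRNA,
the rest random-sequence noise; a tRF-5c-dominant subtype mix with
tiRNA-5 at 4.5% (inside the reported 3–6% band); dose-dependent
suppression or induction of selected fragment species with log-normal
between-sample dispersion; and Ct tables with per-sample spike-in
measurements. Fragment species have fixed coordinates per
(tRNA, subtype), so the same species recurs identically across samples;
base abundances follow a fixed log-normal-like profile that is a
property of the reference set, not of the seed, so fold changes across
libraries compare like with like.

Deliberately not modelled: realistic sequencing-error profiles (errors
are off by default; a uniform per-base substitution rate exists to
exercise the one-mismatch path), adapter content (inputs are assumed
trimmed), RNA-modification effects on library construction, and
inter-individual biological variance structure, for which no published
estimates exist — the dispersion defaults (0.05 on the log scale) are a
design choice, not a measured quantity. Passing tests on these data
therefore demonstrate the correctness of the *computational chain* —
classification, screening, quantification, scoring — not the biological
effect sizes recoverable from real serum.

In the qPCR simulator the spike-in is drawn once per sample and shared
across that sample's targets, as a single normalisation reaction would
be. Its noise (`spikeSd`, pipeline default 0.15 cycles) is smaller than
target noise (`ctSd`, pipeline default 0.45 cycles): the spike-in is a
fixed-quantity exogenous control, while target Ct reflects biological
plus technical variation. This split matters for the panel-vs-single
comparison — spike error is shared across markers and cannot be averaged
away by the panel, so making it dominant would (unrealistically) cap the
panel's advantage.

## Numerical choices and degenerate inputs

* Zero-noise qPCR simulation composed with ΔΔCt is the identity on fold
  change (tested exactly); `−log2(0.25) = 2` cycles, and so on.
* Two identical comparison groups yield t = 0, p = 1 (the degenerate
  constant-data case is handled explicitly rather than erroring).
* Single-sample groups skip significance testing with a flag.
* The monotone-suppression flag in the dose-response table uses
  non-increasing group means with a 1e-9 slack; with one dose level it
  is `NA`.
* Empty screens, empty read sets and zero-total samples either pass
  through gracefully or fail with the offending sample named.
* Seeds: every generator takes an explicit integer seed, recorded in
  output manifests; the pipeline derives per-stage stream seeds from the
  single config seed (kept below 2^31).

## Problem sizes

The default pipeline simulates five pooled libraries (one per dose at
0, 0.05, 0.1, 0.5, 1 Gy) of 100,000 reads over a 20-tRNA / 5-precursor /
10-miRNA reference set, plus a five-marker Ct table with 10 replicates
per dose; it completes in well under a minute on one CPU. The test
suite's composition and screen checks use 10,000-read libraries and
200-species matrices. These sizes were chosen so the statistical margins
(binomial tolerance on composition fractions, σ-margins on the screen)
are wide at desk scale; they are orders of magnitude below real serum
sequencing depth, which is why the screen-stage assertions are about
exact planted-truth recovery rather than about real-data power.

## Known limitations

* The aligner is exact Hamming matching by design; it will not place
  reads with indels or more than one substitution, and does not model
  modification-induced misincorporation patterns characteristic of real
  tRNA sequencing.
* Multi-mapping reads are counted once for the single tie-broken best
  target; no fractional assignment.
* The ERS model is linear in RQ with no interaction or regularisation;
  with more markers than samples it will (correctly) refuse to fit.
* Amplification-efficiency correction, melt-curve QC and absolute
  quantification are out of scope for the qPCR module.

## A compact run

```{r, eval = FALSE}
cfg <- pipelineConfig(seed = 1, output_dir = "tsrna-run")
res <- runPipeline(cfg)
screenTable(res$screen$screen)   # per-species FCs, flags, intersection
res$model$comparison             # panel vs single-marker AUC table
```
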
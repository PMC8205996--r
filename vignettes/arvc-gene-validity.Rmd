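---
title: "Scoring gene-disease validity for ARVC: model, configuration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-disease validity for ARVC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arvcvalidity)
```

## The procedure and its assumptions

`arvcvalidity` computes the semiquantitative clinical-validity score that
gene curation expert panels use to decide whether a gene genuinely causes
a disease — here, arrhythmogenic right ventricular cardiomyopathy (ARVC)
defined by the 2010 Task Force Criteria. The package deliberately models
the *arithmetic* of curation, not the *judgment*: which probands count,
what points a particular publication deserves, and whether a mouse heart
looks like ARVC are curator inputs recorded in the evidence files; the
package guarantees that once those adjudications are fixed, the subtotals,
caps, bands and reports that follow from them are deterministic,
order-independent and reproducible.

The underlying model assumes a Mendelian architecture with a single gene
under assessment: evidence items contribute points independently, caps
express saturating belief (a twentieth null-variant proband adds nothing
once the case-level cap is reached), and classification is a monotone step
function of the total. Oligogenic contribution, environmental modifiers
(notably exercise, a known driver of ARVC penetrance) and reduced
penetrance are outside the model except insofar as curators down-weight
individual items.

Two panel-specific rules are layered on top of the generic framework and
are modelled explicitly:

* **The model-phenotype gate.** A model-organism, cell-model or rescue
  item carries a `phenotype_consistent` judgment; when false the item
  scores zero regardless of its award. This encodes the panel practice of
  discounting, for example, a knockout mouse with dilated cardiomyopathy
  as evidence for ARVC. Whether partially consistent phenotypes should
  earn reduced (rather than zero) points was left open by the published
  account; we chose the strict zero because any intermediate credit is an
  adjudication, and adjudications belong in `awarded_points`, not in code.
* **Allele-frequency admissibility.** Candidate variants in patients must
  be rarer than a maximum credible population allele frequency; the
  package computes the threshold and a per-population filtering allele
  frequency and records the assessment on the evidence item.

## Tunable parameters

All scoring constants live in the `score_matrix` (YAML/JSON-serializable,
checksum logged by `run_full_curation()`); disease parameters live in
`frequency_params`. Defaults and rationale:

| parameter | default | why |
|---|---|---|
| null-variant proband | 1.5 pts, range 0–3, cap 10 | framework default for predicted/proven null variants |
| other variant w/ gene impact | 0.1 pts, range 0–1.5, cap 7 | framework default; missense without functional support is weak |
| de novo (non-null) variant | 0.5 pts | framework upgrade for de novo occurrence; confirmed and assumed treated identically (the published account does not distinguish them) |
| AR biallelic categories | 2 / 1 pts | framework defaults for in-trans genotypes with/without a null allele |
| segregation bins | LOD 2/3/5 → 1/2/3 (candidate gene), halved for exome/genome | framework mapping; cap 3 |
| case-control study | 0–6 pts, cap 12 | framework range |
| subtotal caps | genetic 12, experimental 6 | fixes the 0–18 scale |
| bands | 0 / (0,7) / [7,12) / [12,18] | see "Numerical choices" |
| prevalence | 1/1000 | accepted ARVC prevalence order |
| max allelic contribution | 0.1 | no single ARVC variant explains more than ~10% of cases outside founder regions |
| penetrance | 0.5 | conservative allowance for the age-related, reduced penetrance of ARVC |
| inheritance factor | 0.5 | one pathogenic allele per affected genotype (monoallelic dominant) |
| FAF confidence | 0.95 | conventional one-sided level |
| min allele number | 2000 | below ~1000 genotypes a subpopulation frequency is too noisy to filter on |

The frequency parameters are configuration, not ground truth: the panel's
actual numeric cutoffs were not published, so every run should state the
values used (the assessment object records them).

A de novo *null* variant resolves to the null category (default 1.5,
curator may award up to 3) rather than the 0.5 de novo category, which
models de novo occurrence as an upgrade consideration for otherwise weak
variant classes only.

## Numerical choices

* **Points grid.** Points are multiples of 0.05. R doubles cannot
  represent 0.05 exactly, so every subtotal is re-snapped to the grid
  (`round(x * 20) / 20`); all representable sums on the 0–18 scale
  round-trip exactly, which keeps half-point totals such as 9.5 exact.
* **Band edges.** The published bands print "1–6" for Limited and "12–18"
  for Strong, leaving scores in (6, 7) formally unassigned. We assign
  (0, 7) to Limited so the bands partition the whole representable scale;
  this is the conservative choice (a 6.5 does not reach Moderate) and is
  consistent with every printed example. The partition is property-tested
  on the full 0.05 grid.
* **Out-of-range awards error, never clamp.** Curation files record panel
  decisions; silently altering one would hide a data error.
* **Degenerate inputs.** Empty evidence lists are valid (score 0, No
  Known Relationship); a segregation item must carry exactly one of a
  meiosis count or a published LOD; an all-underpowered frequency panel
  yields an explicitly undetermined assessment rather than a pass.
* **Filtering allele frequency.** Computed in closed form through the
  Poisson/gamma tail identity (`qgamma(1 - confidence, shape = ac) / an`);
  the test suite cross-checks it against an independent bisection of the
  `ppois` tail.
* **Consensus.** When the two blinded teams disagree on the preliminary
  band, the pipeline reports `needs_panel_review` rather than averaging
  or taking either side: band disagreement is precisely the event the
  dual design exists to surface.
* **Replication.** `replicated_over_time` is a stored panel judgment; the
  helper predicate (≥ 2 independent publications spanning ≥ 3 years) is
  advisory only, because the operational threshold the panel used was not
  published.

## What the synthetic data emulates — and what it does not

`generate_curation()` draws evidence compositions (proband awards on the
grid within category ranges, segregation as either a published LOD or an
equivalent meiosis count, case-control studies, experimental items across
the three groups, occasionally a phenotype-gated model item) that land in
a requested classification band, and records the expected breakdown
computed by its own independent tally — plain running sums with caps
applied once at the end, sharing no code with the scoring modules. That
independence is what makes "scoring reproduces the generator's
expectation, exactly, across 200 records and all bands" a meaningful
test: both sides would have to contain the same bug for it to pass
wrongly.

The packaged 26-gene fixture transcribes the published panel outcome: the
final classifications, the three printed totals (DES 9.5, PLN 11, SCN5A 6)
and the ClinVar tier aggregates (450/462 desmosomal P/LP; 5 P/LP in
limited-evidence genes) are pinned to the printed values, while each
gene's item-level evidence and genetic/experimental split are synthetic
placeholders constrained only to land the gene in its printed band (the
granular subscores live in a supplement that is not machine-readable, and
per-gene P/LP counts within the desmosomal tier were likewise only
printed in aggregate). Passing the fixture tests therefore shows that the
scoring and classification machinery reproduces the published taxonomy
from band-consistent inputs; it does **not** re-curate the underlying
literature, re-derive any gene's granular subscores, or re-query ClinVar.
Equally, the synthetic generator emulates evidence *arithmetic*, not
evidence *quality*: real curations have correlated items, contested
adjudications and missing data that no generated record reproduces.

Problem sizes throughout were chosen at desk scale — 26 genes, a few
dozen evidence items per record, a ~1,900-row variant table, 200 generated
curations and 1,000 random evidence sets in the property suites — which
the full test suite and the acceptance script traverse in seconds.

## Known limitations

* No likelihood-based pedigree LOD computation: only meiosis counting or
  published-LOD pass-through (the counting approximation assumes full
  penetrance and no phenocopies, so it overstates LOD for ARVC families
  with unaffected carriers).
* No automated judgment of model-phenotype consistency, variant
  consequence annotation, or literature retrieval — all are curator
  inputs by design.
* VCF ingest of population frequencies is not provided; frequencies enter
  via the TSV interchange (`variant_id`, `population`, `AC`, `AN`).
* The "Strong without Definitive due to contradictory evidence" nuance of
  the full framework is not modelled beyond the Disputed/Refuted
  overrides.
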
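# arvcvalidity

Semiquantitative gene–disease clinical validity scoring for
arrhythmogenic right ventricular cardiomyopathy (ARVC).

Diagnostic sequencing panels for ARVC list anywhere from 11 to 46 genes,
yet for many of those genes the published evidence of disease causation is
thin. Because a pathogenic variant in an "ARVC gene" constitutes a major
diagnostic criterion, over-inclusive panels translate directly into
misdiagnosis and incorrect cascade testing of relatives. `arvcvalidity`
implements, as reusable and tested code, the evidence-scoring computation a
gene curation expert panel (GCEP) applies when it reappraises such genes:
it is written for clinical-genomics curators and methodologists who want
the arithmetic of a curation to be reproducible, auditable and
configurable.

## The scoring model

Each gene–disease pair is scored on a 0–18 point scale composed of two
capped subtotals:

* **Genetic evidence** (cap 12) — case-level variant points (per-category
  defaults and ranges, e.g. a predicted/proven null variant in a proband
  defaults to 1.5 points within [0, 3], category cap 10; overall
  case-level cap 12), segregation points obtained by summing family LOD
  scores and binning (LOD 2–2.99 → 1, 3–4.99 → 2, ≥ 5 → 3 for
  candidate-gene studies, halved for exome/genome-era studies; cap 3), and
  case–control points (0–6 per study, cap 12). A family's LOD is the
  published value when available, otherwise the counting approximation
  *LOD = n·log₁₀2* over *n* informative meioses.
* **Experimental evidence** (cap 6) — function (≤ 2), functional
  alteration (≤ 2), and model-system/rescue (≤ 4) groups, with an
  ARVC-specific gate: a model or rescue system whose phenotype was judged
  inconsistent with ARVC contributes zero points.

Totals map onto validity bands — 0: No Known Relationship; (0, 7):
Limited; [7, 12): Moderate; [12, 18]: Strong, upgraded to **Definitive**
when the association has replicated across cohorts — and the panel-level
**Disputed**/**Refuted** overrides beat points. All constants live in a
user-overridable score matrix whose checksum is logged on every run.

Candidate-variant admissibility uses the maximum credible population
allele frequency, *prevalence × max allelic contribution × inheritance
factor / penetrance*, compared against a one-sided Poisson lower
confidence bound on the variant's observed frequency (the filtering allele
frequency), per population, with founder-variant exemptions.

## Worked example

```r
library(arvcvalidity)

rec <- gene_disease_record("DES",
  proband_evidence = c(
    replicate(3, proband_variant_evidence("p", "predicted_or_proven_null"),
              simplify = FALSE),
    replicate(2, proband_variant_evidence("q", "other_with_gene_impact",
                                          awarded_points = 0.5),
              simplify = FALSE)),
  segregation_evidence = list(segregation_evidence("fam1", published_lod = 3.2)),
  experimental_evidence = list(
    experimental_evidence_item("biochemical_function"),
    experimental_evidence_item("expression"),
    experimental_evidence_item("functional_alteration_patient_cells")))

score_record(rec)
#> Gene-disease validity score for DES
#>   genetic 7.5 + experimental 2 = total 9.5
#>   preliminary: moderate | final: moderate
```

7.5 genetic points (4.5 from null-variant probands at the 1.5 default,
1 from the two adjudicated missense probands, 2 from the LOD 3.2
segregation bin) plus 2 experimental points total 9.5, which falls in the
Moderate band [7, 12).

The packaged fixture reproduces the full 26-gene reappraisal:

```r
fx <- arvc_fixture()
final <- vapply(fx$records, function(r) score_record(r)$final$value, character(1))
table(final)
#> final
#>            definitive              disputed               limited
#>                     6                     1                    10
#>              moderate no_known_relationship               refuted
#>                     2                     6                     1

summarize_variant_classes(fx$variant_table, fx$tier_map)
#> Variant-class summary: 1857 variants, 462 P/LP
#>   desmosomal                    450 P/LP ( 97.4%)
#>   definitive_nondesmosomal        4 P/LP (  0.9%)
#>   moderate                        3 P/LP (  0.6%)
#>   limited                         5 P/LP (  1.1%)
#>   ...
```

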
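m <- default_score_matrix()

test_that("proband variants score the matrix default or the adjudicated award", {
  null_ev <- proband_variant_evidence("p", "predicted_or_proven_null")
  other_ev <- proband_variant_evidence("p", "other_with_gene_impact")
  dnv_ev <- proband_variant_evidence("p", "other_with_gene_impact",
                                     de_novo = "confirmed")
  expect_equal(score_proband_variant(null_ev, "AD", m), 1.5)
  expect_equal(score_proband_variant(other_ev, "AD", m), 0.1)
  expect_equal(score_proband_variant(dnv_ev, "AD", m), 0.5)

  awarded <- proband_variant_evidence("p", "predicted_or_proven_null",
                                      awarded_points = 2.0)
  expect_equal(score_proband_variant(awarded, "AD", m), 2.0)

  # adjudicated values outside the category range error, never clamp
  too_high <- proband_variant_evidence("p", "predicted_or_proven_null",
                                       awarded_points = 3.5)
  expect_error(score_proband_variant(too_high, "AD", m), "outside range")
})

test_that("recessive curations use the biallelic categories and need a phase", {
  ar_null <- proband_variant_evidence("p", "predicted_or_proven_null",
                                      phase_for_AR = "in_trans")
  ar_other <- proband_variant_evidence("p", "other_with_gene_impact",
                                       phase_for_AR = "unknown")
  expect_equal(score_proband_variant(ar_null, "AR", m), 2)
  expect_equal(score_proband_variant(ar_other, "AR", m), 1)
  bad <- proband_variant_evidence("p", "predicted_or_proven_null")
  expect_error(score_proband_variant(bad, "AR", m), "unresolvable")
})

test_that("variant subtotals respect category caps, the overall cap and item order", {
  three <- replicate(3, proband_variant_evidence("p", "predicted_or_proven_null"),
                     simplify = FALSE)
  expect_equal(variant_evidence_subtotal(three, "AD", m)$capped, 4.5)

  # null-category sum 14 clamps at the category cap of 10
  seven <- replicate(7, proband_variant_evidence("p", "predicted_or_proven_null",
                                                 awarded_points = 2),
                     simplify = FALSE)
  sub <- variant_evidence_subtotal(seven, "AD", m)
  expect_equal(sub$by_category[["predicted_or_proven_null"]], 10)
  expect_equal(sub$capped, 10)

  expect_equal(variant_evidence_subtotal(list(), "AD", m)$capped, 0)

  mixed <- c(seven, replicate(4, proband_variant_evidence(
    "q", "other_with_gene_impact", awarded_points = 1.5), simplify = FALSE))
  expect_equal(variant_evidence_subtotal(mixed, "AD", m)$capped, 12)  # 10+6 -> 12
  for (s in 1:5) {
    perm <- sample(mixed)
    expect_identical(variant_evidence_subtotal(perm, "AD", m),
                     variant_evidence_subtotal(mixed, "AD", m))
  }
})

test_that("segregation LOD estimation counts meioses, passes published LODs, and is additive", {
  expect_equal(estimate_segregation_lod(
    segregation_evidence("f", informative_meioses = 0)), 0)
  expect_equal(estimate_segregation_lod(
    segregation_evidence("f", informative_meioses = 10)), 3.0103,
    tolerance = 1e-4)
  expect_equal(estimate_segregation_lod(
    segregation_evidence("f", published_lod = 2.3)), 2.3)

  for (n in c(0L, 3L, 11L)) for (mm in c(1L, 6L)) {
    joint <- estimate_segregation_lod(
      segregation_evidence("f", informative_meioses = n + mm))
    parts <- estimate_segregation_lod(
      segregation_evidence("f", informative_meioses = n)) +
      estimate_segregation_lod(
        segregation_evidence("f", informative_meioses = mm))
    expect_equal(joint, parts)
  }
})

test_that("segregation points bin summed LODs per approach and clamp at the cap", {
  seg <- function(lod, ap = "candidate_gene")
    segregation_evidence("f", published_lod = lod, sequencing_approach = ap)
  expect_equal(segregation_points(list(seg(1.0)), m), 0)
  expect_equal(segregation_points(list(seg(3.5)), m), 2)
  expect_equal(segregation_points(list(), m), 0)

  fams <- list(segregation_evidence("a", informative_meioses = 6),
               segregation_evidence("b", informative_meioses = 5))
  expect_equal(sum(vapply(fams, estimate_segregation_lod, numeric(1))),
               3.3113, tolerance = 1e-4)
  expect_equal(segregation_points(fams, m), 2)

  # exome/genome-era families earn half points; approaches sum then clamp
  expect_equal(segregation_points(list(seg(3.5, "exome_genome")), m), 1)
  expect_equal(segregation_points(list(seg(6), seg(6, "exome_genome")), m), 3)
})

test_that("case-control points sum per-study awards and clamp at 12", {
  cc <- function(p) case_control_evidence("s", "aggregate", awarded_points = p)
  expect_equal(case_control_points(list(), m), 0)
  expect_equal(case_control_points(list(cc(4), cc(3)), m), 7)
  expect_equal(case_control_points(list(cc(6), cc(6), cc(6)), m), 12)
})

test_that("the genetic subtotal combines components and clamps at 12", {
  rec <- gene_disease_record("G",
    proband_evidence = replicate(7, proband_variant_evidence(
      "p", "predicted_or_proven_null", awarded_points = 2), simplify = FALSE),
    segregation_evidence = list(segregation_evidence("f", published_lod = 6)),
    case_control_evidence = list(case_control_evidence("s", "aggregate",
                                                       awarded_points = 2)))
  g <- genetic_subtotal(rec, m)
  expect_equal(g$variant_points_capped, 10)
  expect_equal(g$segregation_points, 3)
  expect_equal(g$case_control_points, 2)
  expect_equal(g$genetic_subtotal, 12)  # 10+3+2 clamps at the genetic cap

  expect_equal(genetic_subtotal(gene_disease_record("G"), m)$genetic_subtotal, 0)
})

test_that("genetic subtotal matches a brute-force oracle and is monotone in added evidence", {
  for (seed in 1:60) {
    rec <- random_small_record(seed)
    g <- genetic_subtotal(rec, m)$genetic_subtotal
    expect_equal(g, brute_force_genetic(rec, m), tolerance = 1e-9)

    grown <- rec
    grown$proband_evidence <- c(grown$proband_evidence, list(
      proband_variant_evidence("extra", "predicted_or_proven_null")))
    expect_gte(genetic_subtotal(grown, m)$genetic_subtotal, g)
    expect_lte(genetic_subtotal(grown, m)$genetic_subtotal, 12)
  }
})
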
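m <- default_score_matrix()

test_that("dual curation scores both teams independently and flags band differences", {
  fx <- arvc_fixture()
  same <- dual_curation(fx$records$PKP2, fx$records$PKP2, m)
  expect_identical(same$A$preliminary$value, same$B$preliminary$value)
  expect_equal(same$point_difference, 0)

  # half-point difference within one band: same class, nonzero difference
  des <- dual_curation(fx$records$DES, fx$records_B$DES, m)
  expect_identical(des$A$preliminary$value, "moderate")
  expect_identical(des$B$preliminary$value, "moderate")
  expect_equal(des$point_difference, 0.5)

  expect_error(dual_curation(fx$records$DES, fx$records$PLN, m), "same gene")

  # different bands are visible as a class mismatch
  weak <- gene_disease_record("DES", proband_evidence = list(
    proband_variant_evidence("p", "predicted_or_proven_null")))
  mism <- dual_curation(fx$records$DES, weak, m)
  expect_false(identical(mism$A$preliminary$value, mism$B$preliminary$value))
})

test_that("scoring one team's record is blind to the other's content", {
  fx <- arvc_fixture()
  a1 <- dual_curation(fx$records$PLN, fx$records_B$PLN, m)$A
  mangled <- fx$records_B$PLN
  mangled$proband_evidence <- list()
  a2 <- dual_curation(fx$records$PLN, mangled, m)$A
  expect_identical(a1, a2)
})

test_that("concordance is counted on preliminary classes, not points", {
  fx <- arvc_fixture()
  pairs <- lapply(fx$genes, function(g)
    dual_curation(fx$records[[g]], fx$records_B[[g]], m))
  cr <- concordance_report(pairs)
  expect_equal(cr$fraction_concordant, 1.0)
  expect_true(any(cr$per_gene$point_difference != 0))  # matched despite points

  # one discordant gene out of 26
  weak <- gene_disease_record("PKP2", proband_evidence = list(
    proband_variant_evidence("p", "predicted_or_proven_null")))
  pairs[[which(fx$genes == "PKP2")]] <- dual_curation(fx$records$PKP2, weak, m)
  cr2 <- concordance_report(pairs)
  expect_equal(cr2$fraction_concordant, 25 / 26, tolerance = 1e-4)
  expect_error(concordance_report(list()), "at least one")
})

test_that("consensus applies panel flags on agreement and never resolves a mismatch", {
  fx <- arvc_fixture()
  strong_pair <- dual_curation(fx$records$PKP2, fx$records_B$PKP2, m)
  expect_identical(
    consensus_classification(strong_pair, "none", TRUE, m)$value, "definitive")
  expect_identical(
    consensus_classification(strong_pair, "none", FALSE, m)$value, "strong")

  limited_pair <- dual_curation(fx$records$RYR2, fx$records_B$RYR2, m)
  expect_identical(
    consensus_classification(limited_pair, "refuted", FALSE, m)$value, "refuted")

  weak <- gene_disease_record("DES", proband_evidence = list(
    proband_variant_evidence("p", "predicted_or_proven_null")))
  mism <- dual_curation(fx$records$DES, weak, m)
  expect_identical(consensus_classification(mism, "none", FALSE, m)$value,
                   "needs_panel_review")
})

test_that("variant-class summaries count, normalize vocabulary and tier the P/LP fractions", {
  tier <- arvc_tier_map()
  one <- data.frame(gene = "PKP2", variant_id = "v1", significance = "P")
  s <- summarize_variant_classes(one, tier)
  expect_equal(s$plp_by_tier$percent[s$plp_by_tier$tier == "desmosomal"], 100.0)

  raw <- data.frame(
    gene = c("PKP2", "PKP2", "DSP", "RYR2", "LMNA"),
    significance = c("Pathogenic", "Pathogenic/Likely pathogenic",
                     "Likely pathogenic",
                     "Conflicting interpretations of pathogenicity",
                     "Benign/Likely benign"))
  s2 <- summarize_variant_classes(raw, tier)
  expect_equal(s2$total_plp, 3L)
  expect_equal(sum(s2$counts[, "VUS"]), 1)
  expect_equal(sum(s2$counts[, "LB"]), 1)
  expect_equal(sum(s2$plp_by_tier$fraction), 1)

  expect_warning(
    s3 <- summarize_variant_classes(
      data.frame(gene = "NOTAGENE", significance = "P"), tier),
    "binned as 'other'")
  expect_equal(s3$plp_by_tier$fraction[s3$plp_by_tier$tier == "other"], 1)

  empty <- summarize_variant_classes(
    data.frame(gene = character(), significance = character()), tier)
  expect_true(empty$undefined)
  expect_error(summarize_variant_classes(
    data.frame(gene = "PKP2", significance = "odd stuff"), tier), "unmapped")
})

test_that("the full pipeline writes deterministic reports with a config checksum", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  input <- file.path(dir, "curations")
  write_arvc_fixture_dir(input)

  r1 <- run_full_curation(input, m, out1)
  expect_equal(nrow(r1$classification), 26)
  expect_equal(r1$concordance$fraction_concordant, 1.0)
  expect_match(readLines(r1$paths[["log"]])[2], matrix_checksum(m), fixed = TRUE)

  r2 <- run_full_curation(input, m, out2)
  for (nm in c("classification", "concordance", "log"))
    expect_identical(readLines(r1$paths[[nm]]), readLines(r2$paths[[nm]]))

  expect_error(run_full_curation(withr::local_tempdir(), m, out1),
               "no curation files")

  # an unpaired gene is refused
  file.copy(file.path(input, "PKP2_teamA.json"),
            file.path(input, "ZZZ_extra.json"))
  txt <- readLines(file.path(input, "ZZZ_extra.json"))
  writeLines(sub('"PKP2"', '"ZZZ"', txt), file.path(input, "ZZZ_extra.json"))
  expect_error(run_full_curation(input, m, out1), "exactly two records")
})
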
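test_that("a well-formed record validates cleanly, including empty evidence lists", {
  rec <- gene_disease_record("PKP2",
    proband_evidence = list(
      proband_variant_evidence("p1", "predicted_or_proven_null"),
      proband_variant_evidence("p2", "other_with_gene_impact",
                               de_novo = "confirmed", awarded_points = 0.5)),
    segregation_evidence = list(
      segregation_evidence("f1", informative_meioses = 8)),
    experimental_evidence = list(
      experimental_evidence_item("model_organism", phenotype_consistent = TRUE)))
  expect_identical(validate_record(rec), character(0))
  expect_identical(validate_record(gene_disease_record("DSP")), character(0))
})

test_that("validation reports out-of-range awards, exclusivity breaches and gate omissions", {
  rec <- gene_disease_record("PKP2",
    proband_evidence = list(
      proband_variant_evidence("p1", "predicted_or_proven_null",
                               awarded_points = 3.5)))
  v <- validate_record(rec)
  expect_length(v, 1)
  expect_match(v, "outside range \\[0, 3\\]")

  seg_both <- segregation_evidence("f1", informative_meioses = 4)
  seg_both$published_lod <- 2.1  # force the invalid both-supplied state
  v2 <- validate_record(gene_disease_record("DSP",
                                            segregation_evidence = list(seg_both)))
  expect_length(v2, 1)
  expect_match(v2, "exactly one of")

  item <- experimental_evidence_item("model_organism", phenotype_consistent = TRUE)
  item$phenotype_consistent <- NULL
  v3 <- validate_record(gene_disease_record("DSP",
                                            experimental_evidence = list(item)))
  expect_match(v3, "phenotype_consistent is required")

  # off-grid awards are flagged
  v4 <- validate_record(gene_disease_record("DSP", proband_evidence = list(
    proband_variant_evidence("p1", "predicted_or_proven_null",
                             awarded_points = 1.23))))
  expect_match(v4, "0.05 grid")
})

test_that("validation is order-independent over evidence lists", {
  rec <- gene_disease_record("DSG2",
    proband_evidence = list(
      proband_variant_evidence("a", "predicted_or_proven_null", awarded_points = 9),
      proband_variant_evidence("b", "other_with_gene_impact", awarded_points = 2)))
  rec_rev <- rec
  rec_rev$proband_evidence <- rev(rec$proband_evidence)
  strip_index <- function(v) sort(sub("\\[\\d+\\]", "", v))
  expect_identical(strip_index(validate_record(rec)),
                   strip_index(validate_record(rec_rev)))
  expect_length(validate_record(rec), 2)
})

test_that("save/load round-trips records identically and byte-stably", {
  fx <- arvc_fixture()
  for (g in c("PKP2", "DES", "CTNNA3", "ACTC1")) {
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    save_curation(fx$records[[g]], p1)
    rec2 <- load_curation(p1)
    expect_identical(rec2, fx$records[[g]])
    save_curation(rec2, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("YAML curation files are accepted on input", {
  rec <- arvc_fixture()$records$TJP1
  jp <- withr::local_tempfile(fileext = ".json")
  yp <- withr::local_tempfile(fileext = ".yaml")
  save_curation(rec, jp)
  yaml::write_yaml(jsonlite::fromJSON(jp, simplifyVector = FALSE), yp)
  expect_identical(load_curation(yp), rec)
})

test_that("malformed files, unknown schema versions and invalid records are refused", {
  p <- withr::local_tempfile(fileext = ".json")
  rec <- arvc_fixture()$records$PLN
  save_curation(rec, p)

  txt <- readLines(p)
  writeLines(txt[1:(length(txt) %/% 2)], p)  # truncate mid-object
  expect_error(load_curation(p), "cannot parse")

  save_curation(rec, p)
  plain <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  plain$schema_version <- "arvc-curation/99"
  jsonlite::write_json(plain, p, auto_unbox = TRUE)
  expect_error(load_curation(p), "schema version")

  bad <- gene_disease_record("PKP2", proband_evidence = list(
    proband_variant_evidence("p", "predicted_or_proven_null", awarded_points = 99)))
  expect_error(save_curation(bad, p), "refusing to write")
  expect_error(load_curation(withr::local_tempfile(fileext = ".json")),
               "no such curation file")
})
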
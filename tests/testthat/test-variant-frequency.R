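test_that("the maximum credible allele frequency follows the disease parameters", {
  expect_equal(max_credible_af(frequency_params(1 / 1000, 0.1, 0.5, 0.5)), 1e-4)
  # with one fully penetrant variant causing all cases, the bound is prevalence/2
  p <- 1 / 5000
  expect_equal(max_credible_af(frequency_params(p, 1, 1, 0.5)), p / 2)
  base <- max_credible_af(frequency_params(1 / 1000, 0.1, 0.5, 0.5))
  expect_equal(max_credible_af(frequency_params(1 / 1000, 0.1, 0.25, 0.5)), 2 * base)
  expect_equal(max_credible_af(frequency_params(2 / 1000, 0.1, 0.5, 0.5)), 2 * base)
  expect_equal(max_credible_af(frequency_params(1 / 1000, 0.2, 0.5, 0.5)), 2 * base)
  expect_error(frequency_params(penetrance = 0), "\\(0, 1\\]")
  expect_error(frequency_params(prevalence = 1.5), "\\(0, 1\\]")
})

test_that("the filtering allele frequency inverts the Poisson tail", {
  expect_equal(filtering_allele_frequency(0, 5000), 0)
  expect_equal(filtering_allele_frequency(5, 10000, 0.95), 1.970e-4,
               tolerance = 1e-6 / 1.970e-4)
  # dual route: bisection over the ppois tail, independent of qgamma
  cases <- expand.grid(ac = c(1, 2, 5, 20, 100), an = c(1000, 150000),
                       conf = c(0.9, 0.95, 0.99))
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      filtering_allele_frequency(cases$ac[i], cases$an[i], cases$conf[i]),
      faf_bisect_oracle(cases$ac[i], cases$an[i], cases$conf[i]),
      tolerance = 1e-8)
  }
  mono <- filtering_allele_frequency(100, 100)
  expect_gt(mono, 0); expect_lt(mono, 1)
  expect_error(filtering_allele_frequency(3, 0), "positive")
  expect_error(filtering_allele_frequency(5, 4), "allele count")
})

test_that("the filtering AF is monotone in AC, AN and confidence", {
  for (ac in c(1, 4, 30)) {
    expect_gt(filtering_allele_frequency(ac + 1, 10000),
              filtering_allele_frequency(ac, 10000))
    expect_gt(filtering_allele_frequency(ac, 5000),
              filtering_allele_frequency(ac, 10000))
    expect_gt(filtering_allele_frequency(ac, 10000, 0.90),
              filtering_allele_frequency(ac, 10000, 0.99))
  }
})

test_that("variant assessment passes absent variants and fails common ones on the worst population", {
  params <- frequency_params()  # threshold 1e-4
  absent <- list(population_frequency("African", 0, 16000),
                 population_frequency("European (non-Finnish)", 0, 64000),
                 population_frequency("East Asian", 0, 9000))
  a <- assess_variant(absent, params)
  expect_true(a$passes)
  expect_equal(a$filtering_af, 0)

  # common in Europeans while rare globally: fails, naming Europeans
  eu_common <- list(population_frequency("global", 40, 280000),
                    population_frequency("European (non-Finnish)", 60, 60000))
  b <- assess_variant(eu_common, params)
  expect_false(b$passes)
  expect_identical(b$worst_population, "European (non-Finnish)")
  expect_gt(b$filtering_af, b$threshold)

  # permutation invariance
  expect_equal(assess_variant(rev(eu_common), params)$filtering_af,
               b$filtering_af)

  # dropping a non-worst population cannot flip a failure to a pass
  expect_false(assess_variant(eu_common[2], params)$passes)
})

test_that("underpowered populations are ignored or flagged undetermined; founder variants are exempt", {
  params <- frequency_params()
  pops <- list(population_frequency("tiny isolate", 10, 200),
               population_frequency("European (non-Finnish)", 0, 50000))
  a <- assess_variant(pops, params, min_allele_number = 2000)
  expect_true(a$passes)  # the 200-allele isolate is below the AN floor

  u <- assess_variant(list(population_frequency("tiny isolate", 10, 200)),
                      params, min_allele_number = 2000)
  expect_true(u$undetermined)
  expect_true(is.na(u$passes))

  f <- assess_variant(pops, params, founder_exempt = TRUE)
  expect_true(f$passes)
  expect_match(f$reason, "founder")
})

test_that("population-frequency tables round-trip from TSV", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    variant_id = c("NM_024334.3:c.1073C>T", "NM_024334.3:c.1073C>T", "X:c.1A>G"),
    population = c("European (non-Finnish)", "African", "global"),
    AC = c(12L, 0L, 3L), AN = c(60000L, 16000L, 250000L))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  freqs <- read_population_frequencies(tsv)
  expect_named(freqs, sort(unique(df$variant_id)), ignore.order = TRUE)
  expect_length(freqs[["NM_024334.3:c.1073C>T"]], 2)
  expect_s3_class(freqs[["X:c.1A>G"]][[1]], "population_frequency")
  a <- assess_variant(freqs[["X:c.1A>G"]], frequency_params())
  expect_s3_class(a, "frequency_assessment")
})
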
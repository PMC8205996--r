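#' Disease parameters for the allele-frequency cutoff
#'
#' The maximum credible population allele frequency for a pathogenic
#' variant follows from disease prevalence, the largest fraction of cases
#' attributable to any single variant (allelic heterogeneity), penetrance,
#' and an inheritance factor converting affected genotypes to allele counts
#' (0.5 for monoallelic dominant disease).  The shipped ARVC defaults
#' (prevalence 1/1000, contribution 0.1, penetrance 0.5, factor 0.5) are
#' configuration, not ground truth, and every run should log the values
#' used.
#'
#' @param prevalence disease prevalence, cases per individual, in `(0, 1]`.
#' @param max_allelic_contribution largest fraction of cases attributable
#'   to one variant, in `(0, 1]`.
#' @param penetrance fraction of carriers affected, in `(0, 1]`.
#' @param inheritance_factor alleles per affected genotype, in `(0, 1]`.
#' @return An object of class `frequency_params`.
#' @export
frequency_params <- function(prevalence = 1 / 1000,
                             max_allelic_contribution = 0.1,
                             penetrance = 0.5,
                             inheritance_factor = 0.5) {
  p <- list(prevalence = prevalence,
            max_allelic_contribution = max_allelic_contribution,
            penetrance = penetrance,
            inheritance_factor = inheritance_factor)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0 || x > 1,
                logical(1))
  if (any(bad))
    stop("frequency parameters must lie in (0, 1]: ",
         paste(names(p)[bad], collapse = ", "))
  structure(p, class = "frequency_params")
}

#' Maximum credible population allele frequency
#'
#' `prevalence * max_allelic_contribution * inheritance_factor / penetrance`:
#' the highest allele frequency compatible with the variant causing a
#' disease of the given prevalence, allelic heterogeneity and penetrance.
#' Linear in prevalence and contribution; inversely proportional to
#' penetrance.
#'
#' @param params a [frequency_params()].
#' @return Allele frequency threshold (scalar).
#' @export
#' @examples
#' max_credible_af(frequency_params(1 / 1000, 0.1, 0.5, 0.5))  # 1e-4
max_credible_af <- function(params = frequency_params()) {
  if (params$penetrance <= 0) stop("penetrance must be positive")
  params$prevalence * params$max_allelic_contribution *
    params$inheritance_factor / params$penetrance
}

#' Filtering allele frequency (confidence-bounded observed frequency)
#'
#' One-sided lower confidence bound on the true population allele
#' frequency given `ac` observed alleles among `an` sampled: the rate
#' `lambda` solving `P(X >= ac | Poisson(lambda)) = 1 - confidence`,
#' returned as `lambda / an`.  With no observations the bound is 0.  A
#' variant is filtered only when even this conservative lower bound exceeds
#' the credible threshold, so rare chance observations in small reference
#' panels do not exclude a genuinely rare variant.
#'
#' Computed through the Poisson/gamma tail identity
#' `P(X >= ac | lambda) = P(Gamma(ac, 1) <= lambda)`, i.e.
#' `lambda = qgamma(1 - confidence, shape = ac)`.
#'
#' @param ac observed allele count (nonnegative integer).
#' @param an allele number sampled (positive integer).
#' @param confidence one-sided confidence level in `(0, 1)`.
#' @return Allele frequency bound (scalar).
#' @export
#' @examples
#' filtering_allele_frequency(5, 10000)  # ~1.97e-4
filtering_allele_frequency <- function(ac, an, confidence = 0.95) {
  if (an <= 0) stop("allele number must be positive")
  if (ac < 0 || ac > an) stop("allele count must lie in [0, allele number]")
  if (confidence <= 0 || confidence >= 1) stop("confidence must lie in (0, 1)")
  if (ac == 0) return(0)
  stats::qgamma(1 - confidence, shape = ac) / an
}

#' Population allele counts for one variant
#'
#' @param population_label population name (e.g. "European (non-Finnish)").
#' @param allele_count nonnegative observed allele count.
#' @param allele_number positive total alleles sampled.
#' @return An object of class `population_frequency`.
#' @export
population_frequency <- function(population_label, allele_count, allele_number) {
  allele_count <- as.integer(allele_count)
  allele_number <- as.integer(allele_number)
  if (allele_number <= 0) stop("allele_number must be positive")
  if (allele_count < 0 || allele_count > allele_number)
    stop("allele_count must lie in [0, allele_number]")
  structure(list(population_label = as.character(population_label),
                 allele_count = allele_count, allele_number = allele_number),
            class = "population_frequency")
}

#' Assess a candidate variant's allele-frequency admissibility
#'
#' The filtering allele frequency is taken as the maximum of the
#' per-population confidence bounds over populations with adequate coverage
#' (`allele_number >= min_allele_number`); the variant passes iff that
#' bound does not exceed the maximum credible frequency.  A variant can
#' therefore fail on one well-sampled subpopulation (for ARVC typically
#' Europeans) even when its global frequency looks acceptable.  Declared
#' founder variants bypass the filter with a logged justification.
#'
#' @param popfreqs list of [population_frequency()] records (at least one).
#' @param params a [frequency_params()].
#' @param confidence one-sided confidence for the frequency bound.
#' @param min_allele_number minimum alleles sampled for a population to
#'   count; smaller populations are ignored.  If no population qualifies
#'   the assessment is returned with `undetermined = TRUE`.
#' @param founder_exempt the variant is a recognized founder allele; the
#'   filter is bypassed.
#' @return An object of class `frequency_assessment` with fields
#'   `threshold`, `filtering_af`, `worst_population`, `passes`,
#'   `undetermined` and `reason`.
#' @export
assess_variant <- function(popfreqs, params = frequency_params(),
                           confidence = 0.95, min_allele_number = 2000,
                           founder_exempt = FALSE) {
  if (!length(popfreqs)) stop("at least one population record is required")
  threshold <- max_credible_af(params)
  if (founder_exempt) {
    return(structure(list(
      threshold = threshold, filtering_af = NA_real_,
      worst_population = NA_character_, passes = TRUE, undetermined = FALSE,
      reason = "founder variant: frequency filter bypassed by declared exemption"),
      class = "frequency_assessment"))
  }
  an <- vapply(popfreqs, function(p) p$allele_number, numeric(1))
  keep <- an >= min_allele_number
  if (!any(keep)) {
    return(structure(list(
      threshold = threshold, filtering_af = NA_real_,
      worst_population = NA_character_, passes = NA, undetermined = TRUE,
      reason = sprintf(
        "no population reaches min_allele_number %d; frequency admissibility undetermined",
        as.integer(min_allele_number))),
      class = "frequency_assessment"))
  }
  faf <- vapply(popfreqs[keep], function(p)
    filtering_allele_frequency(p$allele_count, p$allele_number, confidence),
    numeric(1))
  worst <- which.max(faf)
  worst_pop <- popfreqs[keep][[worst]]$population_label
  passes <- faf[worst] <= threshold
  structure(list(
    threshold = threshold, filtering_af = faf[worst],
    worst_population = worst_pop, passes = passes, undetermined = FALSE,
    reason = if (passes) {
      sprintf("filtering AF %.3g in worst population '%s' within threshold %.3g",
              faf[worst], worst_pop, threshold)
    } else {
      sprintf("filtering AF %.3g in population '%s' exceeds threshold %.3g",
              faf[worst], worst_pop, threshold)
    }), class = "frequency_assessment")
}

#' Read a population-frequency table from TSV
#'
#' Expected columns: `variant_id`, `population`, `AC`, `AN` (gnomAD-style
#' allele count/number per population).
#'
#' @param path TSV file path.
#' @return Named list: for each variant id, a list of
#'   [population_frequency()] records.
#' @export
read_population_frequencies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "population", "AC", "AN")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("frequency table lacks columns: ", paste(missing, collapse = ", "))
  lapply(split(df, df$variant_id), function(rows)
    lapply(seq_len(nrow(rows)), function(i)
      population_frequency(rows$population[i], rows$AC[i], rows$AN[i])))
}

#' @export
print.frequency_assessment <- function(x, ...) {
  status <- if (isTRUE(x$undetermined)) "UNDETERMINED"
            else if (isTRUE(x$passes)) "PASS" else "FAIL"
  cat(sprintf("<frequency_assessment> %s\n  %s\n", status, x$reason))
  invisible(x)
}
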
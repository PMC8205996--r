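# Synthetic evidence generators.  The expected breakdowns are produced by
# an independent tally (plain running sums with caps applied once at the
# end, and a literal transcription of the LOD bins) that deliberately
# shares no code with the scoring modules, so it can serve as an oracle
# for them.

# decompose a grid total x into awards each in (0, unit]; returns numeric(0)
# for x == 0
split_awards <- function(x, unit) {
  if (x <= 0) return(numeric(0))
  n_full <- floor(round(x / unit, 6))
  rem <- round_points(x - n_full * unit)
  out <- rep(unit, n_full)
  if (rem > 0) out <- c(out, rem)
  out
}

# independent tally over raw drawn values; caps applied once at the end
tally_breakdown <- function(null_awards, other_awards, denovo_awards,
                            seg_lods, cc_awards, exp_df) {
  vn <- min(sum(null_awards), 10)
  vo <- min(sum(other_awards), 7)
  vd <- min(sum(denovo_awards), 10)
  variant <- min(vn + vo + vd, 12)
  lod <- sum(seg_lods)
  seg <- if (lod >= 5) 3 else if (lod >= 3) 2 else if (lod >= 2) 1 else 0
  seg <- min(seg, 3)
  cc <- min(sum(cc_awards), 12)
  genetic <- min(variant + seg + cc, 12)

  award <- exp_df$award
  award[exp_df$gated] <- 0          # inconsistent model/rescue phenotype
  grp <- function(g) min(sum(award[exp_df$group == g]), switch(g,
    "function" = 2, functional_alteration = 2, models_rescue = 4))
  experimental <- min(grp("function") + grp("functional_alteration") +
                        grp("models_rescue"), 6)
  list(genetic_subtotal = round_points(genetic),
       experimental_subtotal = round_points(experimental),
       total = round_points(genetic + experimental))
}

band_of <- function(total, replicated) {
  if (total == 0) "no_known_relationship"
  else if (total < 7) "limited"
  else if (total < 12) "moderate"
  else if (replicated) "definitive" else "strong"
}

#' Generate a synthetic curation with a known expected breakdown
#'
#' Draws evidence items (counts and award values on the 0.05 grid within
#' the matrix ranges) whose generator-side tally lands in the requested
#' classification band.  The expected breakdown is computed by the
#' generator's own independent tally, never by the scoring modules, so it
#' is a valid oracle for them.  Reproducible per seed.
#'
#' @param seed integer seed.
#' @param target_class target band: `"no_known_relationship"`, `"limited"`,
#'   `"moderate"`, `"strong"` or `"definitive"` (overrides are panel-level
#'   and not generated).
#' @param matrix a `score_matrix` (used only for its ranges).
#' @return An object of class `synthetic_curation`: `record`, `expected`
#'   (genetic subtotal, experimental subtotal, total, classification) and
#'   `seed`.
#' @export
#' @examples
#' sc <- generate_curation(1, "moderate")
#' sc$expected$total                       # in [7, 12)
#' score_record(sc$record)$total == sc$expected$total
generate_curation <- function(seed,
                              target_class = c("limited", "moderate", "strong",
                                               "definitive",
                                               "no_known_relationship"),
                              matrix = default_score_matrix()) {
  target_class <- match.arg(target_class)
  set.seed(as.integer(seed))
  replicated <- target_class == "definitive"

  if (target_class == "no_known_relationship") {
    rec <- gene_disease_record("GENE_SYN", replicated_over_time = FALSE,
                               curator_id = sprintf("synthetic-%d", seed))
    expected <- list(genetic_subtotal = 0, experimental_subtotal = 0,
                     total = 0, classification = "no_known_relationship")
    return(structure(list(record = rec, expected = expected, seed = seed),
                     class = "synthetic_curation"))
  }

  grid_pick <- function(lo, hi) round_points(stats::runif(1, lo, hi))
  # target total uniform on the band's 0.05 grid (interior, so rounding
  # never crosses a band edge)
  total <- switch(target_class,
    limited = grid_pick(0.1, 6.9),
    moderate = grid_pick(7, 11.9),
    strong = grid_pick(12, 17.5),
    definitive = grid_pick(12, 17.5))

  # split total into experimental (<= 6) and genetic (<= 12) parts
  e_lo <- max(0, total - 12)
  e_hi <- min(6, total)
  exp_total <- round_points(stats::runif(1, e_lo, e_hi))
  gen_total <- round_points(total - exp_total)

  # genetic composition: segregation bin, case-control, rest as variants
  seg_pts_opts <- c(0, 1, 2, 3)
  seg_pts_opts <- seg_pts_opts[seg_pts_opts <= gen_total]
  seg_pts <- seg_pts_opts[sample.int(length(seg_pts_opts), 1)]
  cc_max <- min(6, gen_total - seg_pts)
  cc_total <- if (cc_max > 0 && stats::runif(1) < 0.6)
    round_points(stats::runif(1, 0, cc_max)) else 0
  v_total <- round_points(gen_total - seg_pts - cc_total)  # <= 12
  null_sum <- min(v_total, 10)
  other_sum <- round_points(v_total - null_sum)            # <= 2
  null_awards <- split_awards(null_sum, 1.5)
  other_awards <- split_awards(other_sum, 1.5)
  cc_awards <- split_awards(cc_total, 6)

  seg_lods <- if (seg_pts == 0) numeric(0) else {
    lod <- switch(as.character(seg_pts), "1" = 2.5, "2" = 3.5, "3" = 6)
    if (stats::runif(1) < 0.5) lod else {
      # equivalent meiosis counts landing in the same bin
      n <- switch(as.character(seg_pts), "1" = sample(7:9, 1),
                  "2" = sample(10:16, 1), "3" = sample(17:25, 1))
      attr(n, "as_meioses") <- TRUE
      n
    }
  }

  # experimental composition across groups (function <= 2, functional
  # alteration <= 2, models & rescue <= 4)
  repeat {
    f <- round_points(stats::runif(1, 0, min(2, exp_total)))
    fa <- round_points(stats::runif(1, 0, min(2, exp_total - f)))
    mr <- round_points(exp_total - f - fa)
    if (mr <= 4) break
  }
  exp_df <- data.frame(category = character(), award = numeric(),
                       group = character(), gated = logical(),
                       stringsAsFactors = FALSE)
  add_exp <- function(category, award, group, gated = FALSE) {
    exp_df <<- rbind(exp_df, data.frame(category = category, award = award,
                                        group = group, gated = gated,
                                        stringsAsFactors = FALSE))
  }
  if (f > 0) add_exp("expression", f, "function")
  if (fa > 0) add_exp("functional_alteration_patient_cells", fa,
                      "functional_alteration")
  if (mr > 0) add_exp("model_organism", mr, "models_rescue")
  if (stats::runif(1) < 0.3)  # exercise the phenotype gate; contributes 0
    add_exp("cell_culture_model", grid_pick(0.05, 2), "models_rescue",
            gated = TRUE)

  expected_tally <- tally_breakdown(
    null_awards, other_awards, numeric(0),
    if (length(seg_lods)) {
      if (isTRUE(attr(seg_lods, "as_meioses"))) as.numeric(seg_lods) * log10(2)
      else as.numeric(seg_lods)
    } else numeric(0),
    cc_awards, exp_df)
  expected <- c(expected_tally,
                list(classification = band_of(expected_tally$total, replicated)))

  probands <- c(
    lapply(seq_along(null_awards), function(i)
      proband_variant_evidence(sprintf("null-%d", i), "predicted_or_proven_null",
                               awarded_points = null_awards[i])),
    lapply(seq_along(other_awards), function(i)
      proband_variant_evidence(sprintf("other-%d", i), "other_with_gene_impact",
                               awarded_points = other_awards[i])))
  segs <- if (!length(seg_lods)) list() else if (isTRUE(attr(seg_lods, "as_meioses"))) {
    list(segregation_evidence("fam-1", informative_meioses = as.integer(seg_lods)))
  } else {
    list(segregation_evidence("fam-1", published_lod = as.numeric(seg_lods)))
  }
  ccs <- lapply(seq_along(cc_awards), function(i)
    case_control_evidence(sprintf("study-%d", i), "aggregate",
                          awarded_points = cc_awards[i]))
  exps <- lapply(seq_len(nrow(exp_df)), function(i)
    experimental_evidence_item(
      exp_df$category[i],
      phenotype_consistent = if (is_model_or_rescue(exp_df$category[i]))
        !exp_df$gated[i],
      awarded_points = exp_df$award[i]))

  rec <- gene_disease_record(
    "GENE_SYN",
    proband_evidence = probands, segregation_evidence = segs,
    case_control_evidence = ccs, experimental_evidence = exps,
    replicated_over_time = replicated,
    curator_id = sprintf("synthetic-%d", seed))
  structure(list(record = rec, expected = expected, seed = seed),
            class = "synthetic_curation")
}

#' Simulate a family's segregation evidence
#'
#' Emits one family with a known count of informative meioses and its true
#' LOD under the counting approximation.  A noise fraction marks that
#' share of meioses uninformative (e.g. ungenotyped relatives); they are
#' excluded from the count.
#'
#' @param seed integer seed.
#' @param n_meioses total meioses in the family (nonnegative).
#' @param noise_fraction fraction of meioses that are uninformative.
#' @param sequencing_approach passed to [segregation_evidence()].
#' @return List with `evidence` (a [segregation_evidence()]),
#'   `informative_meioses` and `true_lod`.
#' @export
simulate_segregation <- function(seed, n_meioses, noise_fraction = 0,
                                 sequencing_approach = "candidate_gene") {
  stopifnot(n_meioses >= 0, noise_fraction >= 0, noise_fraction <= 1)
  set.seed(as.integer(seed))
  informative <- if (noise_fraction == 0) as.integer(n_meioses)
  else if (noise_fraction == 1) 0L
  else stats::rbinom(1, n_meioses, 1 - noise_fraction)
  list(evidence = segregation_evidence(sprintf("simfam-%d", seed),
                                       informative_meioses = informative,
                                       sequencing_approach = sequencing_approach),
       informative_meioses = informative,
       true_lod = informative * log10(2))
}

#' Generate a variant table with specified per-gene class counts
#'
#' @param spec nested named list, gene -> significance class -> count.
#' @param seed integer seed used to shuffle row order.
#' @return Data frame with columns `gene`, `variant_id`, `significance`,
#'   holding exactly the requested counts.
#' @export
#' @examples
#' generate_variant_table(list(PKP2 = list(P = 3)), seed = 1)
generate_variant_table <- function(spec, seed = 1) {
  set.seed(as.integer(seed))
  rows <- list()
  for (gene in names(spec)) {
    for (cls in names(spec[[gene]])) {
      n <- spec[[gene]][[cls]]
      stopifnot(n >= 0)
      if (n > 0)
        rows[[length(rows) + 1]] <- data.frame(
          gene = gene,
          variant_id = sprintf("%s:synthetic_%s_%03d", gene, cls, seq_len(n)),
          significance = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), variant_id = character(),
                      significance = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[sample(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.synthetic_curation <- function(x, ...) {
  cat(sprintf("<synthetic_curation> seed %d: expected total %g (%s)\n",
              x$seed, x$expected$total, x$expected$classification))
  invisible(x)
}
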
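# Independent oracles, re-derived here so they share no code path with the
# package internals they check.

# plain summation of genetic evidence, caps applied once at the end
brute_force_genetic <- function(record, m = default_score_matrix()) {
  pts <- c(predicted_or_proven_null = 0, other_with_gene_impact = 0,
           other_de_novo = 0, ar_biallelic_null = 0, ar_biallelic_other = 0)
  for (ev in record$proband_evidence) {
    cat_name <- if (record$inheritance == "AR") {
      if (ev$variant_class == "predicted_or_proven_null") "ar_biallelic_null"
      else "ar_biallelic_other"
    } else if (ev$variant_class == "predicted_or_proven_null") {
      "predicted_or_proven_null"
    } else if (ev$de_novo != "none") "other_de_novo" else "other_with_gene_impact"
    award <- if (is.null(ev$awarded_points))
      m$genetic$variant$categories[[cat_name]]$default else ev$awarded_points
    pts[cat_name] <- pts[cat_name] + award
  }
  caps <- vapply(m$genetic$variant$categories, function(c) c$cap, numeric(1))
  variant <- min(sum(pmin(pts, caps[names(pts)])), m$genetic$variant$overall_cap)

  lod <- c(candidate_gene = 0, exome_genome = 0)
  for (seg in record$segregation_evidence) {
    l <- if (!is.null(seg$published_lod)) seg$published_lod
         else seg$informative_meioses * log10(2)
    lod[seg$sequencing_approach] <- lod[seg$sequencing_approach] + l
  }
  bin <- function(l, half) {
    p <- if (l >= 5) 3 else if (l >= 3) 2 else if (l >= 2) 1 else 0
    if (half) p / 2 else p
  }
  seg_pts <- min(bin(lod[["candidate_gene"]], FALSE) +
                   bin(lod[["exome_genome"]], TRUE), 3)

  cc <- 0
  for (s in record$case_control_evidence) cc <- cc + s$awarded_points
  cc <- min(cc, 12)
  min(variant + seg_pts + cc, 12)
}

# plain summation of experimental evidence with the phenotype gate
brute_force_experimental <- function(items, m = default_score_matrix()) {
  grp <- c("function" = 0, functional_alteration = 0, models_rescue = 0)
  for (item in items) {
    cfg <- m$experimental$categories[[item$category]]
    gated <- grepl("model|rescue|cell_culture", item$category) &&
      !isTRUE(item$phenotype_consistent)
    award <- if (gated) 0
      else if (is.null(item$awarded_points)) cfg$default else item$awarded_points
    grp[cfg$group] <- grp[cfg$group] + award
  }
  min(min(grp[["function"]], 2) + min(grp[["functional_alteration"]], 2) +
        min(grp[["models_rescue"]], 4), 6)
}

# invert the Poisson tail P(X >= ac | lambda) = 1 - conf by bisection
faf_bisect_oracle <- function(ac, an, confidence) {
  if (ac == 0) return(0)
  f <- function(lam) (1 - ppois(ac - 1, lam)) - (1 - confidence)
  lo <- 0; hi <- ac * 10 + 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 / an
}

# a random valid record with <= n_items evidence items, awards on the grid
random_small_record <- function(seed, n_items = 6) {
  set.seed(seed)
  n <- sample(0:n_items, 1)
  kinds <- if (n) sample(c("null", "other", "denovo", "seg", "cc", "exp"),
                         n, replace = TRUE) else character()
  probands <- list(); segs <- list(); ccs <- list(); exps <- list()
  grid <- function(lo, hi) round(runif(1, lo, hi) * 20) / 20
  for (i in seq_along(kinds)) {
    k <- kinds[i]
    if (k == "null") probands[[length(probands) + 1]] <-
      proband_variant_evidence(paste0("p", i), "predicted_or_proven_null",
                               awarded_points = grid(0, 3))
    else if (k == "other") probands[[length(probands) + 1]] <-
      proband_variant_evidence(paste0("p", i), "other_with_gene_impact",
                               awarded_points = grid(0, 1.5))
    else if (k == "denovo") probands[[length(probands) + 1]] <-
      proband_variant_evidence(paste0("p", i), "other_with_gene_impact",
                               de_novo = "confirmed", awarded_points = grid(0, 3))
    else if (k == "seg") segs[[length(segs) + 1]] <-
      if (runif(1) < 0.5)
        segregation_evidence(paste0("f", i),
                             informative_meioses = sample(0:20, 1),
                             sequencing_approach = sample(c("candidate_gene",
                                                            "exome_genome"), 1))
      else segregation_evidence(paste0("f", i), published_lod = runif(1, 0, 7))
    else if (k == "cc") ccs[[length(ccs) + 1]] <-
      case_control_evidence(paste0("s", i), "aggregate",
                            awarded_points = grid(0, 6))
    else {
      cat_name <- sample(c("biochemical_function", "expression",
                           "functional_alteration_patient_cells",
                           "model_organism", "rescue_model_organism",
                           "cell_culture_model"), 1)
      m <- default_score_matrix()$experimental$categories[[cat_name]]
      is_mr <- !m$group %in% c("function", "functional_alteration")
      exps[[length(exps) + 1]] <- experimental_evidence_item(
        cat_name,
        phenotype_consistent = if (is_mr) runif(1) < 0.8,
        awarded_points = grid(m$range[1], m$range[2]))
    }
  }
  gene_disease_record("SYNGENE", proband_evidence = probands,
                      segregation_evidence = segs,
                      case_control_evidence = ccs,
                      experimental_evidence = exps)
}
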
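#' Blinded dual curation of a gene-disease pair
#'
#' Scores two independently curated records of the same gene-disease pair;
#' no information flows between them (each is scored exactly as
#' [score_record()] would score it alone).
#'
#' @param record_A,record_B [gene_disease_record()]s for the same gene.
#' @param matrix a `score_matrix`.
#' @return An object of class `dual_curation`: `gene`, per-team
#'   `score_breakdown`s `A` and `B`, and `point_difference`
#'   (total A - total B).
#' @export
dual_curation <- function(record_A, record_B, matrix = default_score_matrix()) {
  if (!identical(record_A$gene_symbol, record_B$gene_symbol))
    stop("dual curation requires the same gene: got '",
         record_A$gene_symbol, "' and '", record_B$gene_symbol, "'")
  a <- score_record(record_A, matrix)
  b <- score_record(record_B, matrix)
  structure(list(gene = record_A$gene_symbol, A = a, B = b,
                 point_difference = round_points(a$total - b$total)),
            class = "dual_curation")
}

#' Concordance report over dual-curation results
#'
#' Concordance is defined on preliminary classifications, not raw points:
#' two teams that award slightly different points within the same band
#' still concord.  Point differences are reported alongside but do not
#' affect the match flag.
#'
#' @param pairs list of [dual_curation()] results (at least one).
#' @return An object of class `concordance_report`: `per_gene` (data frame
#'   with gene, class_A, class_B, match, point_difference) and
#'   `fraction_concordant`.
#' @export
concordance_report <- function(pairs) {
  if (!length(pairs)) stop("at least one dual-curation pair is required")
  per_gene <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(gene = p$gene,
               class_A = p$A$preliminary$value,
               class_B = p$B$preliminary$value,
               match = identical(p$A$preliminary$value, p$B$preliminary$value),
               point_difference = p$point_difference,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_gene = per_gene,
                 fraction_concordant = mean(per_gene$match)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Dual-curation concordance: %d/%d genes (%.1f%%)\n",
              sum(x$per_gene$match), nrow(x$per_gene),
              100 * x$fraction_concordant))
  mism <- x$per_gene[!x$per_gene$match, , drop = FALSE]
  if (nrow(mism)) {
    cat("  discordant:\n")
    for (i in seq_len(nrow(mism)))
      cat(sprintf("    %s: %s vs %s\n", mism$gene[i], mism$class_A[i],
                  mism$class_B[i]))
  }
  invisible(x)
}

#' Panel consensus classification for a dual-curated gene
#'
#' When the two preliminary classifications agree, the consensus is that
#' class with the panel-level flags applied: a Disputed/Refuted override
#' wins outright, and a Strong consensus with replication across cohorts is
#' upgraded to Definitive.  A preliminary mismatch is never silently
#' resolved; it returns `needs_panel_review`.
#'
#' @param pair a [dual_curation()] result.
#' @param panel_override `"none"`, `"disputed"` or `"refuted"`.
#' @param panel_replicated panel judgment of replication over time.
#' @param matrix a `score_matrix`.
#' @return A `gene_validity_class` (value `needs_panel_review` on
#'   mismatch).
#' @export
consensus_classification <- function(pair, panel_override = "none",
                                     panel_replicated = FALSE,
                                     matrix = default_score_matrix()) {
  panel_override <- match.arg(panel_override, OVERRIDES)
  if (!identical(pair$A$preliminary$value, pair$B$preliminary$value))
    return(new_classification("needs_panel_review", pair$A$total,
                              preliminary = FALSE))
  classify(pair$A$total, panel_replicated, panel_override, matrix)
}

## ---- ClinVar-style variant-class summaries ---------------------------------

SIGNIFICANCE_CLASSES <- c("P", "LP", "VUS", "B", "LB")

# ClinVar exports vary; this mapping is deliberately explicit configuration.
# Combined P/LP rows are binned as LP (the more conservative of the pair);
# conflicting interpretations are binned as VUS.
default_significance_map <- function() c(
  "P" = "P", "Pathogenic" = "P",
  "LP" = "LP", "Likely pathogenic" = "LP",
  "Pathogenic/Likely pathogenic" = "LP",
  "VUS" = "VUS", "Uncertain significance" = "VUS",
  "Conflicting interpretations of pathogenicity" = "VUS",
  "B" = "B", "Benign" = "B",
  "LB" = "LB", "Likely benign" = "LB",
  "Benign/Likely benign" = "LB")

normalize_significance <- function(x, map = default_significance_map()) {
  out <- unname(map[x])
  if (anyNA(out))
    stop("unmapped clinical significance value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Summarize a variant table by gene, significance class and evidence tier
#'
#' Counts variants per gene and significance class (`P`, `LP`, `VUS`, `B`,
#' `LB`, after vocabulary normalization) and computes, for each evidence
#' tier in `tier_map`, the fraction of all P/LP variants falling in that
#' tier.  Genes absent from `tier_map` are binned as `"other"` with a
#' warning.
#'
#' @param table data frame with columns `gene` and `significance` (a
#'   `variant_id` column is carried along if present); see
#'   [read_variant_table()].
#' @param tier_map named character vector mapping gene symbol to evidence
#'   tier.
#' @param significance_map vocabulary normalization map (named character
#'   vector raw -> {P, LP, VUS, B, LB}).
#' @return An object of class `variant_class_summary`: `counts` (gene x
#'   class table), `tier_map`, `plp_by_tier` (data frame with tier, P/LP
#'   count, fraction and percent to one decimal), `total_plp`, and an
#'   `undefined` flag when the table holds no P/LP variants.
#' @export
summarize_variant_classes <- function(table, tier_map,
                                      significance_map = default_significance_map()) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) {
    return(structure(list(
      counts = table(factor(character(), levels = character()),
                     factor(character(), levels = SIGNIFICANCE_CLASSES)),
      tier_map = tier_map,
      plp_by_tier = data.frame(tier = character(), plp = integer(),
                               fraction = numeric(), percent = numeric()),
      total_plp = 0L, undefined = TRUE), class = "variant_class_summary"))
  }
  need <- c("gene", "significance")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  sig <- factor(normalize_significance(table$significance, significance_map),
                levels = SIGNIFICANCE_CLASSES)
  unknown <- setdiff(unique(table$gene), names(tier_map))
  if (length(unknown)) {
    warning("genes absent from tier_map binned as 'other': ",
            paste(unknown, collapse = ", "))
    tier_map <- c(tier_map, stats::setNames(rep("other", length(unknown)), unknown))
  }
  counts <- table(gene = table$gene, class = sig)
  tier <- factor(unname(tier_map[table$gene]), levels = unique(unname(tier_map)))
  is_plp <- sig %in% c("P", "LP")
  total_plp <- sum(is_plp)
  plp_by_tier_counts <- tapply(is_plp, tier, sum, default = 0L)
  frac <- if (total_plp > 0) plp_by_tier_counts / total_plp else
    rep(NA_real_, length(plp_by_tier_counts))
  structure(list(
    counts = counts,
    tier_map = tier_map,
    plp_by_tier = data.frame(tier = names(plp_by_tier_counts),
                             plp = as.integer(plp_by_tier_counts),
                             fraction = as.numeric(frac),
                             percent = round(100 * as.numeric(frac), 1),
                             row.names = NULL, stringsAsFactors = FALSE),
    total_plp = as.integer(total_plp),
    undefined = total_plp == 0), class = "variant_class_summary")
}

#' @export
print.variant_class_summary <- function(x, ...) {
  cat("Variant-class summary:", sum(x$counts), "variants,",
      x$total_plp, "P/LP\n")
  if (x$undefined) {
    cat("  (no P/LP variants; tier fractions undefined)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$plp_by_tier)))
    cat(sprintf("  %-28s %4d P/LP (%5.1f%%)\n", x$plp_by_tier$tier[i],
                x$plp_by_tier$plp[i], x$plp_by_tier$percent[i]))
  invisible(x)
}

#' Read a ClinVar-style variant table from TSV
#'
#' Expected columns: `gene`, `variant_id`, `significance` (raw ClinVar
#' vocabulary accepted; see [summarize_variant_classes()]); an optional
#' `condition` column is carried along.
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("gene", "significance"), names(df))
  if (length(missing))
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  df
}

## ---- full pipeline ---------------------------------------------------------

#' Run the full dual-curation pipeline over a directory of curation files
#'
#' Reads paired curation files (two per gene, any mix of JSON/YAML),
#' scores each blindly, builds the concordance report and the consensus
#' classification per gene (using each record pair's stored override and
#' replication flags, which must agree between the two copies), and writes
#' deterministic TSV reports plus a run log carrying the score-matrix
#' checksum.  Rerunning on the same inputs yields byte-identical outputs.
#'
#' @param input_dir directory of curation files.
#' @param matrix a `score_matrix`.
#' @param output_dir directory for reports (created if needed).
#' @return Invisibly, a list with `classification` and `concordance` data
#'   frames and the paths written.
#' @export
run_full_curation <- function(input_dir, matrix = default_score_matrix(),
                              output_dir) {
  files <- sort(list.files(input_dir, pattern = "\\.(json|ya?ml)$",
                           full.names = TRUE))
  if (!length(files)) stop("no curation files found in ", input_dir)
  records <- list()
  failures <- character()
  for (f in files) {
    rec <- tryCatch(load_curation(f), error = function(e) conditionMessage(e))
    if (is.character(rec)) failures <- c(failures, rec)
    else records[[f]] <- rec
  }
  if (length(failures))
    stop("unreadable curation inputs:\n  ", paste(failures, collapse = "\n  "))

  genes <- vapply(records, function(r) r$gene_symbol, character(1))
  by_gene <- split(records, genes)
  n_bad <- vapply(by_gene, length, integer(1)) != 2L
  if (any(n_bad))
    stop("dual curation requires exactly two records per gene; offending: ",
         paste(names(by_gene)[n_bad], collapse = ", "))

  gene_order <- sort(names(by_gene))
  pairs <- lapply(by_gene[gene_order], function(two)
    dual_curation(two[[1]], two[[2]], matrix))
  conc <- concordance_report(pairs)

  classification <- do.call(rbind, lapply(gene_order, function(g) {
    two <- by_gene[[g]]
    if (!identical(two[[1]]$expert_override, two[[2]]$expert_override) ||
        !identical(two[[1]]$replicated_over_time, two[[2]]$replicated_over_time))
      stop("panel flags disagree between the two curation files for ", g)
    pair <- pairs[[g]]
    cons <- consensus_classification(pair, two[[1]]$expert_override,
                                     two[[1]]$replicated_over_time, matrix)
    data.frame(gene = g,
               genetic = pair$A$genetic$genetic_subtotal,
               experimental = pair$A$experimental$experimental_subtotal,
               total = pair$A$total,
               total_B = pair$B$total,
               preliminary = pair$A$preliminary$value,
               final = cons$value,
               override = two[[1]]$expert_override,
               replicated = two[[1]]$replicated_over_time,
               stringsAsFactors = FALSE)
  }))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    classification = file.path(output_dir, "classification.tsv"),
    concordance = file.path(output_dir, "concordance.tsv"),
    log = file.path(output_dir, "run_log.txt"))
  utils::write.table(classification, paths[["classification"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(conc$per_gene, paths[["concordance"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(
    "arvcvalidity run log",
    sprintf("score matrix: %s (md5 %s)", matrix$version, matrix_checksum(matrix)),
    sprintf("curation files: %d (%d genes)", length(files), length(gene_order)),
    sprintf("fraction concordant: %.4f", conc$fraction_concordant)),
    paths[["log"]])
  invisible(list(classification = classification, concordance = conc,
                 paths = paths))
}

#' Stacked-bar plot of the genetic/experimental score decomposition
#'
#' Mirrors the customary presentation of panel results: one bar per gene,
#' genetic points (dark) stacked under experimental points (light), genes
#' ordered by total score.
#'
#' @param classification data frame with columns `gene`, `genetic`,
#'   `experimental` (as produced by [run_full_curation()]).
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_score_decomposition <- function(classification, ...) {
  ord <- order(-(classification$genetic + classification$experimental))
  m <- t(as.matrix(classification[ord, c("genetic", "experimental")]))
  colnames(m) <- classification$gene[ord]
  mid <- graphics::barplot(m, las = 2, col = c("#1f4e79", "#9dc3e6"),
                           ylab = "evidence points", ylim = c(0, 18),
                           legend.text = c("genetic", "experimental"), ...)
  graphics::abline(h = c(7, 12), lty = 3)
  invisible(mid)
}
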
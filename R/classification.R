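CLASS_LEVELS <- c("no_known_relationship", "limited", "moderate", "strong",
                  "definitive", "disputed", "refuted", "needs_panel_review")

# rank used for band-monotonicity; overrides sit outside the point ladder
CLASS_RANK <- c(no_known_relationship = 0, limited = 1, moderate = 2,
                strong = 3, definitive = 3)

#' Total validity score
#'
#' Sum of the genetic and experimental subtotals on the 0-18 scale.
#'
#' @param g a `genetic_breakdown` (or its subtotal as a number).
#' @param e an `experimental_breakdown` (or its subtotal as a number).
#' @return Points (scalar, at most 18).
#' @export
total_score <- function(g, e) {
  gs <- if (inherits(g, "genetic_breakdown")) g$genetic_subtotal else g
  es <- if (inherits(e, "experimental_breakdown")) e$experimental_subtotal else e
  round_points(gs + es)
}

new_classification <- function(value, total, preliminary,
                               override = "none", replicated = FALSE) {
  structure(list(value = value, total_points = total,
                 preliminary = preliminary, override = override,
                 replicated = replicated),
            class = "gene_validity_class")
}

#' Classify a total score into a validity category
#'
#' A non-none expert override (Disputed/Refuted) fixes the outcome
#' regardless of points.  Otherwise the bands partition the 0-18 scale:
#' 0 -> No Known Relationship; (0, 7) -> Limited; \[7, 12) -> Moderate;
#' \[12, 18\] -> Strong, upgraded to Definitive when the association has
#' been replicated over time.  Every representable (0.05-grid) score falls
#' in exactly one band.
#'
#' @param total total points in `[0, 18]`.
#' @param replicated has the association replicated across cohorts?
#' @param override `"none"`, `"disputed"` or `"refuted"`.
#' @param matrix a `score_matrix` (band edges are configuration).
#' @param preliminary marks the classification as a preliminary (per-team)
#'   one; see [preliminary_classification()].
#' @return An object of class `gene_validity_class`.
#' @export
#' @examples
#' classify(9.5, FALSE, "none")$value   # "moderate"
#' classify(13, TRUE, "none")$value     # "definitive"
#' classify(5, FALSE, "refuted")$value  # "refuted" (override beats points)
classify <- function(total, replicated = FALSE, override = "none",
                     matrix = default_score_matrix(), preliminary = FALSE) {
  override <- match.arg(override, OVERRIDES)
  total <- round_points(total)
  if (total < 0 || total > matrix$bands$max)
    stop("total score ", total, " outside [0, ", matrix$bands$max, "]")
  if (override != "none")
    return(new_classification(override, total, preliminary, override, replicated))
  value <-
    if (total == 0) "no_known_relationship"
    else if (total < matrix$bands$moderate_floor) "limited"
    else if (total < matrix$bands$strong_floor) "moderate"
    else if (replicated) "definitive"
    else "strong"
  new_classification(value, total, preliminary, override, replicated)
}

#' Score a curation record end to end
#'
#' Computes the genetic and experimental breakdowns, the total, the
#' preliminary classification (points only; expert overrides are
#' panel-level and applied only after dual curation) and the final
#' classification (with the record's override and replication flag).
#'
#' @param record a [gene_disease_record()].
#' @param matrix a `score_matrix`.
#' @return An object of class `score_breakdown` with fields `gene`,
#'   `genetic`, `experimental`, `total`, `preliminary` and `final`.
#' @export
score_record <- function(record, matrix = default_score_matrix()) {
  bad <- validate_record(record, matrix)
  if (length(bad))
    stop("invalid record for ", record$gene_symbol, ":\n  ",
         paste(bad, collapse = "\n  "))
  g <- genetic_subtotal(record, matrix)
  e <- experimental_subtotal(record$experimental_evidence, matrix)
  total <- total_score(g, e)
  structure(list(
    gene = record$gene_symbol,
    genetic = g,
    experimental = e,
    total = total,
    preliminary = classify(total, record$replicated_over_time, "none",
                           matrix, preliminary = TRUE),
    final = classify(total, record$replicated_over_time,
                     record$expert_override, matrix)
  ), class = "score_breakdown")
}

#' Preliminary classification of a record
#'
#' Classifies on points alone, with the expert override forced to `none`:
#' Disputed/Refuted judgments are panel-level and only enter at consensus
#' (see [consensus_classification()]).
#'
#' @param record a [gene_disease_record()].
#' @param matrix a `score_matrix`.
#' @return A `gene_validity_class` with `preliminary = TRUE`.
#' @export
preliminary_classification <- function(record, matrix = default_score_matrix()) {
  score_record(record, matrix)$preliminary
}

#' Advisory replication predicate
#'
#' The replication flag on a record is a stored panel judgment; this helper
#' offers a mechanical default (at least two independent publications
#' spanning at least three years) for curators who want a starting point.
#'
#' @param n_publications number of independent publications asserting the
#'   association.
#' @param years_span years between the first and last such publication.
#' @return Logical.
#' @export
suggest_replicated_over_time <- function(n_publications, years_span) {
  n_publications >= 2 && years_span >= 3
}

#' @export
print.gene_validity_class <- function(x, ...) {
  cat(sprintf("<%s classification> %s (total %g points)\n",
              if (x$preliminary) "preliminary" else "final", x$value,
              x$total_points))
  invisible(x)
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("Gene-disease validity score for %s\n", x$gene))
  cat(sprintf("  genetic %g + experimental %g = total %g\n",
              x$genetic$genetic_subtotal,
              x$experimental$experimental_subtotal, x$total))
  cat(sprintf("  preliminary: %s | final: %s\n",
              x$preliminary$value, x$final$value))
  invisible(x)
}

#' @export
summary.score_breakdown <- function(object, ...) {
  print(object$genetic)
  print(object$experimental)
  print(object$final)
  invisible(object)
}
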
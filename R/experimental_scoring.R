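#' Score one experimental evidence item
#'
#' Applies the ARVC-specific model-phenotype gate: a model-system or rescue
#' item whose phenotype was judged not consistent with the curated disease
#' contributes zero points regardless of any awarded value (an animal model
#' with, say, a dilated-cardiomyopathy phenotype is not evidence for ARVC).
#' Otherwise the panel award applies, or the matrix default when no award
#' was recorded.  Out-of-range awards and model/rescue items missing the
#' phenotype judgment are errors.
#'
#' @param item an [experimental_evidence_item()].
#' @param matrix a `score_matrix`.
#' @return Points (scalar).
#' @export
#' @examples
#' m <- default_score_matrix()
#' score_experimental_item(
#'   experimental_evidence_item("model_organism", phenotype_consistent = TRUE), m)
score_experimental_item <- function(item, matrix = default_score_matrix()) {
  cfg <- matrix$experimental$categories[[item$category]]
  if (is.null(cfg)) stop("unknown experimental category: ", item$category)
  if (is_model_or_rescue(item$category)) {
    if (is.null(item$phenotype_consistent))
      stop("phenotype_consistent is required for model/rescue item (",
           item$category, ")")
    if (!item$phenotype_consistent) return(0)
  }
  pts <- item$awarded_points %||% cfg$default
  if (pts < cfg$range[1] || pts > cfg$range[2])
    stop(sprintf("awarded_points %s outside range [%s, %s] for category %s",
                 pts, cfg$range[1], cfg$range[2], item$category))
  pts
}

#' Experimental-evidence subtotal with group caps
#'
#' Items are summed within their evidence groups (function, functional
#' alteration, models & rescue), each group is clamped at its cap (2/2/4 in
#' the shipped matrix), and the combined total is clamped at the
#' experimental cap (6).
#'
#' @param items list of [experimental_evidence_item()]s.
#' @param matrix a `score_matrix`.
#' @return An object of class `experimental_breakdown` with fields
#'   `points_by_category`, `function_points`, `functional_alteration_points`,
#'   `models_rescue_points` and `experimental_subtotal`.
#' @export
experimental_subtotal <- function(items, matrix = default_score_matrix()) {
  cats <- matrix$experimental$categories
  by_cat <- stats::setNames(numeric(length(cats)), names(cats))
  for (item in items)
    by_cat[item$category] <- by_cat[item$category] + score_experimental_item(item, matrix)

  groups <- vapply(cats, function(c) c$group, character(1))
  group_caps <- matrix$experimental$group_caps
  group_pts <- vapply(names(group_caps), function(g)
    clamp_cap(sum(by_cat[groups == g]), group_caps[[g]]), numeric(1))

  structure(list(
    points_by_category = by_cat,
    function_points = group_pts[["function"]],
    functional_alteration_points = group_pts[["functional_alteration"]],
    models_rescue_points = group_pts[["models_rescue"]],
    experimental_subtotal = clamp_cap(sum(group_pts), matrix$experimental$cap)
  ), class = "experimental_breakdown")
}

#' @export
print.experimental_breakdown <- function(x, ...) {
  cat("Experimental evidence breakdown\n")
  cat(sprintf("  function: %g | functional alteration: %g | models & rescue: %g\n",
              x$function_points, x$functional_alteration_points,
              x$models_rescue_points))
  cat(sprintf("  experimental subtotal: %g\n", x$experimental_subtotal))
  invisible(x)
}
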
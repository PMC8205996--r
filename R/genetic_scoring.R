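#' Resolve the variant-evidence category for a proband
#'
#' Category resolution implements the case-level rules: under dominant-type
#' inheritance (AD, XL, semidominant) a predicted/proven null variant scores
#' in the null category; a non-null variant with a confirmed or assumed de
#' novo occurrence scores in the de novo category; any other variant with
#' some evidence of gene impact scores in the low-default "other" category.
#' Recessive curations use the biallelic categories and require a stated
#' phase (`in_trans` or `unknown`); `not_applicable` is an error under AR.
#'
#' @param inheritance inheritance mode of the curation.
#' @param variant_class,de_novo,phase_for_AR fields of
#'   [proband_variant_evidence()].
#' @return Category name (a key of `matrix$genetic$variant$categories`).
#' @export
resolve_variant_category <- function(inheritance, variant_class, de_novo,
                                     phase_for_AR = "not_applicable") {
  if (inheritance == "AR") {
    if (phase_for_AR == "not_applicable")
      stop("unresolvable category: AR inheritance requires phase in_trans or unknown")
    if (variant_class == "predicted_or_proven_null") "ar_biallelic_null"
    else "ar_biallelic_other"
  } else {
    if (variant_class == "predicted_or_proven_null") "predicted_or_proven_null"
    else if (de_novo %in% c("confirmed", "assumed")) "other_de_novo"
    else "other_with_gene_impact"
  }
}

#' Score one proband variant
#'
#' Returns the panel-awarded points when present, otherwise the matrix
#' default for the resolved category.  An awarded value outside the
#' category's range is an error, never silently clamped: curation files
#' record panel decisions, and silent modification would hide data errors.
#'
#' @param ev a [proband_variant_evidence()] item.
#' @param inheritance inheritance mode of the record.
#' @param matrix a `score_matrix`.
#' @return Points (scalar).
#' @export
#' @examples
#' m <- default_score_matrix()
#' ev <- proband_variant_evidence("p1", "predicted_or_proven_null")
#' score_proband_variant(ev, "AD", m)  # 1.5, the shipped default
score_proband_variant <- function(ev, inheritance, matrix = default_score_matrix()) {
  cat_name <- resolve_variant_category(inheritance, ev$variant_class,
                                       ev$de_novo, ev$phase_for_AR)
  cfg <- matrix$genetic$variant$categories[[cat_name]]
  pts <- ev$awarded_points %||% cfg$default
  if (pts < cfg$range[1] || pts > cfg$range[2])
    stop(sprintf("awarded_points %s outside range [%s, %s] for category %s",
                 pts, cfg$range[1], cfg$range[2], cat_name))
  pts
}

#' Variant-evidence subtotal with category and overall caps
#'
#' Per-category sums are clamped at their category caps, then the combined
#' sum is clamped at the overall case-level variant cap (12 in the shipped
#' matrix).  Order-independent.
#'
#' @param evs list of [proband_variant_evidence()] items.
#' @param inheritance inheritance mode.
#' @param matrix a `score_matrix`.
#' @return List with `by_category` (named capped per-category sums) and
#'   `capped` (the overall subtotal).
#' @export
variant_evidence_subtotal <- function(evs, inheritance, matrix = default_score_matrix()) {
  cats <- matrix$genetic$variant$categories
  sums <- stats::setNames(numeric(length(cats)), names(cats))
  for (ev in evs) {
    cat_name <- resolve_variant_category(inheritance, ev$variant_class,
                                         ev$de_novo, ev$phase_for_AR)
    sums[cat_name] <- sums[cat_name] + score_proband_variant(ev, inheritance, matrix)
  }
  caps <- vapply(cats, function(c) c$cap, numeric(1))
  by_cat <- clamp_cap(sums, caps)
  list(by_category = by_cat,
       capped = clamp_cap(sum(by_cat), matrix$genetic$variant$overall_cap))
}

#' Estimate a family's segregation LOD score
#'
#' A published LOD is passed through unchanged.  Otherwise the LOD is the
#' fully-informative, fully-penetrant dominant counting approximation
#' `informative_meioses * log10(2)`: each phenotype-concordant genotyped
#' meiosis (proband excluded) contributes log10(2) ~= 0.301.
#'
#' @param seg a [segregation_evidence()] item.
#' @return LOD score (scalar).
#' @export
#' @examples
#' estimate_segregation_lod(segregation_evidence("f1", informative_meioses = 10))
estimate_segregation_lod <- function(seg) {
  if (!is.null(seg$published_lod)) return(seg$published_lod)
  if (is.null(seg$informative_meioses))
    stop("segregation evidence carries neither informative_meioses nor published_lod")
  seg$informative_meioses * log10(2)
}

# map a summed LOD onto points via the matrix thresholds (largest bin whose
# threshold the LOD reaches)
lod_to_points <- function(lod, mapping) {
  hit <- which(lod >= mapping$thresholds)
  if (!length(hit)) 0 else mapping$points[max(hit)]
}

#' Segregation points from summed LOD scores
#'
#' Family LODs are summed per sequencing approach; the matrix mapping for
#' each approach is applied to that approach's summed LOD (candidate-gene
#' studies: LOD 2-2.99 -> 1, 3-4.99 -> 2, >= 5 -> 3; exome/genome earns
#' half), and the combined result is clamped at the segregation cap.
#'
#' @param segs list of [segregation_evidence()] items.
#' @param matrix a `score_matrix`.
#' @return Points (scalar).
#' @export
segregation_points <- function(segs, matrix = default_score_matrix()) {
  if (!length(segs)) return(0)
  approaches <- vapply(segs, function(s) s$sequencing_approach, character(1))
  lods <- vapply(segs, estimate_segregation_lod, numeric(1))
  pts <- 0
  for (ap in unique(approaches)) {
    mapping <- matrix$genetic$segregation$mapping[[ap]]
    pts <- pts + lod_to_points(sum(lods[approaches == ap]), mapping)
  }
  clamp_cap(pts, matrix$genetic$segregation$cap)
}

#' Case-control points
#'
#' Sum of per-study awarded points (each already range-checked to `[0, 6]`)
#' clamped at the case-control cap (12 in the shipped matrix).
#'
#' @param studies list of [case_control_evidence()] items.
#' @param matrix a `score_matrix`.
#' @return Points (scalar).
#' @export
case_control_points <- function(studies, matrix = default_score_matrix()) {
  rng <- matrix$genetic$case_control$study_range
  pts <- vapply(studies, function(s) s$awarded_points, numeric(1))
  if (length(pts) && (any(pts < rng[1]) || any(pts > rng[2])))
    stop(sprintf("case-control awarded_points outside [%s, %s]", rng[1], rng[2]))
  clamp_cap(sum(pts), matrix$genetic$case_control$cap)
}

#' Genetic-evidence subtotal for a record
#'
#' Combines capped case-level variant points, segregation points and
#' case-control points, clamping the sum at the genetic cap (12).
#'
#' @param record a [gene_disease_record()].
#' @param matrix a `score_matrix`.
#' @return An object of class `genetic_breakdown` with fields
#'   `variant_points_by_category`, `variant_points_capped`,
#'   `segregation_lod_total`, `segregation_points`, `case_control_points`
#'   and `genetic_subtotal`.
#' @export
genetic_subtotal <- function(record, matrix = default_score_matrix()) {
  vs <- variant_evidence_subtotal(record$proband_evidence, record$inheritance, matrix)
  seg_lod <- if (length(record$segregation_evidence)) {
    sum(vapply(record$segregation_evidence, estimate_segregation_lod, numeric(1)))
  } else 0
  seg_pts <- segregation_points(record$segregation_evidence, matrix)
  cc_pts <- case_control_points(record$case_control_evidence, matrix)
  structure(list(
    variant_points_by_category = vs$by_category,
    variant_points_capped = vs$capped,
    segregation_lod_total = seg_lod,
    segregation_points = seg_pts,
    case_control_points = cc_pts,
    genetic_subtotal = clamp_cap(vs$capped + seg_pts + cc_pts, matrix$genetic$cap)
  ), class = "genetic_breakdown")
}

#' @export
print.genetic_breakdown <- function(x, ...) {
  cat("Genetic evidence breakdown\n")
  nz <- x$variant_points_by_category[x$variant_points_by_category > 0]
  if (length(nz))
    cat("  variant points:", paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  variant (capped): %g | segregation: %g (LOD %.3f) | case-control: %g\n",
              x$variant_points_capped, x$segregation_points,
              x$segregation_lod_total, x$case_control_points))
  cat(sprintf("  genetic subtotal: %g\n", x$genetic_subtotal))
  invisible(x)
}
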
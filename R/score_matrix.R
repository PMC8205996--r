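#' Default evidence score matrix
#'
#' The score matrix is configuration data, not code: it holds the default
#' points, allowed ranges and caps for every evidence category of the
#' semiquantitative gene-disease validity framework, the segregation
#' LOD-to-points mapping per sequencing approach, and the subtotal caps
#' (genetic 12, experimental 6, total 18).  Panel-specific revisions are a
#' config change, not a code change: load an edited copy with
#' [load_score_matrix()].
#'
#' Case-level variant categories (autosomal dominant / X-linked /
#' semidominant): predicted or proven null variants default to 1.5 points
#' (range 0-3, category cap 10); other variants with some evidence of gene
#' impact default to 0.1 (range 0-1.5, cap 7); a de novo occurrence of a
#' non-null variant defaults to 0.5.  Autosomal recessive curations use the
#' biallelic categories (defaults 2 and 1 depending on whether a null allele
#' is involved).  Case-level variant evidence overall is capped at 12.
#'
#' Segregation: summed LOD per sequencing approach is binned
#' (candidate-gene: LOD 2-2.99 -> 1, 3-4.99 -> 2, >= 5 -> 3; exome/genome
#' sequencing earns half these points), capped at 3 overall.  Case-control
#' studies earn 0-6 points each, capped at 12.  Experimental categories are
#' grouped (function <= 2, functional alteration <= 2, models and rescue
#' <= 4) and capped at 6 overall.
#'
#' @return An object of class `score_matrix`.
#' @seealso [load_score_matrix()], [save_score_matrix()], [matrix_checksum()]
#' @export
#' @examples
#' m <- default_score_matrix()
#' m$genetic$cap + m$experimental$cap  # total scale maximum, 18
default_score_matrix <- function() {
  m <- list(
    version = "arvc-matrix/1.0",
    genetic = list(
      variant = list(
        categories = list(
          predicted_or_proven_null = list(default = 1.5, range = c(0, 3), cap = 10),
          other_with_gene_impact   = list(default = 0.1, range = c(0, 1.5), cap = 7),
          other_de_novo            = list(default = 0.5, range = c(0, 3), cap = 10),
          ar_biallelic_null        = list(default = 2, range = c(0, 3), cap = 12),
          ar_biallelic_other       = list(default = 1, range = c(0, 3), cap = 12)
        ),
        overall_cap = 12
      ),
      segregation = list(
        mapping = list(
          candidate_gene = list(thresholds = c(2, 3, 5), points = c(1, 2, 3)),
          exome_genome   = list(thresholds = c(2, 3, 5), points = c(0.5, 1, 1.5))
        ),
        cap = 3
      ),
      case_control = list(study_range = c(0, 6), cap = 12),
      cap = 12
    ),
    experimental = list(
      categories = list(
        biochemical_function                   = list(default = 0.5, range = c(0, 2), group = "function"),
        protein_interaction                    = list(default = 0.5, range = c(0, 2), group = "function"),
        expression                             = list(default = 0.5, range = c(0, 2), group = "function"),
        functional_alteration_patient_cells    = list(default = 1, range = c(0, 2), group = "functional_alteration"),
        functional_alteration_nonpatient_cells = list(default = 0.5, range = c(0, 1), group = "functional_alteration"),
        model_organism                         = list(default = 2, range = c(0, 4), group = "models_rescue"),
        cell_culture_model                     = list(default = 1, range = c(0, 2), group = "models_rescue"),
        rescue_human                           = list(default = 2, range = c(0, 4), group = "models_rescue"),
        rescue_model_organism                  = list(default = 2, range = c(0, 4), group = "models_rescue"),
        rescue_cell_culture                    = list(default = 1, range = c(0, 2), group = "models_rescue"),
        rescue_patient_cells                   = list(default = 1, range = c(0, 2), group = "models_rescue")
      ),
      group_caps = list("function" = 2, functional_alteration = 2, models_rescue = 4),
      cap = 6
    ),
    bands = list(moderate_floor = 7, strong_floor = 12, max = 18)
  )
  class(m) <- "score_matrix"
  m
}

#' Validate a score matrix
#'
#' Checks the structural invariants of a matrix: every category default lies
#' within its range, caps are nonnegative, and the genetic and experimental
#' caps add up to the total scale maximum.
#'
#' @param matrix a `score_matrix`.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_score_matrix <- function(matrix) {
  v <- character()
  chk_cat <- function(name, cat) {
    if (cat$default < cat$range[1] || cat$default > cat$range[2])
      v <<- c(v, sprintf("category '%s': default %s outside range [%s, %s]",
                         name, cat$default, cat$range[1], cat$range[2]))
    cap <- cat$cap
    if (!is.null(cap) && cap < 0) v <<- c(v, sprintf("category '%s': negative cap", name))
  }
  for (nm in names(matrix$genetic$variant$categories))
    chk_cat(nm, matrix$genetic$variant$categories[[nm]])
  for (nm in names(matrix$experimental$categories))
    chk_cat(nm, matrix$experimental$categories[[nm]])
  caps <- c(matrix$genetic$variant$overall_cap, matrix$genetic$segregation$cap,
            matrix$genetic$case_control$cap, matrix$genetic$cap,
            unlist(matrix$experimental$group_caps), matrix$experimental$cap)
  if (any(caps < 0)) v <- c(v, "negative subtotal cap")
  if (matrix$genetic$cap + matrix$experimental$cap != matrix$bands$max)
    v <- c(v, "genetic cap + experimental cap must equal the total maximum")
  v
}

#' Read a score matrix from a YAML or JSON config file
#'
#' @param path file path; format is chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return A validated `score_matrix`.
#' @export
load_score_matrix <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  if (is.null(raw$version) || !identical(raw$version, "arvc-matrix/1.0"))
    stop("unrecognized score-matrix version: ", raw$version %||% "<missing>")
  m <- structure(raw, class = "score_matrix")
  bad <- validate_score_matrix(m)
  if (length(bad)) stop("invalid score matrix:\n  ", paste(bad, collapse = "\n  "))
  m
}

#' Write a score matrix to a YAML config file
#'
#' @param matrix a `score_matrix`.
#' @param path output file path.
#' @export
save_score_matrix <- function(matrix, path) {
  bad <- validate_score_matrix(matrix)
  if (length(bad)) stop("refusing to write invalid score matrix:\n  ",
                        paste(bad, collapse = "\n  "))
  yaml::write_yaml(unclass(matrix), path)
  invisible(path)
}

#' Checksum of a score matrix configuration
#'
#' MD5 of the canonical JSON serialization; logged by [run_full_curation()]
#' so every report records exactly which scoring configuration produced it.
#'
#' @param matrix a `score_matrix`.
#' @return Character MD5 digest.
#' @export
matrix_checksum <- function(matrix) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical_sort(unclass(matrix)), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Evidence score matrix (", x$version, ")\n", sep = "")
  cat("  genetic cap:", x$genetic$cap,
      "| experimental cap:", x$experimental$cap,
      "| total max:", x$bands$max, "\n")
  cat("  variant categories:",
      paste(names(x$genetic$variant$categories), collapse = ", "), "\n")
  cat("  checksum:", matrix_checksum(x), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
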
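CURATION_SCHEMA <- "arvc-curation/1.0"

INHERITANCE_MODES <- c("AD", "AR", "XL", "semidominant")
VARIANT_CLASSES   <- c("predicted_or_proven_null", "other_with_gene_impact")
DE_NOVO_STATES    <- c("confirmed", "assumed", "none")
PHASE_STATES      <- c("in_trans", "unknown", "not_applicable")
SEQ_APPROACHES    <- c("candidate_gene", "exome_genome")
OVERRIDES         <- c("none", "disputed", "refuted")
EXPERIMENTAL_CATEGORIES <- c(
  "biochemical_function", "protein_interaction", "expression",
  "functional_alteration_patient_cells", "functional_alteration_nonpatient_cells",
  "model_organism", "cell_culture_model", "rescue_human",
  "rescue_model_organism", "rescue_cell_culture", "rescue_patient_cells")

# model-system and rescue categories are subject to the ARVC phenotype gate
is_model_or_rescue <- function(category) {
  category %in% c("model_organism", "cell_culture_model") |
    startsWith(category, "rescue_")
}

#' Construct a gene-disease curation record
#'
#' One record holds all adjudicated evidence for a single gene-disease pair
#' under one inheritance mode: case-level proband variants, family
#' segregation data, case-control studies and experimental evidence, plus
#' the panel-level flags (replication across cohorts, and the Disputed /
#' Refuted expert override that takes precedence over points).
#'
#' @param gene_symbol HGNC gene symbol (nonempty).
#' @param disease_label free-text disease name.
#' @param inheritance one of `"AD"`, `"AR"`, `"XL"`, `"semidominant"`.
#' @param proband_evidence list of [proband_variant_evidence()] items.
#' @param segregation_evidence list of [segregation_evidence()] items.
#' @param case_control_evidence list of [case_control_evidence()] items.
#' @param experimental_evidence list of [experimental_evidence_item()] items.
#' @param replicated_over_time has the association been independently
#'   replicated across cohorts/publications (gates the Strong -> Definitive
#'   upgrade)?
#' @param expert_override `"none"`, `"disputed"` or `"refuted"`; a non-none
#'   override fixes the final classification regardless of points.
#' @param curator_id identifier of the curation team/curator.
#' @param curation_date ISO date string (`"YYYY-MM-DD"`) or `NA`.
#' @return An object of class `gene_disease_record`.
#' @export
#' @examples
#' rec <- gene_disease_record("PKP2",
#'   proband_evidence = list(proband_variant_evidence("p1",
#'     "predicted_or_proven_null")))
#' validate_record(rec)
gene_disease_record <- function(gene_symbol,
                                disease_label = "arrhythmogenic right ventricular cardiomyopathy",
                                inheritance = "AD",
                                proband_evidence = list(),
                                segregation_evidence = list(),
                                case_control_evidence = list(),
                                experimental_evidence = list(),
                                replicated_over_time = FALSE,
                                expert_override = "none",
                                curator_id = "",
                                curation_date = NA_character_) {
  structure(list(
    gene_symbol = as.character(gene_symbol),
    disease_label = as.character(disease_label),
    inheritance = match.arg(inheritance, INHERITANCE_MODES),
    proband_evidence = proband_evidence,
    segregation_evidence = segregation_evidence,
    case_control_evidence = case_control_evidence,
    experimental_evidence = experimental_evidence,
    replicated_over_time = isTRUE(replicated_over_time),
    expert_override = match.arg(expert_override, OVERRIDES),
    curator_id = as.character(curator_id),
    curation_date = as.character(curation_date)
  ), class = "gene_disease_record")
}

#' Case-level proband variant evidence
#'
#' @param proband_id proband identifier.
#' @param variant_class `"predicted_or_proven_null"` or
#'   `"other_with_gene_impact"`.
#' @param de_novo `"confirmed"`, `"assumed"` or `"none"`.
#' @param phase_for_AR phase of the two alleles for recessive curations:
#'   `"in_trans"`, `"unknown"`, or `"not_applicable"` (dominant/X-linked).
#' @param meets_diagnostic_criteria does the proband fulfil the disease's
#'   diagnostic criteria (here, the 2010 Task Force Criteria)?
#' @param awarded_points panel-adjudicated points (0.05 grid) or `NULL` to
#'   use the matrix default for the resolved category.
#' @param variant_frequency_check optional [assess_variant()] result
#'   recording the allele-frequency admissibility assessment.
#' @return An object of class `proband_variant_evidence`.
#' @export
proband_variant_evidence <- function(proband_id,
                                     variant_class,
                                     de_novo = "none",
                                     phase_for_AR = "not_applicable",
                                     meets_diagnostic_criteria = TRUE,
                                     awarded_points = NULL,
                                     variant_frequency_check = NULL) {
  structure(list(
    proband_id = as.character(proband_id),
    variant_class = match.arg(variant_class, VARIANT_CLASSES),
    de_novo = match.arg(de_novo, DE_NOVO_STATES),
    phase_for_AR = match.arg(phase_for_AR, PHASE_STATES),
    meets_diagnostic_criteria = isTRUE(meets_diagnostic_criteria),
    awarded_points = if (!is.null(awarded_points)) as.numeric(awarded_points),
    variant_frequency_check = variant_frequency_check
  ), class = "proband_variant_evidence")
}

#' Family segregation evidence
#'
#' Exactly one of `informative_meioses` (a count of phenotype-concordant
#' genotyped meioses, excluding the proband) or `published_lod` (a LOD score
#' taken from the literature) must be supplied.
#'
#' @param family_id family identifier.
#' @param informative_meioses nonnegative integer count, or `NULL`.
#' @param published_lod published LOD score, or `NULL`.
#' @param sequencing_approach `"candidate_gene"` or `"exome_genome"`;
#'   exome/genome-era segregation earns half points in the shipped matrix.
#' @return An object of class `segregation_evidence`.
#' @export
segregation_evidence <- function(family_id,
                                 informative_meioses = NULL,
                                 published_lod = NULL,
                                 sequencing_approach = "candidate_gene") {
  structure(list(
    family_id = as.character(family_id),
    informative_meioses = if (!is.null(informative_meioses)) as.integer(informative_meioses),
    published_lod = if (!is.null(published_lod)) as.numeric(published_lod),
    sequencing_approach = match.arg(sequencing_approach, SEQ_APPROACHES)
  ), class = "segregation_evidence")
}

#' Case-control study evidence
#'
#' @param study_id study identifier.
#' @param design `"single_variant"` or `"aggregate"`.
#' @param awarded_points adjudicated points in `[0, 6]`.
#' @param case_allele_count,case_allele_number,control_allele_count,control_allele_number
#'   optional allele counts backing the study.
#' @return An object of class `case_control_evidence`.
#' @export
case_control_evidence <- function(study_id,
                                  design = c("single_variant", "aggregate"),
                                  awarded_points,
                                  case_allele_count = NULL,
                                  case_allele_number = NULL,
                                  control_allele_count = NULL,
                                  control_allele_number = NULL) {
  structure(list(
    study_id = as.character(study_id),
    design = match.arg(design),
    case_allele_count = if (!is.null(case_allele_count)) as.integer(case_allele_count),
    case_allele_number = if (!is.null(case_allele_number)) as.integer(case_allele_number),
    control_allele_count = if (!is.null(control_allele_count)) as.integer(control_allele_count),
    control_allele_number = if (!is.null(control_allele_number)) as.integer(control_allele_number),
    awarded_points = as.numeric(awarded_points)
  ), class = "case_control_evidence")
}

#' Experimental evidence item
#'
#' Model-system and rescue items must state whether the observed phenotype
#' is consistent with the curated disease; an inconsistent phenotype earns
#' zero points under the ARVC-specific gate (see
#' [score_experimental_item()]).
#'
#' @param category one of the experimental evidence categories (see
#'   [default_score_matrix()]).
#' @param phenotype_consistent logical; required for model/rescue
#'   categories.
#' @param awarded_points adjudicated points or `NULL` for the matrix
#'   default.
#' @return An object of class `experimental_evidence_item`.
#' @export
experimental_evidence_item <- function(category,
                                       phenotype_consistent = NULL,
                                       awarded_points = NULL) {
  structure(list(
    category = match.arg(category, EXPERIMENTAL_CATEGORIES),
    phenotype_consistent = if (!is.null(phenotype_consistent)) isTRUE(phenotype_consistent),
    awarded_points = if (!is.null(awarded_points)) as.numeric(awarded_points)
  ), class = "experimental_evidence_item")
}

#' Validate a curation record against a score matrix
#'
#' Checks every type invariant and range constraint; violations are
#' returned as messages (naming the field and rule), never raised, so a
#' curation file can be fully linted in one pass.
#'
#' @param record a [gene_disease_record()].
#' @param matrix a `score_matrix` (defaults to the shipped one).
#' @return Character vector of violation messages; empty iff the record is
#'   valid.
#' @export
validate_record <- function(record, matrix = default_score_matrix()) {
  v <- character()
  add <- function(...) v <<- c(v, sprintf(...))

  if (!inherits(record, "gene_disease_record")) return("not a gene_disease_record")
  if (!nzchar(record$gene_symbol)) add("gene_symbol: must be nonempty")
  if (!record$inheritance %in% INHERITANCE_MODES)
    add("inheritance: '%s' not one of %s", record$inheritance,
        paste(INHERITANCE_MODES, collapse = "/"))
  if (!record$expert_override %in% OVERRIDES)
    add("expert_override: '%s' not one of %s", record$expert_override,
        paste(OVERRIDES, collapse = "/"))

  for (i in seq_along(record$proband_evidence)) {
    ev <- record$proband_evidence[[i]]
    where <- sprintf("proband_evidence[%d] (%s)", i, ev$proband_id %||% "?")
    cat_name <- tryCatch(
      resolve_variant_category(record$inheritance, ev$variant_class,
                               ev$de_novo, ev$phase_for_AR),
      error = function(e) {
        add("%s: %s", where, conditionMessage(e)); NULL
      })
    if (!is.null(ev$awarded_points)) {
      if (!on_points_grid(ev$awarded_points))
        add("%s: awarded_points %s not on the 0.05 grid", where, ev$awarded_points)
      if (!is.null(cat_name)) {
        rng <- matrix$genetic$variant$categories[[cat_name]]$range
        if (ev$awarded_points < rng[1] || ev$awarded_points > rng[2])
          add("%s: awarded_points %s outside range [%s, %s] for category %s",
              where, ev$awarded_points, rng[1], rng[2], cat_name)
      }
    }
  }

  for (i in seq_along(record$segregation_evidence)) {
    seg <- record$segregation_evidence[[i]]
    where <- sprintf("segregation_evidence[%d] (%s)", i, seg$family_id %||% "?")
    has_m <- !is.null(seg$informative_meioses)
    has_l <- !is.null(seg$published_lod)
    if (has_m == has_l)
      add("%s: exactly one of informative_meioses / published_lod must be supplied", where)
    if (has_m && seg$informative_meioses < 0)
      add("%s: informative_meioses must be >= 0", where)
    if (!seg$sequencing_approach %in% SEQ_APPROACHES)
      add("%s: unknown sequencing_approach '%s'", where, seg$sequencing_approach)
  }

  for (i in seq_along(record$case_control_evidence)) {
    cc <- record$case_control_evidence[[i]]
    where <- sprintf("case_control_evidence[%d] (%s)", i, cc$study_id %||% "?")
    rng <- matrix$genetic$case_control$study_range
    if (is.null(cc$awarded_points) || cc$awarded_points < rng[1] || cc$awarded_points > rng[2])
      add("%s: awarded_points must lie in [%s, %s]", where, rng[1], rng[2])
    for (side in c("case", "control")) {
      ac <- cc[[paste0(side, "_allele_count")]]
      an <- cc[[paste0(side, "_allele_number")]]
      if (!is.null(ac) && ac < 0) add("%s: %s_allele_count must be >= 0", where, side)
      if (!is.null(ac) && !is.null(an) && ac > an)
        add("%s: %s allele_count exceeds allele_number", where, side)
    }
  }

  for (i in seq_along(record$experimental_evidence)) {
    item <- record$experimental_evidence[[i]]
    where <- sprintf("experimental_evidence[%d] (%s)", i, item$category %||% "?")
    if (!item$category %in% EXPERIMENTAL_CATEGORIES) {
      add("%s: unknown category", where)
      next
    }
    if (is_model_or_rescue(item$category) && is.null(item$phenotype_consistent))
      add("%s: phenotype_consistent is required for model/rescue categories", where)
    if (!is.null(item$awarded_points)) {
      rng <- matrix$experimental$categories[[item$category]]$range
      if (!on_points_grid(item$awarded_points))
        add("%s: awarded_points %s not on the 0.05 grid", where, item$awarded_points)
      if (item$awarded_points < rng[1] || item$awarded_points > rng[2])
        add("%s: awarded_points %s outside range [%s, %s]", where,
            item$awarded_points, rng[1], rng[2])
    }
  }
  v
}

#' @export
print.gene_disease_record <- function(x, ...) {
  cat(sprintf("<gene_disease_record> %s - %s (%s)\n",
              x$gene_symbol, x$disease_label, x$inheritance))
  cat(sprintf("  evidence: %d proband, %d segregation, %d case-control, %d experimental\n",
              length(x$proband_evidence), length(x$segregation_evidence),
              length(x$case_control_evidence), length(x$experimental_evidence)))
  cat(sprintf("  replicated_over_time: %s | expert_override: %s\n",
              x$replicated_over_time, x$expert_override))
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

# recursively sort named-list keys so the canonical serialization is unique
canonical_sort <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, canonical_sort)
  } else x
}

drop_nulls <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, drop_nulls)
    x[!vapply(x, is.null, logical(1))]
  } else x
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- if (!is.null(names(x))) list(names = names(x))
    x
  } else x
}

record_to_plain <- function(record) {
  plain <- drop_nulls(strip_classes(unclass(record)))
  plain$schema_version <- CURATION_SCHEMA
  canonical_sort(plain)
}

plain_to_record <- function(x) {
  if (is.null(x$schema_version) || !identical(x$schema_version, CURATION_SCHEMA))
    stop("unknown curation schema version: ", x$schema_version %||% "<missing>")
  req <- function(item, field) {
    if (is.null(item[[field]])) stop("missing required field '", field, "'")
    item[[field]]
  }
  gene_disease_record(
    gene_symbol = req(x, "gene_symbol"),
    disease_label = x$disease_label %||% "",
    inheritance = req(x, "inheritance"),
    proband_evidence = lapply(x$proband_evidence, function(ev)
      proband_variant_evidence(
        proband_id = req(ev, "proband_id"),
        variant_class = req(ev, "variant_class"),
        de_novo = ev$de_novo %||% "none",
        phase_for_AR = ev$phase_for_AR %||% "not_applicable",
        meets_diagnostic_criteria = ev$meets_diagnostic_criteria %||% TRUE,
        awarded_points = ev$awarded_points,
        variant_frequency_check = ev$variant_frequency_check)),
    segregation_evidence = lapply(x$segregation_evidence, function(seg)
      segregation_evidence(
        family_id = req(seg, "family_id"),
        informative_meioses = seg$informative_meioses,
        published_lod = seg$published_lod,
        sequencing_approach = seg$sequencing_approach %||% "candidate_gene")),
    case_control_evidence = lapply(x$case_control_evidence, function(cc)
      case_control_evidence(
        study_id = req(cc, "study_id"),
        design = cc$design %||% "single_variant",
        awarded_points = req(cc, "awarded_points"),
        case_allele_count = cc$case_allele_count,
        case_allele_number = cc$case_allele_number,
        control_allele_count = cc$control_allele_count,
        control_allele_number = cc$control_allele_number)),
    experimental_evidence = lapply(x$experimental_evidence, function(item)
      experimental_evidence_item(
        category = req(item, "category"),
        phenotype_consistent = item$phenotype_consistent,
        awarded_points = item$awarded_points)),
    replicated_over_time = x$replicated_over_time %||% FALSE,
    expert_override = x$expert_override %||% "none",
    curator_id = x$curator_id %||% "",
    curation_date = x$curation_date %||% NA_character_
  )
}

#' Write a curation record to a canonical JSON file
#'
#' Serialization is canonical: keys sorted, `NULL` optional fields omitted,
#' a schema version tag included, so saving the same record twice yields
#' byte-identical files.  An invalid record is refused.
#'
#' @param record a [gene_disease_record()].
#' @param path output file path (`.json`).
#' @param matrix score matrix used for validation.
#' @return `path`, invisibly.
#' @export
save_curation <- function(record, path, matrix = default_score_matrix()) {
  bad <- validate_record(record, matrix)
  if (length(bad))
    stop("refusing to write invalid record:\n  ", paste(bad, collapse = "\n  "))
  jsonlite::write_json(record_to_plain(record), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a curation record from a JSON or YAML file
#'
#' JSON is the canonical on-disk format; YAML is accepted on input.  Files
#' with an unrecognized schema version are rejected rather than guessed at.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return A [gene_disease_record()].
#' @export
load_curation <- function(path) {
  if (!file.exists(path)) stop("no such curation file: ", path)
  plain <- tryCatch({
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else
      jsonlite::fromJSON(path, simplifyVector = FALSE)
  }, error = function(e) {
    stop("cannot parse curation file '", path, "': ", conditionMessage(e))
  })
  tryCatch(plain_to_record(plain), error = function(e) {
    stop("malformed curation file '", path, "': ", conditionMessage(e))
  })
}
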
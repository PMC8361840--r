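#' The EVIDEM quantitative core model
#'
#' Builds the 13-criterion EVIDEM core model as a validated criterion table.
#' The core model spans five domains (need for intervention, comparative
#' outcomes, type of benefit, economic consequences, knowledge about the
#' intervention). Six criteria are *relative* — scored against a comparator on
#' a -5..+5 scale — and seven are *absolute*, scored 0..5 on their own merits.
#'
#' @return A tibble of class `criterion_model` with one row per criterion and
#'   columns `id`, `label`, `domain`, `scale_kind`, `comparator_note`.
#' @examples
#' core <- evidem_core_model()
#' dplyr::count(core, scale_kind)
#' @export
evidem_core_model <- function() {
  tbl <- tibble::tribble(
    ~id, ~label, ~domain, ~scale_kind,
    "disease_severity", "Disease severity",
      "Need for Intervention", "absolute",
    "size_of_affected_population", "Size of affected population",
      "Need for Intervention", "absolute",
    "unmet_needs", "Unmet needs",
      "Need for Intervention", "absolute",
    "comparative_effectiveness", "Comparative effectiveness",
      "Comparative Outcomes of Intervention", "relative",
    "comparative_safety_tolerability", "Comparative safety/tolerability",
      "Comparative Outcomes of Intervention", "relative",
    "patient_perceived_health_pro", "Comparative patient-perceived health / PRO",
      "Comparative Outcomes of Intervention", "relative",
    "type_of_preventive_benefit", "Type of preventive benefit",
      "Type of Benefit of Intervention", "absolute",
    "type_of_therapeutic_benefit", "Type of therapeutic benefit",
      "Type of Benefit of Intervention", "absolute",
    "cost_of_intervention", "Comparative cost consequences - cost of intervention",
      "Economic Consequences of Intervention", "relative",
    "other_medical_costs", "Comparative cost consequences - other medical costs",
      "Economic Consequences of Intervention", "relative",
    "non_medical_costs", "Comparative cost consequences - non-medical costs",
      "Economic Consequences of Intervention", "relative",
    "quality_of_evidence", "Quality of evidence",
      "Knowledge about Intervention", "absolute",
    "expert_consensus_guidelines", "Expert consensus/clinical practice guidelines",
      "Knowledge about Intervention", "absolute"
  )
  tbl$comparator_note <- ifelse(tbl$scale_kind == "relative", "vs placebo", NA_character_)
  new_criterion_model(tbl, name = "EVIDEM core model")
}

#' The EVIDEM qualitative contextual tool
#'
#' Builds the 7-criterion contextual tool. Contextual criteria are discussed
#' deliberatively by the appraisal committee; they are qualitative and never
#' enter the quantitative value estimate.
#'
#' @return A tibble of class `criterion_model`, all rows `scale_kind = "qualitative"`.
#' @export
evidem_contextual_tool <- function() {
  tbl <- tibble::tribble(
    ~id, ~label, ~domain,
    "mandate_scope_healthcare_system", "Mandate and scope of healthcare system",
      "Normative Contextual Criteria",
    "population_priorities_access", "Population priorities and access",
      "Normative Contextual Criteria",
    "common_goal_specific_interests", "Common goal and specific interests",
      "Normative Contextual Criteria",
    "environmental_impact", "Environmental impact",
      "Normative Contextual Criteria",
    "system_capacity_appropriate_use", "System capacity and appropriate use of intervention",
      "Feasibility Contextual Criteria",
    "political_historical_cultural_context", "Political/historical/cultural context",
      "Feasibility Contextual Criteria",
    "opportunity_costs_affordability", "Opportunity costs and affordability",
      "Opportunity Cost"
  )
  tbl$scale_kind <- "qualitative"
  tbl$comparator_note <- NA_character_
  new_criterion_model(tbl, name = "EVIDEM contextual tool")
}

# constructor + validator; qualitative criteria are only legal in the
# contextual tool, enforced at validate_panel time (scores on them are errors)
new_criterion_model <- function(tbl, name) {
  stopifnot(all(c("id", "label", "domain", "scale_kind", "comparator_note") %in% names(tbl)))
  if (anyDuplicated(tbl$id) > 0) {
    rlang::abort(paste0(
      "duplicate criterion ids: ",
      paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(tbl$scale_kind), c("absolute", "relative", "qualitative"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown scale_kind: ", paste(bad, collapse = ", ")))
  }
  out <- tibble::new_tibble(
    tbl[c("id", "label", "domain", "scale_kind", "comparator_note")],
    model_name = name,
    class = "criterion_model"
  )
  out
}

#' Look up one criterion definition by id
#'
#' @param model A `criterion_model`.
#' @param id A single criterion id.
#' @return The one-row tibble for that criterion.
#' @export
lookup_criterion <- function(model, id) {
  stopifnot(inherits(model, "criterion_model"), nrow(model) > 0)
  hit <- model[model$id == id, ]
  if (nrow(hit) != 1) {
    rlang::abort(paste0(
      "unknown criterion id '", id, "'; available: ",
      paste(model$id, collapse = ", ")
    ))
  }
  hit
}

#' Scale bounds for a criterion kind
#'
#' Absolute criteria are scored 0..5; relative criteria -5..+5 against the
#' comparator. Qualitative criteria carry no quantitative scale.
#'
#' @param scale_kind "absolute" or "relative" (vectorised).
#' @return A two-column tibble `lower`, `upper`.
#' @export
scale_bounds <- function(scale_kind) {
  lower <- dplyr::case_when(
    scale_kind == "absolute" ~ 0,
    scale_kind == "relative" ~ -5,
    TRUE ~ NA_real_
  )
  upper <- dplyr::if_else(scale_kind %in% c("absolute", "relative"), 5, NA_real_)
  tibble::tibble(lower = lower, upper = upper)
}

#' Write a criterion model to JSON or YAML
#'
#' Format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#' Criterion order is preserved and round-trips losslessly through
#' [read_criterion_model()].
#'
#' @param model A `criterion_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_criterion_model <- function(model, path) {
  stopifnot(inherits(model, "criterion_model"))
  payload <- list(
    name = attr(model, "model_name"),
    criteria = purrr::pmap(model, function(id, label, domain, scale_kind, comparator_note) {
      x <- list(id = id, label = label, domain = domain, scale_kind = scale_kind)
      if (!is.na(comparator_note)) x$comparator_note <- comparator_note
      x
    })
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else {
    rlang::abort(paste0("unsupported criterion-model format: .", ext))
  }
  invisible(path)
}

#' Read a criterion model from JSON or YAML
#'
#' @param path File written by [write_criterion_model()].
#' @return A `criterion_model`.
#' @export
read_criterion_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  payload <- if (ext == "json") {
    jsonlite::read_json(path)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    rlang::abort(paste0("unsupported criterion-model format: .", ext))
  }
  tbl <- purrr::map_dfr(payload$criteria, function(x) {
    tibble::tibble(
      id = x$id, label = x$label, domain = x$domain, scale_kind = x$scale_kind,
      comparator_note = x$comparator_note %||% NA_character_
    )
  })
  new_criterion_model(tbl, name = payload$name)
}

#' @export
print.criterion_model <- function(x, ...) {
  cat("<criterion_model> ", attr(x, "model_name"), ": ", nrow(x), " criteria, ",
      dplyr::n_distinct(x$domain), " domains\n", sep = "")
  NextMethod()
}
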
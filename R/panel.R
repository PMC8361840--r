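#' Panelist-level elicitation matrices
#'
#' Container for the raw committee elicitation data: one weight per panelist
#' per criterion (importance rating on a 1-5 scale, fractional values allowed)
#' and one score per panelist per criterion per intervention (0..5 for
#' absolute criteria, -5..+5 for relative criteria). Missing responses are
#' explicit `NA`s, never zeros: a committee that did not score a criterion is
#' different from one that scored it zero.
#'
#' @param weights Long tibble `panelist_id`, `criterion_id`, `weight`.
#' @param scores Long tibble `panelist_id`, `criterion_id`, `intervention`,
#'   `score`.
#' @return An object of class `panel_matrices`.
#' @export
panel_matrices <- function(weights, scores) {
  weights <- tibble::as_tibble(weights)[c("panelist_id", "criterion_id", "weight")]
  scores <- tibble::as_tibble(scores)[c("panelist_id", "criterion_id", "intervention", "score")]
  structure(
    list(
      weights = weights,
      scores = scores,
      panelist_ids = sort(unique(c(weights$panelist_id, scores$panelist_id))),
      interventions = unique(scores$intervention)
    ),
    class = "panel_matrices"
  )
}

#' @export
print.panel_matrices <- function(x, ...) {
  cat("<panel_matrices> ", length(x$panelist_ids), " panelists, ",
      length(x$interventions), " interventions, ",
      dplyr::n_distinct(x$weights$criterion_id), " weighted criteria\n", sep = "")
  invisible(x)
}

#' Validate raw panel matrices against a criterion model
#'
#' Checks every weight lies in \[1, 5\] (or is missing), every score lies
#' within the scale bounds of its criterion (or is missing), no score refers
#' to a qualitative criterion, and all criterion ids exist in the model. All
#' violations are collected and reported together in a single error.
#'
#' @param panel A `panel_matrices` object.
#' @param model A `criterion_model` (default the EVIDEM core model).
#' @return `panel`, invisibly marked validated.
#' @export
validate_panel <- function(panel, model = evidem_core_model()) {
  stopifnot(inherits(panel, "panel_matrices"), inherits(model, "criterion_model"))
  problems <- character()

  unknown_w <- setdiff(unique(panel$weights$criterion_id), model$id)
  unknown_s <- setdiff(unique(panel$scores$criterion_id), model$id)
  for (id in union(unknown_w, unknown_s)) {
    problems <- c(problems, paste0("criterion '", id, "' not in model '",
                                   attr(model, "model_name"), "'"))
  }

  w_bad <- dplyr::filter(panel$weights, !is.na(.data$weight),
                         .data$weight < 1 | .data$weight > 5)
  problems <- c(problems, purrr::pmap_chr(w_bad, function(panelist_id, criterion_id, weight) {
    paste0("weight out of [1, 5]: panelist ", panelist_id, ", criterion ",
           criterion_id, ", value ", weight)
  }))

  sc <- dplyr::left_join(panel$scores,
                         model[c("id", "scale_kind")],
                         by = c("criterion_id" = "id"))
  sc <- dplyr::bind_cols(sc, scale_bounds(sc$scale_kind))
  qual <- dplyr::filter(sc, !is.na(.data$score), .data$scale_kind %in% "qualitative")
  problems <- c(problems, purrr::pmap_chr(
    qual[c("panelist_id", "criterion_id", "intervention", "score")],
    function(panelist_id, criterion_id, intervention, score) {
      paste0("score assigned to qualitative criterion ", criterion_id,
             " (panelist ", panelist_id, ", ", intervention, ")")
    }
  ))
  s_bad <- dplyr::filter(sc, !is.na(.data$score), !is.na(.data$lower),
                         .data$score < .data$lower | .data$score > .data$upper)
  problems <- c(problems, purrr::pmap_chr(
    s_bad[c("panelist_id", "criterion_id", "intervention", "score", "lower", "upper")],
    function(panelist_id, criterion_id, intervention, score, lower, upper) {
      paste0("score out of [", lower, ", ", upper, "]: panelist ", panelist_id,
             ", criterion ", criterion_id, ", intervention ", intervention,
             ", value ", score)
    }
  ))

  if (length(problems) > 0) {
    rlang::abort(c("panel validation failed", problems), class = "evidemcda_validation_error")
  }
  attr(panel, "validated") <- TRUE
  invisible(panel)
}

#' Aggregate a raw panel to per-criterion means and SDs
#'
#' Computes the per-criterion mean and sample standard deviation (n-1
#' denominator) of weights over non-missing panelists, and the
#' per-criterion-per-intervention mean and SD of scores — the summary a
#' committee report tabulates. A criterion counts as *scored* only if it has
#' at least one non-missing score for every intervention.
#'
#' @param panel A `panel_matrices` object.
#' @return An `aggregated_panel` object.
#' @export
aggregate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_matrices"))
  if (length(panel$panelist_ids) == 0) {
    rlang::abort("empty panel: no panelists")
  }
  w <- panel$weights |>
    dplyr::group_by(.data$criterion_id) |>
    dplyr::summarise(
      weight_mean = if (all(is.na(.data$weight))) NA_real_ else mean(.data$weight, na.rm = TRUE),
      weight_sd = sample_sd(.data$weight),
      .groups = "drop"
    )
  s <- panel$scores |>
    dplyr::group_by(.data$criterion_id, .data$intervention) |>
    dplyr::summarise(
      score_mean = if (all(is.na(.data$score))) NA_real_ else mean(.data$score, na.rm = TRUE),
      score_sd = sample_sd(.data$score),
      .groups = "drop"
    )
  aggregated_panel(w, s,
                   n_panelists = length(panel$panelist_ids),
                   interventions = panel$interventions)
}

#' Aggregated panel summary (mean/SD weights and scores)
#'
#' The committee-level object the value model consumes: mean and sample SD of
#' the weight for each criterion, and of the score for each criterion and
#' intervention. Criteria with no weight are flagged `unweighted`; criteria
#' missing a score for any intervention are flagged `unscored`.
#'
#' @param weights Tibble `criterion_id`, `weight_mean`, `weight_sd`. A missing
#'   `weight_mean` (or an absent row) marks an unweighted criterion.
#' @param scores Tibble `criterion_id`, `intervention`, `score_mean`,
#'   `score_sd`; missing means mark unscored cells.
#' @param n_panelists Number of committee members behind the summary.
#' @param interventions Intervention names, in presentation order. Defaults to
#'   their order of appearance in `scores`.
#' @return An object of class `aggregated_panel`.
#' @export
aggregated_panel <- function(weights, scores, n_panelists,
                             interventions = unique(scores$intervention)) {
  weights <- tibble::as_tibble(weights)[c("criterion_id", "weight_mean", "weight_sd")]
  scores <- tibble::as_tibble(scores)[c("criterion_id", "intervention", "score_mean", "score_sd")]
  stopifnot(n_panelists >= 1)

  bad_w <- weights$weight_mean[!is.na(weights$weight_mean)]
  if (any(bad_w < 1 | bad_w > 5)) {
    rlang::abort("weight_mean outside [1, 5]")
  }
  if (any(stats::na.omit(c(weights$weight_sd, scores$score_sd)) < 0)) {
    rlang::abort("negative SD")
  }
  if (n_panelists == 1 &&
      any(stats::na.omit(c(weights$weight_sd, scores$score_sd)) != 0)) {
    rlang::abort("SD must be 0 when n_panelists = 1")
  }

  scored_tbl <- scores |>
    dplyr::group_by(.data$criterion_id) |>
    dplyr::summarise(scored = all(!is.na(.data$score_mean)) &&
                       dplyr::n() == length(interventions),
                     .groups = "drop")
  structure(
    list(
      weights = weights,
      scores = scores,
      n_panelists = n_panelists,
      interventions = interventions,
      unweighted = union(weights$criterion_id[is.na(weights$weight_mean)],
                         setdiff(scores$criterion_id, weights$criterion_id)),
      unscored = scored_tbl$criterion_id[!scored_tbl$scored]
    ),
    class = "aggregated_panel"
  )
}

#' @export
print.aggregated_panel <- function(x, ...) {
  cat("<aggregated_panel> ", x$n_panelists, " panelists, ",
      length(x$interventions), " interventions (",
      paste(x$interventions, collapse = ", "), ")\n", sep = "")
  if (length(x$unscored) > 0)
    cat("  unscored: ", paste(x$unscored, collapse = ", "), "\n", sep = "")
  if (length(x$unweighted) > 0)
    cat("  unweighted: ", paste(x$unweighted, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in DPP-4 inhibitor appraisal fixture
#'
#' The aggregated six-member hospital committee appraisal of five DPP-4
#' inhibitors (Saxagliptin, Alogliptin, Sitagliptin, Linagliptin,
#' Vildagliptin) under the EVIDEM core model: per-criterion mean/SD weights
#' and per-criterion-per-intervention mean/SD scores. The committee assigned
#' no weight or score to *type of preventive benefit* and no scores to *other
#' medical costs* (no evidence was available for either), so those criteria
#' are flagged accordingly.
#'
#' @return A list with elements `model` (a `criterion_model`) and `panel`
#'   (an `aggregated_panel`).
#' @examples
#' fx <- dpp4_panel()
#' fx$panel
#' @export
dpp4_panel <- function() {
  weights <- readr::read_csv(
    system.file("extdata", "dpp4_weights.csv", package = "evidemcda"),
    col_types = readr::cols(
      criterion_id = readr::col_character(),
      weight_mean = readr::col_double(),
      weight_sd = readr::col_double()
    )
  )
  scores <- readr::read_csv(
    system.file("extdata", "dpp4_scores.csv", package = "evidemcda"),
    col_types = readr::cols(
      criterion_id = readr::col_character(),
      intervention = readr::col_character(),
      score_mean = readr::col_double(),
      score_sd = readr::col_double()
    )
  )
  model <- evidem_core_model()
  # keep rows in model order; preventive benefit has no weight row
  weights <- dplyr::semi_join(
    tibble::tibble(criterion_id = model$id), weights, by = "criterion_id"
  ) |>
    dplyr::left_join(weights, by = "criterion_id")
  list(
    model = model,
    panel = aggregated_panel(
      weights, scores, n_panelists = 6,
      interventions = c("Saxagliptin", "Alogliptin", "Sitagliptin",
                        "Linagliptin", "Vildagliptin")
    )
  )
}
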
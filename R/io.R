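#' Write raw panel matrices as a CSV pair
#'
#' Weights go to a wide CSV (one row per panelist, one column per criterion
#' id); scores go to a long CSV (`panelist_id`, `criterion_id`,
#' `intervention`, `score`). Missing responses are written as empty fields,
#' never zeros. UTF-8, comma-separated, header row.
#'
#' @param panel A `panel_matrices` object.
#' @param weights_path,scores_path Output file paths.
#' @return The two paths, invisibly.
#' @export
write_panel <- function(panel, weights_path, scores_path) {
  stopifnot(inherits(panel, "panel_matrices"))
  wide <- tidyr::pivot_wider(panel$weights, names_from = "criterion_id",
                             values_from = "weight")
  readr::write_csv(wide, weights_path, na = "")
  readr::write_csv(panel$scores, scores_path, na = "")
  invisible(c(weights_path, scores_path))
}

#' Read raw panel matrices from a CSV pair
#'
#' Inverse of [write_panel()]; the round trip is lossless.
#'
#' @param weights_path,scores_path Files in the panel CSV dialect.
#' @return A `panel_matrices` object.
#' @export
read_panel <- function(weights_path, scores_path) {
  wide <- readr::read_csv(weights_path, col_types = readr::cols(
    panelist_id = readr::col_character(), .default = readr::col_double()))
  weights <- tidyr::pivot_longer(wide, -"panelist_id",
                                 names_to = "criterion_id", values_to = "weight")
  scores <- readr::read_csv(scores_path, col_types = readr::cols(
    panelist_id = readr::col_character(),
    criterion_id = readr::col_character(),
    intervention = readr::col_character(),
    score = readr::col_double()
  ))
  panel_matrices(weights, scores)
}

#' Write an aggregated panel to JSON
#'
#' @param panel An `aggregated_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregated_panel <- function(panel, path) {
  stopifnot(inherits(panel, "aggregated_panel"))
  payload <- list(
    n_panelists = panel$n_panelists,
    interventions = panel$interventions,
    weights = panel$weights,
    scores = panel$scores,
    unweighted = panel$unweighted,
    unscored = panel$unscored
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an aggregated panel from JSON
#'
#' @param path File written by [write_aggregated_panel()].
#' @return An `aggregated_panel`.
#' @export
read_aggregated_panel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- tibble::as_tibble(payload$weights)
  scores <- tibble::as_tibble(payload$scores)
  weights$weight_mean <- as.numeric(weights$weight_mean)
  weights$weight_sd <- as.numeric(weights$weight_sd)
  scores$score_mean <- as.numeric(scores$score_mean)
  scores$score_sd <- as.numeric(scores$score_sd)
  aggregated_panel(weights, scores,
                   n_panelists = payload$n_panelists,
                   interventions = as.character(payload$interventions))
}
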
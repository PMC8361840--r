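#' Missing-criterion policy
#'
#' When a criterion is weighted but never scored (or vice versa), two
#' arithmetically natural treatments exist and they give different totals:
#'
#' * `"retain_weights"` — unscored criteria keep their weight in the
#'   normalization denominator and contribute a standardized score of 0. This
#'   is the package default: on the built-in DPP-4 appraisal it reproduces the
#'   committee's published totals most closely.
#' * `"renormalize_excluding"` — unscored (and unweighted) criteria are
#'   dropped before the weights are normalized, so the remaining criteria
#'   absorb their weight share.
#'
#' Criteria with no weight at all never enter the sum under either policy.
#' Both policies apply one common denominator to every intervention, so the
#' *ranking* of interventions is identical under the two.
#'
#' @param mode `"retain_weights"` or `"renormalize_excluding"`.
#' @return A `missing_policy` object.
#' @export
missing_policy <- function(mode = c("retain_weights", "renormalize_excluding")) {
  mode <- match.arg(mode)
  description <- switch(mode,
    retain_weights = paste(
      "unscored criteria keep their weight in the normalization denominator",
      "and contribute a standardized score of 0"),
    renormalize_excluding = paste(
      "unscored or unweighted criteria are removed before weight",
      "normalization; remaining weights are rescaled to unit sum")
  )
  structure(list(mode = mode, description = description), class = "missing_policy")
}

as_missing_policy <- function(policy) {
  if (inherits(policy, "missing_policy")) return(policy)
  missing_policy(policy)
}

#' Normalize panel weights to unit sum
#'
#' Divides each criterion's mean weight by the sum of mean weights over the
#' denominator set chosen by the missing-criterion policy, yielding the
#' dimensionless normalized weights `Wx` with `sum(Wx) = 1`.
#'
#' @param panel An `aggregated_panel`.
#' @param policy A [missing_policy()] (or its mode string).
#' @return A tibble `criterion_id`, `weight_mean`, `Wx` over the included
#'   criteria, with attributes `denominator` (the weight sum) and `policy`.
#' @export
normalize_weights <- function(panel, policy = missing_policy()) {
  stopifnot(inherits(panel, "aggregated_panel"))
  policy <- as_missing_policy(policy)
  w <- dplyr::filter(panel$weights, !is.na(.data$weight_mean))
  if (policy$mode == "renormalize_excluding") {
    w <- dplyr::filter(w, !(.data$criterion_id %in% panel$unscored))
  }
  usable <- setdiff(w$criterion_id, panel$unscored)
  if (length(usable) == 0) {
    rlang::abort("no criterion is both weighted and scored")
  }
  denom <- sum(w$weight_mean)
  if (denom <= 0) {
    rlang::abort("weight normalization denominator is zero")
  }
  out <- dplyr::mutate(w, Wx = .data$weight_mean / denom)
  attr(out, "denominator") <- denom
  attr(out, "policy") <- policy
  out
}

#' Standardize a raw-scale score
#'
#' Maps a committee mean score to the dimensionless `Sx` by dividing by 5, for
#' both scale kinds: an absolute 5 becomes 1, a relative -5 becomes -1. The
#' sign of comparative effects is preserved — a negative `Sx` means the
#' intervention performs worse than its comparator on that criterion.
#'
#' @param score Numeric score(s) on the elicitation scale; `NA` passes through.
#' @param scale_kind `"absolute"` or `"relative"`, recycled against `score`.
#' @return Standardized score(s) in \[0, 1\] (absolute) or \[-1, 1\] (relative).
#' @export
standardize_score <- function(score, scale_kind) {
  b <- scale_bounds(scale_kind)
  if (any(is.na(b$lower))) {
    rlang::abort("scale_kind must be 'absolute' or 'relative'")
  }
  ok <- is.na(score) | (score >= b$lower & score <= b$upper)
  if (!all(ok)) {
    rlang::abort(paste0("score out of range for its scale: ",
                        paste(score[!ok], collapse = ", ")))
  }
  score / 5
}

#' Compute the linear additive MCDA value estimate
#'
#' For each intervention, combines the normalized weights `Wx` with the
#' standardized scores `Sx` into per-criterion value contributions
#' `Vx = Wx * Sx` and the total value estimate `V = sum(Vx)` — the EVIDEM core
#' model's linear additive value. `V` lies in \[-1, 1\], and in \[0, 1\] when
#' no criterion scores below its comparator.
#'
#' @param panel An `aggregated_panel`.
#' @param policy A [missing_policy()]; default `"retain_weights"`.
#' @param model The `criterion_model` giving each criterion's scale kind.
#' @return An object of class `mcda_value`: a list with `values` (tibble
#'   `intervention`, `total`, `n_criteria`, input order preserved),
#'   `contributions` (tibble `intervention`, `criterion_id`, `weight_mean`,
#'   `Wx`, `score_mean`, `Sx`, `Vx`), the normalized `weights`, `policy`, and
#'   the weight `denominator`.
#' @examples
#' fx <- dpp4_panel()
#' v <- compute_value(fx$panel)
#' v$values
#' @export
compute_value <- function(panel, policy = missing_policy(), model = evidem_core_model()) {
  stopifnot(inherits(panel, "aggregated_panel"))
  policy <- as_missing_policy(policy)
  dead <- panel$scores |>
    dplyr::group_by(.data$intervention) |>
    dplyr::summarise(none = all(is.na(.data$score_mean)), .groups = "drop") |>
    dplyr::filter(.data$none)
  if (nrow(dead) > 0) {
    rlang::abort(paste0("intervention with all scores missing: ",
                        paste(dead$intervention, collapse = ", ")))
  }
  nw <- normalize_weights(panel, policy)

  contrib <- nw |>
    dplyr::inner_join(panel$scores, by = "criterion_id",
                      relationship = "one-to-many") |>
    dplyr::left_join(model[c("id", "scale_kind")], by = c("criterion_id" = "id")) |>
    dplyr::mutate(
      Sx = dplyr::if_else(is.na(.data$score_mean), 0,
                          standardize_score(.data$score_mean, .data$scale_kind)),
      Vx = .data$Wx * .data$Sx,
      intervention = factor(.data$intervention, levels = panel$interventions)
    ) |>
    dplyr::arrange(.data$intervention) |>
    dplyr::mutate(intervention = as.character(.data$intervention)) |>
    dplyr::select("intervention", "criterion_id", "weight_mean", "Wx",
                  "score_mean", "Sx", "Vx")

  values <- contrib |>
    dplyr::group_by(.data$intervention) |>
    dplyr::summarise(total = sum(.data$Vx), n_criteria = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$intervention, panel$interventions))

  structure(
    list(values = values, contributions = contrib, weights = nw,
         policy = policy, denominator = attr(nw, "denominator"),
         n_panelists = panel$n_panelists),
    class = "mcda_value"
  )
}

#' @export
print.mcda_value <- function(x, ...) {
  cat("<mcda_value> policy = ", x$policy$mode,
      ", weight denominator = ", format(x$denominator), "\n", sep = "")
  print(dplyr::mutate(x$values, total = round_half_up(.data$total, 2)))
  invisible(x)
}

#' Rank interventions by value estimate
#'
#' Orders interventions by descending total value. Tied interventions share
#' the minimum rank and are listed alphabetically within the tie; the result
#' is invariant to the input order.
#'
#' @param estimates An `mcda_value` object, or a data frame with columns
#'   `intervention` and `total`.
#' @return A tibble `rank`, `intervention`, `total`, ordered best first.
#' @export
rank_interventions <- function(estimates) {
  values <- if (inherits(estimates, "mcda_value")) estimates$values else tibble::as_tibble(estimates)
  stopifnot(nrow(values) > 0, all(c("intervention", "total") %in% names(values)))
  values |>
    dplyr::mutate(rank = as.integer(rank(-.data$total, ties.method = "min"))) |>
    dplyr::arrange(.data$rank, .data$intervention) |>
    dplyr::select("rank", "intervention", "total")
}

#' Decompose one intervention's value estimate
#'
#' Breaks a value estimate into its per-criterion contributions, with each
#' row's share of the absolute total. Shares sum to 1 when `V != 0` and are
#' reported empty (`NaN`) for a degenerate all-zero estimate.
#'
#' @param estimates An `mcda_value` object.
#' @param intervention Which intervention to decompose; defaults to the first.
#' @return A tibble `criterion_id`, `Wx`, `Sx`, `Vx`, `share`, with attribute
#'   `total`.
#' @export
decompose_value <- function(estimates, intervention = NULL) {
  stopifnot(inherits(estimates, "mcda_value"))
  intervention <- intervention %||% estimates$values$intervention[[1]]
  rows <- dplyr::filter(estimates$contributions, .data$intervention == !!intervention)
  if (nrow(rows) == 0) {
    rlang::abort(paste0("unknown intervention '", intervention, "'"))
  }
  total <- sum(rows$Vx)
  out <- rows |>
    dplyr::transmute(
      criterion_id = .data$criterion_id,
      Wx = .data$Wx, Sx = .data$Sx, Vx = .data$Vx,
      share = if (total == 0) NaN else .data$Vx / abs(total)
    )
  attr(out, "total") <- total
  attr(out, "intervention") <- intervention
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MCDA value estimate
#'
#' @param x An `mcda_value` object.
#' @param ... Unused.
#' @return The long contribution tibble: one row per intervention-criterion
#'   pair with `Wx`, `Sx` and `Vx`.
#' @method tidy mcda_value
#' @export
tidy.mcda_value <- function(x, ...) {
  x$contributions
}

#' One-row summary of an MCDA value estimate
#'
#' @param x An `mcda_value` object.
#' @param ... Unused.
#' @return A one-row tibble: number of interventions and criteria, the policy,
#'   the weight denominator, and the best intervention with its value.
#' @method glance mcda_value
#' @export
glance.mcda_value <- function(x, ...) {
  rk <- rank_interventions(x)
  tibble::tibble(
    n_interventions = nrow(x$values),
    n_criteria = x$values$n_criteria[[1]],
    policy = x$policy$mode,
    weight_denominator = x$denominator,
    top_intervention = rk$intervention[[1]],
    top_value = rk$total[[1]]
  )
}

#' Stacked contribution-bar plot of value estimates
#'
#' One bar per intervention, segmented by each criterion's value contribution
#' `Vx`; negative contributions (criteria scored below the comparator) stack
#' below zero. The bar heights net to each intervention's total `V`.
#'
#' @param object An `mcda_value` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcda_value
#' @export
autoplot.mcda_value <- function(object, ...) {
  df <- contribution_chart_data(object)
  totals <- object$values
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intervention, y = .data$Vx,
                                   fill = .data$criterion_id)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = totals,
                        ggplot2::aes(x = .data$intervention, y = .data$total),
                        inherit.aes = FALSE, shape = 18, size = 2) +
    ggplot2::labs(x = NULL, y = "value contribution Vx",
                  fill = "criterion",
                  title = "MCDA value estimate by criterion contribution") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
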
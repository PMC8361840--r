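#' Synthetic panel profile
#'
#' Describes the committee a synthetic elicitation should emulate: how many
#' panelists, which interventions, and per-criterion (mean, SD) targets for
#' weights and scores on their elicitation scales. The reference committee
#' shape is six members (two doctors, a nurse, a pharmacist, a health
#' economist and a decision-maker) scoring five interventions.
#'
#' @param weights Tibble `criterion_id`, `mean`, `sd` — weight targets on the
#'   1-5 importance scale.
#' @param scores Tibble `criterion_id`, `intervention`, `mean`, `sd` — score
#'   targets on each criterion's scale. Omit cells the committee left unscored.
#' @param n_panelists Committee size (>= 2 whenever any target SD > 0).
#' @param model `criterion_model` giving scale bounds.
#' @param integer_scores Draw scores as integers on the scale (the elicitation
#'   instrument) rather than continuous values.
#' @param fractional_weights Allow fractional weights in \[1, 5\] (committee
#'   rescaling upstream of aggregation can make them non-integer).
#' @param missing_scores Criterion ids to emit as explicitly missing (`NA`)
#'   score rows for every intervention.
#' @param seed Default integer seed used by [generate_panel()].
#' @return An object of class `panel_profile`.
#' @export
panel_profile <- function(weights, scores, n_panelists,
                          model = evidem_core_model(),
                          integer_scores = TRUE, fractional_weights = TRUE,
                          missing_scores = character(), seed = 1L) {
  weights <- tibble::as_tibble(weights)[c("criterion_id", "mean", "sd")]
  scores <- tibble::as_tibble(scores)[c("criterion_id", "intervention", "mean", "sd")]
  stopifnot(n_panelists >= 1)
  if (n_panelists < 2 && any(c(weights$sd, scores$sd) > 0)) {
    rlang::abort("n_panelists must be >= 2 when any target SD is > 0")
  }
  bad_w <- weights$criterion_id[weights$mean < 1 | weights$mean > 5]
  if (length(bad_w) > 0) {
    rlang::abort(paste0("weight target mean outside [1, 5] for: ",
                        paste(bad_w, collapse = ", ")))
  }
  sk <- model$scale_kind[match(scores$criterion_id, model$id)]
  b <- scale_bounds(sk)
  bad_s <- scores$criterion_id[is.na(b$lower) |
                                 scores$mean < b$lower | scores$mean > b$upper]
  if (length(bad_s) > 0) {
    rlang::abort(paste0("score target mean outside its scale for: ",
                        paste(unique(bad_s), collapse = ", ")))
  }
  # an integer column of length n on [lo, hi] cannot exceed the two-point
  # extreme-split sample SD; reject targets beyond it, naming the criterion
  sd_cap <- (b$upper - b$lower) / 2 * sqrt(n_panelists / (n_panelists - 1 + 1e-12))
  infeasible <- scores$criterion_id[scores$sd > sd_cap]
  if (length(infeasible) > 0) {
    rlang::abort(paste0("score SD target unreachable on the scale for: ",
                        paste(unique(infeasible), collapse = ", ")))
  }
  structure(
    list(weights = weights, scores = scores,
         n_panelists = as.integer(n_panelists),
         interventions = unique(scores$intervention),
         model = model,
         integer_scores = integer_scores,
         fractional_weights = fractional_weights,
         missing_scores = missing_scores,
         seed = as.integer(seed)),
    class = "panel_profile"
  )
}

#' Profile matching the DPP-4 inhibitor appraisal
#'
#' A [panel_profile()] whose weight and score targets are exactly the
#' aggregated DPP-4 committee tables ([dpp4_panel()]): six panelists, integer
#' scores, fractional weights, five interventions, with *type of preventive
#' benefit* unweighted/unscored and *other medical costs* unscored.
#'
#' @param seed Default seed passed through to [generate_panel()].
#' @return A `panel_profile`.
#' @export
dpp4_profile <- function(seed = 1L) {
  fx <- dpp4_panel()
  w <- fx$panel$weights |>
    dplyr::filter(!is.na(.data$weight_mean)) |>
    dplyr::rename(mean = "weight_mean", sd = "weight_sd")
  s <- fx$panel$scores |>
    dplyr::filter(!is.na(.data$score_mean)) |>
    dplyr::rename(mean = "score_mean", sd = "score_sd")
  panel_profile(w, s, n_panelists = 6, model = fx$model,
                integer_scores = TRUE, fractional_weights = TRUE,
                missing_scores = fx$panel$unscored, seed = seed)
}

# greedy repair: nudge single entries by one scale step until the column sum
# hits the closest achievable integer sum to n * target mean, breaking ties
# toward the target SD
repair_integer_column <- function(x, target_mean, target_sd, lo, hi) {
  n <- length(x)
  target_sum <- min(max(round_half_up(target_mean * n, 0), n * lo), n * hi)
  while (sum(x) != target_sum) {
    step <- sign(target_sum - sum(x))
    eligible <- which(if (step > 0) x < hi else x > lo)
    cand_sd <- vapply(eligible, function(i) {
      y <- x; y[i] <- y[i] + step; sample_sd(y)
    }, numeric(1))
    pick <- eligible[which.min(abs(cand_sd - target_sd))]
    x[pick] <- x[pick] + step
  }
  x
}

draw_column <- function(n, mean, sd, lo, hi, integer) {
  x <- rtruncnorm_inv(n, mean, sd, lo, hi)
  if (integer) {
    x <- pmin(pmax(round_half_up(x, 0), lo), hi)
    # a zero-dispersion target pins every panelist to the (rounded) mean;
    # otherwise nudge entries until the column mean is as close as the
    # integer scale allows
    if (sd == 0) x else repair_integer_column(x, mean, sd, lo, hi)
  } else {
    # recentre on the target mean; clamping can bias near the bounds, so
    # iterate the shift a few times
    for (i in 1:5) {
      x <- pmin(pmax(x + (mean - mean(x)), lo), hi)
    }
    x
  }
}

#' Generate a synthetic panelist-level elicitation
#'
#' Draws raw panelist weight and score matrices whose per-criterion sample
#' means and SDs target a [panel_profile()]. Scores are drawn as truncated
#' normals rounded to the nearest scale point, then individual entries are
#' nudged one step at a time until the column mean is the closest achievable
#' to its target (SD targets are matched softly, in expectation over
#' replicates — exact integer (mean, SD) solutions do not always exist at
#' small n). Fractional weights are recentred on their target mean. The
#' result always passes [validate_panel()].
#'
#' @param profile A `panel_profile`.
#' @param seed Integer seed; defaults to the profile's. Same seed, same panel.
#' @return A `panel_matrices` object with panelists `p1..pn`.
#' @examples
#' prof <- dpp4_profile(seed = 7)
#' panel <- generate_panel(prof)
#' aggregate_panel(panel)
#' @export
generate_panel <- function(profile, seed = profile$seed) {
  stopifnot(inherits(profile, "panel_profile"))
  set.seed(as.integer(seed))
  n <- profile$n_panelists
  ids <- paste0("p", seq_len(n))

  weights <- profile$weights |>
    dplyr::mutate(draw = purrr::map2(.data$mean, .data$sd, function(m, s) {
      draw_column(n, m, s, 1, 5, integer = !profile$fractional_weights)
    })) |>
    dplyr::select("criterion_id", "draw") |>
    tidyr::unnest_longer("draw", values_to = "weight") |>
    dplyr::mutate(panelist_id = rep(ids, times = nrow(profile$weights)))

  sk <- profile$model$scale_kind[match(profile$scores$criterion_id, profile$model$id)]
  b <- scale_bounds(sk)
  scores <- profile$scores |>
    dplyr::mutate(lower = b$lower, upper = b$upper) |>
    dplyr::mutate(draw = purrr::pmap(
      list(.data$mean, .data$sd, .data$lower, .data$upper),
      function(m, s, lo, hi) draw_column(n, m, s, lo, hi,
                                         integer = profile$integer_scores))) |>
    dplyr::select("criterion_id", "intervention", "draw") |>
    tidyr::unnest_longer("draw", values_to = "score") |>
    dplyr::mutate(panelist_id = rep(ids, times = nrow(profile$scores)))

  if (length(profile$missing_scores) > 0) {
    na_rows <- tidyr::expand_grid(
      criterion_id = profile$missing_scores,
      intervention = profile$interventions,
      panelist_id = ids
    )
    na_rows$score <- NA_real_
    scores <- dplyr::bind_rows(scores, na_rows)
  }
  scores$intervention <- factor(scores$intervention, levels = profile$interventions)
  scores <- dplyr::arrange(scores, match(.data$criterion_id, profile$model$id),
                           .data$intervention)
  scores$intervention <- as.character(scores$intervention)

  panel_matrices(weights[c("panelist_id", "criterion_id", "weight")],
                 scores[c("panelist_id", "criterion_id", "intervention", "score")])
}
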
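# inverse-CDF truncated-normal sampler; degenerate (sd = 0) returns the mean
rtruncnorm_inv <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

#' Monte-Carlo rank-stability analysis
#'
#' Propagates the panel's reported dispersion through the value model to ask
#' how stable the purchasing order is. Per draw, every mean weight is
#' resampled from a normal centred at its mean — by default with the standard
#' error of the mean, `SD / sqrt(n_panelists)`, as spread — truncated to
#' \[1, 5\], and every mean score likewise truncated to its criterion's scale;
#' the value model and ranking are then recomputed and rank frequencies
#' tabulated. Weights and scores are resampled independently per criterion (no
#' covariance between criteria is available from an aggregated panel). This is
#' an uncertainty extension around the deterministic appraisal, not part of
#' the committee procedure itself.
#'
#' @param panel An `aggregated_panel` with SD columns present.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param policy A [missing_policy()].
#' @param model The `criterion_model`.
#' @param spread `"standard_error"` (default) resamples the panel *mean*;
#'   `"raw_sd"` uses the raw panel SD to explore panel heterogeneity instead.
#' @return An object of class `rank_stability`: `rank_probability` (tibble
#'   `intervention` x `rank` with probabilities; rows and columns each sum to
#'   1), `summary` (per-intervention mean V and central 95% interval),
#'   `n_draws`, `seed`, `policy`, `spread`.
#' @examples
#' fx <- dpp4_panel()
#' st <- simulate_ranks(fx$panel, n_draws = 500, seed = 1)
#' st$rank_probability
#' @export
simulate_ranks <- function(panel, n_draws, seed, policy = missing_policy(),
                           model = evidem_core_model(),
                           spread = c("standard_error", "raw_sd")) {
  stopifnot(inherits(panel, "aggregated_panel"), n_draws >= 1)
  policy <- as_missing_policy(policy)
  spread <- match.arg(spread)

  w_used <- dplyr::filter(panel$weights, !is.na(.data$weight_mean))
  s_used <- dplyr::filter(panel$scores, !is.na(.data$score_mean),
                          .data$criterion_id %in% w_used$criterion_id)
  if (anyNA(w_used$weight_sd) || anyNA(s_used$score_sd)) {
    rlang::abort(paste(
      "SD columns are required for rank-stability simulation;",
      "use compute_value() for a point estimate"))
  }
  s_used <- dplyr::left_join(s_used, model[c("id", "scale_kind")],
                             by = c("criterion_id" = "id"))
  s_used <- dplyr::bind_cols(s_used, scale_bounds(s_used$scale_kind))
  se_div <- if (spread == "standard_error") sqrt(panel$n_panelists) else 1

  interventions <- panel$interventions
  k <- length(interventions)
  scored_crit <- setdiff(w_used$criterion_id, panel$unscored)

  set.seed(as.integer(seed))
  # weight draws: n_draws x weighted criteria
  W <- vapply(seq_len(nrow(w_used)), function(j) {
    rtruncnorm_inv(n_draws, w_used$weight_mean[j],
                   w_used$weight_sd[j] / se_div, 1, 5)
  }, numeric(n_draws))
  if (n_draws == 1) W <- matrix(W, nrow = 1)
  colnames(W) <- w_used$criterion_id

  denom_cols <- if (policy$mode == "retain_weights") w_used$criterion_id else scored_crit
  denom <- rowSums(W[, denom_cols, drop = FALSE])

  # score draws per intervention: numerator V*denom*5 = sum_c w_c * s_c
  V <- matrix(NA_real_, nrow = n_draws, ncol = k,
              dimnames = list(NULL, interventions))
  for (iv in interventions) {
    cells <- s_used[s_used$intervention == iv, ]
    S <- vapply(seq_len(nrow(cells)), function(j) {
      rtruncnorm_inv(n_draws, cells$score_mean[j],
                     cells$score_sd[j] / se_div,
                     cells$lower[j], cells$upper[j])
    }, numeric(n_draws))
    if (n_draws == 1) S <- matrix(S, nrow = 1)
    num <- rowSums(W[, cells$criterion_id, drop = FALSE] * S)
    V[, iv] <- num / (5 * denom)
  }

  ranks <- t(apply(-V, 1, rank, ties.method = "min"))
  if (n_draws == 1) ranks <- matrix(ranks, nrow = 1, dimnames = list(NULL, interventions))
  rank_counts <- matrix(0, nrow = k, ncol = k,
                        dimnames = list(interventions, paste0("rank_", seq_len(k))))
  for (iv in interventions) {
    tab <- tabulate(ranks[, iv], nbins = k)
    rank_counts[iv, ] <- tab
  }

  summary <- tibble::tibble(
    intervention = interventions,
    mean_V = unname(colMeans(V)[interventions]),
    lower = unname(apply(V, 2, stats::quantile, probs = 0.025)[interventions]),
    upper = unname(apply(V, 2, stats::quantile, probs = 0.975)[interventions])
  )
  structure(
    list(
      rank_probability = tibble::as_tibble(rank_counts / n_draws,
                                           rownames = "intervention"),
      summary = summary,
      n_draws = n_draws, seed = as.integer(seed), policy = policy,
      spread = spread
    ),
    class = "rank_stability"
  )
}

#' @export
print.rank_stability <- function(x, ...) {
  cat("<rank_stability> ", x$n_draws, " draws, seed ", x$seed,
      ", policy ", x$policy$mode, "\n", sep = "")
  print(x$rank_probability)
  invisible(x)
}

#' Tidy a rank-stability result
#'
#' @param x A `rank_stability` object.
#' @param ... Unused.
#' @return Long tibble `intervention`, `rank`, `probability`.
#' @method tidy rank_stability
#' @export
tidy.rank_stability <- function(x, ...) {
  x$rank_probability |>
    tidyr::pivot_longer(-"intervention", names_to = "rank",
                        names_prefix = "rank_", names_transform = as.integer,
                        values_to = "probability")
}

#' Rank-probability heatmap
#'
#' @param object A `rank_stability` object.
#' @param ... Unused.
#' @return A ggplot object: intervention x rank tile map of rank probabilities.
#' @method autoplot rank_stability
#' @export
autoplot.rank_stability <- function(object, ...) {
  df <- tidy(object)
  ord <- object$summary$intervention[order(object$summary$mean_V)]
  df$intervention <- factor(df$intervention, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$intervention,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "rank", y = NULL, fill = "P(rank)",
                  title = "Rank acceptability under resampled weights and scores") +
    ggplot2::theme_minimal()
}
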
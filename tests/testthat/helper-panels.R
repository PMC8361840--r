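# shared fixtures and an independent brute-force value oracle

# a random aggregated panel over a subset of the core model; optionally with
# one criterion left unscored to exercise the missing-criterion policies
random_aggregated_panel <- function(n_crit = NULL, n_int = NULL,
                                    with_unscored = FALSE) {
  model <- evidem_core_model()
  n_crit <- n_crit %||% sample(2:13, 1)
  n_int <- n_int %||% sample(1:6, 1)
  crit <- model[sort(sample(nrow(model), n_crit)), ]
  interventions <- paste0("drug", seq_len(n_int))
  weights <- tibble::tibble(
    criterion_id = crit$id,
    weight_mean = round(stats::runif(n_crit, 1, 5), 3),
    weight_sd = round(stats::runif(n_crit, 0, 1), 3)
  )
  b <- scale_bounds(crit$scale_kind)
  scores <- tidyr::expand_grid(criterion_id = crit$id,
                               intervention = interventions)
  idx <- match(scores$criterion_id, crit$id)
  scores$score_mean <- round(stats::runif(nrow(scores), b$lower[idx], b$upper[idx]), 3)
  scores$score_sd <- round(stats::runif(nrow(scores), 0, 1.5), 3)
  if (with_unscored && n_crit > 1) {
    drop <- sample(crit$id, 1)
    scores$score_mean[scores$criterion_id == drop] <- NA_real_
    scores$score_sd[scores$criterion_id == drop] <- NA_real_
  }
  aggregated_panel(weights, scores, n_panelists = sample(2:8, 1),
                   interventions = interventions)
}

# brute-force oracle: plain loops and base arithmetic, sharing no code with
# compute_value()
oracle_values <- function(panel, policy_mode) {
  w <- panel$weights[!is.na(panel$weights$weight_mean), ]
  unscored <- panel$unscored
  denom_ids <- if (policy_mode == "retain_weights") {
    w$criterion_id
  } else {
    setdiff(w$criterion_id, unscored)
  }
  denom <- 0
  for (id in denom_ids) denom <- denom + w$weight_mean[w$criterion_id == id]
  out <- numeric(length(panel$interventions))
  names(out) <- panel$interventions
  for (iv in panel$interventions) {
    v <- 0
    for (id in denom_ids) {
      sm <- panel$scores$score_mean[panel$scores$criterion_id == id &
                                      panel$scores$intervention == iv]
      s <- if (length(sm) == 0 || is.na(sm)) 0 else sm / 5
      v <- v + (w$weight_mean[w$criterion_id == id] / denom) * s
    }
    out[iv] <- v
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# published committee totals for the five DPP-4 inhibitors
dpp4_published <- c(Saxagliptin = 0.40, Alogliptin = 0.42, Sitagliptin = 0.45,
                    Linagliptin = 0.44, Vildagliptin = 0.43)
dpp4_order <- c("Sitagliptin", "Linagliptin", "Vildagliptin",
                "Alogliptin", "Saxagliptin")
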
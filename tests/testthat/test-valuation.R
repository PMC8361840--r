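test_that("normalized weights hit the hand-computed fixture values under both policies", {
  fx <- dpp4_panel()
  retain <- normalize_weights(fx$panel, "retain_weights")
  expect_equal(attr(retain, "denominator"), 41.70)
  expect_equal(retain$Wx[retain$criterion_id == "quality_of_evidence"],
               4.01 / 41.70)
  expect_equal(sum(retain$Wx), 1, tolerance = 1e-12)

  renorm <- normalize_weights(fx$panel, "renormalize_excluding")
  expect_equal(attr(renorm, "denominator"), 38.40)
  expect_equal(renorm$Wx[renorm$criterion_id == "quality_of_evidence"],
               4.01 / 38.40)
  expect_false("other_medical_costs" %in% renorm$criterion_id)
  expect_equal(sum(renorm$Wx), 1, tolerance = 1e-12)

  # uniform case
  eq <- aggregated_panel(
    tibble::tibble(criterion_id = c("disease_severity", "unmet_needs",
                                    "quality_of_evidence", "comparative_effectiveness"),
                   weight_mean = 3, weight_sd = 0),
    tidyr::expand_grid(criterion_id = c("disease_severity", "unmet_needs",
                                        "quality_of_evidence", "comparative_effectiveness"),
                       intervention = "drugA") |>
      dplyr::mutate(score_mean = 2, score_sd = 0),
    n_panelists = 3)
  expect_equal(normalize_weights(eq)$Wx, rep(0.25, 4))
})

test_that("score standardization divides by 5 and preserves sign", {
  expect_equal(standardize_score(5, "absolute"), 1)
  expect_equal(standardize_score(-5, "relative"), -1)
  expect_equal(standardize_score(4.33, "absolute"), 0.866)
  expect_error(standardize_score(6, "absolute"), "out of range")
  expect_error(standardize_score(-1, "absolute"), "out of range")
  expect_error(standardize_score(2, "qualitative"), "scale_kind")
})

test_that("fixture value estimates reproduce the published totals and exact ranking", {
  fx <- dpp4_panel()
  for (mode in c("retain_weights", "renormalize_excluding")) {
    est <- compute_value(fx$panel, mode)
    rk <- rank_interventions(est)
    expect_equal(rk$intervention, dpp4_order)     # ranking exact under both
    # the zero-contribution unscored criterion stays in the sum only when retained
    expect_equal(est$values$n_criteria[1],
                 if (mode == "retain_weights") 12 else 11)
  }
  est <- compute_value(fx$panel, "retain_weights")
  totals <- setNames(est$values$total, est$values$intervention)
  expect_lt(max(abs(totals[names(dpp4_published)] - dpp4_published)), 0.02)
  # frozen against the brute-force oracle
  expect_equal(unname(totals["Sitagliptin"]), 91.2731 / (5 * 41.70),
               tolerance = 1e-10)
})

test_that("compute_value matches the brute-force oracle on random panels", {
  set.seed(2026)
  for (i in 1:300) {
    panel <- random_aggregated_panel(with_unscored = i %% 3 == 0)
    mode <- if (i %% 2 == 0) "retain_weights" else "renormalize_excluding"
    est <- compute_value(panel, mode)
    got <- setNames(est$values$total, est$values$intervention)
    want <- oracle_values(panel, mode)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("analytic limits: scale maxima give V = 1, minima give minus the relative share", {
  model <- evidem_core_model()
  crit <- model[model$id %in% c("disease_severity", "quality_of_evidence",
                                "comparative_effectiveness", "cost_of_intervention"), ]
  w <- tibble::tibble(criterion_id = crit$id,
                      weight_mean = c(4, 2, 3.5, 1.5), weight_sd = 0)
  b <- scale_bounds(crit$scale_kind)
  maxed <- tidyr::expand_grid(criterion_id = crit$id, intervention = "drugA") |>
    dplyr::mutate(score_mean = 5, score_sd = 0)
  mined <- maxed |>
    dplyr::mutate(score_mean = b$lower[match(criterion_id, crit$id)])
  for (mode in c("retain_weights", "renormalize_excluding")) {
    vmax <- compute_value(aggregated_panel(w, maxed, 2), mode)$values$total
    expect_equal(vmax, 1, tolerance = 1e-12)
    vmin <- compute_value(aggregated_panel(w, mined, 2), mode)$values$total
    rel_share <- sum(w$weight_mean[crit$scale_kind == "relative"]) / sum(w$weight_mean)
    expect_equal(vmin, -rel_share, tolerance = 1e-12)
  }
})

test_that("a single included criterion forces W = 1 and V = Sx", {
  p <- aggregated_panel(
    tibble::tibble(criterion_id = "unmet_needs", weight_mean = 2.2, weight_sd = 0),
    tibble::tibble(criterion_id = "unmet_needs", intervention = "drugA",
                   score_mean = 3.5, score_sd = 0),
    n_panelists = 3)
  est <- compute_value(p)
  expect_equal(est$weights$Wx, 1)
  expect_equal(est$values$total, 3.5 / 5)
})

test_that("raising one score never lowers that intervention's value", {
  set.seed(99)
  for (i in 1:25) {
    panel <- random_aggregated_panel(n_crit = 5, n_int = 2)
    base <- compute_value(panel)$values
    row <- sample(nrow(panel$scores), 1)
    kind <- evidem_core_model()$scale_kind[
      match(panel$scores$criterion_id[row], evidem_core_model()$id)]
    hi <- scale_bounds(kind)$upper
    bumped <- panel
    bumped$scores$score_mean[row] <- min(hi, bumped$scores$score_mean[row] + 0.5)
    after <- compute_value(bumped)$values
    iv <- panel$scores$intervention[row]
    expect_gte(after$total[after$intervention == iv] + 1e-12,
               base$total[base$intervention == iv])
    # untouched interventions unchanged
    other <- setdiff(base$intervention, iv)
    expect_equal(after$total[match(other, after$intervention)],
                 base$total[match(other, base$intervention)])
  }
})

test_that("adding an intervention leaves existing value estimates unchanged", {
  set.seed(7)
  panel <- random_aggregated_panel(n_crit = 6, n_int = 2, with_unscored = TRUE)
  extra_scores <- panel$scores |>
    dplyr::filter(intervention == panel$interventions[1]) |>
    dplyr::mutate(intervention = "drug_new",
                  score_mean = ifelse(is.na(score_mean), NA, 1))
  bigger <- aggregated_panel(panel$weights,
                             dplyr::bind_rows(panel$scores, extra_scores),
                             panel$n_panelists,
                             c(panel$interventions, "drug_new"))
  a <- compute_value(panel)$values
  b <- compute_value(bigger)$values
  expect_equal(b$total[match(a$intervention, b$intervention)], a$total)
})

test_that("ranking is order-invariant and ties share the minimum rank alphabetically", {
  vals <- tibble::tibble(intervention = c("b_drug", "a_drug", "c_drug"),
                         total = c(0.3, 0.3, 0.5))
  rk <- rank_interventions(vals)
  expect_equal(rk$rank, c(1L, 2L, 2L))
  expect_equal(rk$intervention, c("c_drug", "a_drug", "b_drug"))
  shuffled <- rank_interventions(vals[c(3, 1, 2), ])
  expect_equal(shuffled, rk)
  one <- rank_interventions(tibble::tibble(intervention = "x", total = 0))
  expect_equal(one$rank, 1L)
})

test_that("value decomposition yields contributions summing to V and unit shares", {
  fx <- dpp4_panel()
  est <- compute_value(fx$panel)
  d <- decompose_value(est, "Sitagliptin")
  expect_equal(sum(d$Vx), attr(d, "total"))
  expect_equal(sum(d$share), 1, tolerance = 1e-12)
  neg <- d$criterion_id[d$Vx < 0]
  expect_setequal(neg, c("patient_perceived_health_pro", "cost_of_intervention",
                         "non_medical_costs"))

  # two-contribution arithmetic identity
  p <- aggregated_panel(
    tibble::tibble(criterion_id = c("unmet_needs", "disease_severity"),
                   weight_mean = c(3, 3), weight_sd = 0),
    tidyr::expand_grid(criterion_id = c("unmet_needs", "disease_severity"),
                       intervention = "drugA") |>
      dplyr::mutate(score_mean = c(2, 1), score_sd = 0),
    n_panelists = 2)
  est2 <- compute_value(p)
  d2 <- decompose_value(est2)
  expect_equal(sort(d2$Vx), sort(c(0.1, 0.2)), tolerance = 1e-12)
  expect_equal(sort(d2$share), sort(c(1 / 3, 2 / 3)), tolerance = 1e-12)

  # degenerate all-zero estimate: undefined shares
  z <- aggregated_panel(
    tibble::tibble(criterion_id = "unmet_needs", weight_mean = 3, weight_sd = 0),
    tibble::tibble(criterion_id = "unmet_needs", intervention = "drugA",
                   score_mean = 0, score_sd = 0),
    n_panelists = 2)
  dz <- decompose_value(compute_value(z))
  expect_equal(attr(dz, "total"), 0)
  expect_true(all(is.nan(dz$share)))
})

test_that("an intervention with no scores at all is refused by name", {
  p <- aggregated_panel(
    tibble::tibble(criterion_id = c("unmet_needs", "disease_severity"),
                   weight_mean = 3, weight_sd = 0),
    tidyr::expand_grid(criterion_id = c("unmet_needs", "disease_severity"),
                       intervention = c("drugA", "ghost")) |>
      dplyr::mutate(score_mean = ifelse(intervention == "ghost", NA, 3),
                    score_sd = ifelse(intervention == "ghost", NA, 0)),
    n_panelists = 2)
  expect_error(compute_value(p, "retain_weights"), "ghost")
})

test_that("tidy, glance and autoplot expose the fit the broom way", {
  est <- compute_value(dpp4_panel()$panel)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5 * 12)
  gl <- glance(est)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$top_intervention, "Sitagliptin")
  expect_equal(gl$policy, "retain_weights")
  plt <- ggplot2::autoplot(est)
  expect_s3_class(plt, "ggplot")
})
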
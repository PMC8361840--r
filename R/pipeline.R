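#' Pipeline run configuration
#'
#' Bundles everything one appraisal run needs: where the aggregated panel
#' comes from, the missing-criterion policy, rounding for display, and the
#' Monte-Carlo settings for the optional rank-stability stage.
#'
#' @param panel Path to an aggregated-panel JSON ([write_aggregated_panel()])
#'   or an `aggregated_panel` object; `NULL` uses the built-in DPP-4 fixture.
#' @param policy Missing-criterion policy mode (see [missing_policy()]).
#' @param digits Decimal places for displayed values (>= 0).
#' @param seed Integer seed for the stability stage.
#' @param draws Monte-Carlo draws; 0 skips the stability stage.
#' @param out Optional output path for the JSON report.
#' @param verbose Print an INFO log of panel size, policy, included and
#'   excluded criteria, and the weight denominator.
#' @return A `run_config` object.
#' @export
run_config <- function(panel = NULL,
                       policy = "retain_weights",
                       digits = 2, seed = 1L, draws = 0L,
                       out = NULL, verbose = FALSE) {
  policy <- missing_policy(policy)  # errors on unknown mode before any work
  stopifnot(digits >= 0, draws >= 0)
  structure(
    list(panel = panel, policy = policy, digits = as.integer(digits),
         seed = as.integer(seed), draws = as.integer(draws),
         out = out, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Run the full appraisal pipeline
#'
#' Loads or accepts an aggregated panel, normalizes the weights, computes
#' every intervention's value estimate and contributions, ranks the
#' interventions, and (when `draws > 0`) runs the rank-stability simulation.
#' The report is assembled in full before anything is written, so a failing
#' stage leaves no partial output. Given the same configuration the report is
#' identical apart from its timestamp.
#'
#' @param config A [run_config()].
#' @return The report, an object of class `mcda_report` (a named list
#'   mirroring the JSON layout). Written to `config$out` when set.
#' @examples
#' rep <- run_pipeline(run_config())
#' rep$ranking
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }

  loaded <- stage("load", {
    if (is.null(config$panel)) {
      dpp4_panel()
    } else if (inherits(config$panel, "aggregated_panel")) {
      list(model = evidem_core_model(), panel = config$panel)
    } else {
      list(model = evidem_core_model(),
           panel = read_aggregated_panel(config$panel))
    }
  })
  panel <- loaded$panel
  model <- loaded$model

  est <- stage("valuation", compute_value(panel, config$policy, model))
  ranking <- stage("ranking", rank_interventions(est))
  stability <- if (config$draws > 0) {
    stage("stability",
          simulate_ranks(panel, n_draws = config$draws, seed = config$seed,
                         policy = config$policy, model = model))
  }

  if (config$verbose) {
    message("INFO n_panelists=", panel$n_panelists,
            " policy=", config$policy$mode,
            " seed=", config$seed,
            " denominator=", format(est$denominator),
            " included=", paste(est$weights$criterion_id, collapse = ","),
            " excluded=", paste(union(panel$unweighted, panel$unscored),
                                collapse = ","))
  }

  report <- list(
    meta = list(
      package = "evidemcda",
      policy = config$policy$mode,
      seed = config$seed,
      digits = config$digits,
      n_panelists = panel$n_panelists,
      weight_denominator = est$denominator,
      included_criteria = est$weights$criterion_id,
      unscored_criteria = panel$unscored,
      unweighted_criteria = panel$unweighted,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    aggregated = list(weights = panel$weights, scores = panel$scores),
    normalized_weights = est$weights[c("criterion_id", "weight_mean", "Wx")],
    contributions = est$contributions,
    values = dplyr::mutate(
      est$values, rounded = round_half_up(.data$total, config$digits)),
    ranking = ranking,
    stability = if (!is.null(stability)) list(
      n_draws = stability$n_draws,
      seed = stability$seed,
      rank_probability = stability$rank_probability,
      summary = stability$summary
    )
  )
  class(report) <- "mcda_report"

  if (!is.null(config$out)) {
    jsonlite::write_json(unclass(report), config$out, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  report
}

#' @export
print.mcda_report <- function(x, ...) {
  cat("<mcda_report> policy = ", x$meta$policy, ", ",
      x$meta$n_panelists, " panelists\n", sep = "")
  print(x$ranking)
  invisible(x)
}

#' Plot-ready contribution table
#'
#' Long-format table (intervention, criterion, `Vx`) of per-criterion value
#' contributions, restricted to criteria the committee actually scored; the
#' per-intervention sums equal each total `V` (unscored criteria contribute
#' exactly zero under every policy).
#'
#' @param estimates An `mcda_value` object.
#' @return A tibble `intervention`, `criterion_id`, `Vx`.
#' @export
contribution_chart_data <- function(estimates) {
  stopifnot(inherits(estimates, "mcda_value"), nrow(estimates$values) > 0)
  estimates$contributions |>
    dplyr::filter(!is.na(.data$score_mean)) |>
    dplyr::select("intervention", "criterion_id", "Vx")
}

#' Check a pipeline report against the shipped schema
#'
#' Validates the structural contract of [run_pipeline()] reports — required
#' fields and their JSON types — against the schema installed at
#' `inst/schema/report.schema.json`. A minimal structural checker, not a full
#' JSON-Schema implementation.
#'
#' @param report An `mcda_report`, or a path to a report JSON file.
#' @return `TRUE` invisibly; errors with the list of violations otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  schema <- jsonlite::read_json(
    system.file("schema", "report.schema.json", package = "evidemcda"),
    simplifyVector = FALSE
  )
  problems <- character()
  check <- function(node, sch, path) {
    type <- sch$type
    if (identical(type, "object")) {
      if (!is.list(node)) {
        problems <<- c(problems, paste0(path, ": expected object"))
        return()
      }
      for (req in sch$required %||% list()) {
        if (is.null(node[[req]])) {
          problems <<- c(problems, paste0(path, ": missing required field '", req, "'"))
        }
      }
      for (nm in names(sch$properties %||% list())) {
        if (!is.null(node[[nm]])) check(node[[nm]], sch$properties[[nm]],
                                        paste0(path, ".", nm))
      }
    } else if (identical(type, "array")) {
      ok <- is.list(node) || is.vector(node) || is.data.frame(node)
      if (!ok) problems <<- c(problems, paste0(path, ": expected array"))
    } else if (identical(type, "string")) {
      if (!is.character(unlist(node)))
        problems <<- c(problems, paste0(path, ": expected string"))
    } else if (identical(type, "number") || identical(type, "integer")) {
      if (!is.numeric(unlist(node)))
        problems <<- c(problems, paste0(path, ": expected number"))
    }
  }
  check(report, schema, "$")
  if (length(problems) > 0) {
    rlang::abort(c("report schema validation failed", problems))
  }
  invisible(TRUE)
}
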
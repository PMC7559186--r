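#' Derive hierarchy weights from the configured expert panel
#'
#' For every internal node with expert matrices: eigen-weights per expert,
#' consistency filtering at the configured CR threshold, weighted geometric
#' aggregation, then composition of global leaf weights down the tree.
#'
#' @param config a `project_config` whose `experts` block covers every
#'   internal node.
#' @return list: `global` (a `weight_vector` over the leaves), `local`
#'   (per-node aggregated `weight_vector`s), `panel` (per-node inclusion
#'   flags and CRs).
#' @export
derive_weights <- function(config) {
  hier <- config$hierarchy
  need <- names(hier$children)
  missing <- setdiff(need, names(config$experts))
  if (length(missing))
    stop("no expert matrices for internal node(s): ",
         paste(missing, collapse = ", "))
  local <- list(); panel <- list()
  for (nd in need) {
    evs <- lapply(config$experts[[nd]], eigen_weights)
    agg <- aggregate_experts(evs, cr_threshold = config$options$cr_threshold)
    local[[nd]] <- agg
    panel[[nd]] <- list(CR = vapply(evs, `[[`, numeric(1), "CR"),
                        included = attr(agg, "included"))
  }
  list(global = compose_global_weights(hier, local),
       local = local, panel = panel)
}

#' Run the full early-warning pipeline
#'
#' Chains every stage: expert weights, fuzzy scoring of detection records,
#' questionnaire risk values with reliability, per-leaf distribution fitting,
#' Latin hypercube simulation of the overall risk value, interval and
#' exceedance probabilities, sensitivity ranking, scenario analysis and
#' warning evaluation. Leaves listed in `options$detection_leaves` are fed
#' by the pooled fuzzy scores; every other leaf is fed by the questionnaire
#' risk values of the matching `factor_id`.
#'
#' @param config a `project_config`.
#' @param detections detection data.frame (`hazard_id`, `value`, ...).
#' @param survey questionnaire data.frame (`respondent_id`, `factor_id`,
#'   `p`, `E`).
#' @param seed overrides `options$simulate$seed` if given.
#' @param out_dir optional directory for the JSON report and per-stage CSVs.
#' @return a `risk_report` list; see the `summary` component for headline
#'   numbers.
#' @export
run_report <- function(config, detections, survey, seed = NULL,
                       out_dir = NULL) {
  opts <- config$options
  if (is.null(seed)) seed <- opts$simulate$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  wts <- stage("weights", derive_weights(config))
  leaf_ids <- wts$global$leaf_ids

  scores <- stage("score", score_series(detections, config$hazards))
  srv <- stage("survey",
               survey_risk_values(survey, scale = opts$questionnaire_scale_factor))

  det_leaves <- opts$detection_leaves
  samples_by_leaf <- lapply(stats::setNames(leaf_ids, leaf_ids), function(lf) {
    if (lf %in% det_leaves) scores$score
    else srv$values$rv[srv$values$factor_id == lf]
  })
  empty <- names(Filter(function(s) length(s) < 8, samples_by_leaf))
  if (length(empty))
    stop("stage 'fit' failed: no (or too little) data for leaf input(s): ",
         paste(empty, collapse = ", "))

  fits <- stage("fit", lapply(samples_by_leaf, function(s)
    rank_fits(s, families = opts$fit$families, n_bins = opts$fit$bins,
              alpha = opts$fit$alpha, min_expected = opts$fit$min_expected)))

  inputs <- lapply(leaf_ids, function(lf)
    input_spec(lf, fits[[lf]]$best,
               wts$global$weights[match(lf, leaf_ids)]))
  mat <- stage("simulate",
               lhs_sample(inputs, n = opts$simulate$n,
                          mode = opts$simulate$mode, seed = seed))
  sim <- aggregate_phi(mat, wts$global)

  intervals <- interval_probabilities(sim, opts$simulate$bins)
  warn <- evaluate_warning(sim, opts$simulate$thresholds)
  sens <- stage("sensitivity",
                correlation_sensitivity(mat, sim, method = opts$sensitivity$method))
  scen <- stage("scenario", tryCatch(
    scenario_analysis(mat, sim, opts$sensitivity$scenario_threshold,
                      opts$sensitivity$shift_cutoff),
    error = function(e) NULL))

  report <- structure(list(
    provenance = list(seed = seed, n_iter = opts$simulate$n,
                      config_hash = config_hash(config),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    weights = list(global = stats::setNames(wts$global$weights, leaf_ids),
                   panel = wts$panel),
    reliability = srv$reliability,
    screening = srv$screening,
    fits = lapply(fits, function(f)
      list(best = list(family = f$best$family,
                       params = as.list(f$best$params),
                       loglik = f$best$loglik),
           ranking = f$fits)),
    simulation = list(mean = sim$mean, sd = sim$sd, min = sim$min,
                      max = sim$max,
                      percentiles = as.list(sim$percentiles),
                      intervals = as.list(intervals)),
    warnings = warn,
    sensitivity = sens,
    scenario = if (is.null(scen)) NULL else
      list(threshold = scen$threshold,
           subset_probability = scen$subset_probability,
           flagged = scen$flagged, shifts = scen$shifts),
    summary = list(
      overall_mean = round(sim$mean, 4),
      warning_triggered = any(warn$triggered),
      top_driver = sens$input[1]),
    phi = sim$phi),
    class = "risk_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "phi")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    write.csv(data.frame(phi = sim$phi),
              file.path(out_dir, "phi_samples.csv"), row.names = FALSE)
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  }
  report
}

config_hash <- function(config) {
  raw <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE, digits = NA)
  # cheap stable fingerprint (no digest dependency): sum of char codes by position
  chars <- utf8ToInt(raw)
  sprintf("%08x", sum(chars * (seq_along(chars) %% 97 + 1)) %% .Machine$integer.max)
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> seed", x$provenance$seed, "N", x$provenance$n_iter, "\n")
  cat(sprintf("  overall risk: mean %.4f, min %.4f, max %.4f\n",
              x$simulation$mean, x$simulation$min, x$simulation$max))
  cat("  warning triggered:", x$summary$warning_triggered,
      "| top driver:", x$summary$top_driver, "\n")
  invisible(x)
}
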
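#' Specify one simulation input
#'
#' Pairs a leaf indicator with its (fitted or explicitly parameterized)
#' distribution and its global hierarchy weight.
#'
#' @param id leaf identifier.
#' @param dist a `fitted_distribution`, or a list
#'   `list(family = "...", params = c(...))`, or a single number (point mass).
#' @param weight global weight in \[0, 1\].
#' @return An `input_spec` with a `quantile` closure and, where available, an
#'   analytic `mean`.
#' @export
input_spec <- function(id, dist, weight) {
  stopifnot(is.numeric(weight), weight >= 0, weight <= 1)
  if (is.numeric(dist) && length(dist) == 1L) {
    point <- dist
    qf <- function(u) rep(point, length(u))
    mn <- point
  } else if (inherits(dist, "fitted_distribution")) {
    qf <- dist$quantile
    mn <- analytic_mean(dist$family, dist$params)
  } else if (is.list(dist) && !is.null(dist$family)) {
    fam <- distribution_families(dist$family)[[1]]
    p <- unname(as.numeric(dist$params))
    qf <- function(u) fam$quantile(u, p)
    mn <- analytic_mean(fam$name, p)
  } else stop("input '", id, "': distribution lacks a quantile evaluator")
  structure(list(id = as.character(id), quantile = qf, weight = weight,
                 mean = mn, dist = dist),
            class = "input_spec")
}

analytic_mean <- function(family, p) {
  p <- unname(as.numeric(p))
  switch(family,
    betageneral = p[3] + (p[4] - p[3]) * p[1] / (p[1] + p[2]),
    normal = p[1],
    lognormal = exp(p[1] + p[2]^2 / 2),
    gamma = p[1] / p[2],
    weibull = p[2] * gamma(1 + 1 / p[1]),
    triangular = mean(p),
    uniform = mean(p),
    NA_real_)
}

#' Latin hypercube (or plain Monte Carlo) sampling of the inputs
#'
#' For each input independently, the unit interval is cut into N
#' equiprobable strata; one uniform is drawn inside each stratum, the strata
#' are randomly permuted, and the stratified uniforms are pushed through the
#' input's quantile function. Inputs are sampled independently of one
#' another. Plain Monte Carlo (`mode = "plain_monte_carlo"`) skips the
#' stratification.
#'
#' @param inputs list of [input_spec()]s.
#' @param n number of iterations (rows).
#' @param mode `"latin_hypercube"` (default) or `"plain_monte_carlo"`.
#' @param seed optional integer; if given, seeds the RNG for a reproducible
#'   sample path.
#' @return N x n_inputs numeric matrix, columns named by input id.
#' @export
lhs_sample <- function(inputs, n, mode = c("latin_hypercube", "plain_monte_carlo"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- vapply(inputs, function(sp) {
    u <- if (mode == "latin_hypercube")
      (sample.int(n) - runif(n)) / n
    else runif(n)
    sp$quantile(u)
  }, numeric(n))
  m <- matrix(m, nrow = n)
  colnames(m) <- vapply(inputs, `[[`, character(1), "id")
  m
}

#' Aggregate sampled inputs into the overall risk value
#'
#' Computes the risk functional `Phi = sum_i w_i mu_i` row-wise over the
#' sample matrix and summarizes the resulting Phi sample.
#'
#' @param samples N x n matrix from [lhs_sample()].
#' @param weights numeric weights (or a `weight_vector`), one per column.
#' @param probs summary percentiles.
#' @return A `simulation_result`: `phi` (length-N vector), `mean`, `sd`,
#'   `min`, `max`, `percentiles`, `n_iter`, `weights`.
#' @export
aggregate_phi <- function(samples, weights,
                          probs = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)) {
  if (inherits(weights, "weight_vector")) weights <- weights$weights
  samples <- as.matrix(samples)
  if (ncol(samples) != length(weights))
    stop("weights length (", length(weights),
         ") does not match input count (", ncol(samples), ")")
  phi <- as.vector(samples %*% weights)
  structure(list(phi = phi, mean = mean(phi), sd = sd(phi),
                 min = min(phi), max = max(phi),
                 percentiles = quantile(phi, probs),
                 n_iter = length(phi), weights = weights),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> N = %d: mean %.4f, sd %.4f, min %.4f, max %.4f\n",
              x$n_iter, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Empirical interval probabilities of the overall risk value
#'
#' Fraction of Phi samples per bin under the `[lo, hi)` convention.
#'
#' @param result a `simulation_result` or a numeric Phi vector.
#' @param edges strictly increasing bin edges.
#' @return named numeric vector of per-bin probabilities.
#' @export
interval_probabilities <- function(result, edges) {
  phi <- if (inherits(result, "simulation_result")) result$phi else result
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  k <- length(edges) - 1L
  counts <- tabulate(findInterval(phi, edges, left.open = FALSE), k + 1L)[seq_len(k)]
  p <- counts / length(phi)
  names(p) <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  p
}

#' Evaluate warning thresholds against a simulation result
#'
#' For each threshold reports the exceedance probability `P(Phi > t)` and a
#' triggered flag. The default trigger fires when the exceedance probability
#' crosses `prob_cutoff`; `trigger_mode = "max"` instead compares the sampled
#' maximum to the threshold (the convention of comparing the simulated
#' extreme to the enterprise limit; less stable across N).
#'
#' @param result a `simulation_result`.
#' @param thresholds strictly increasing threshold(s) on the Phi scale,
#'   e.g. ideal value 40 and enterprise limit 70.
#' @param trigger_mode `"prob"` (default) or `"max"`.
#' @param prob_cutoff exceedance probability above which the `"prob"` trigger
#'   fires (default 0.001).
#' @return data.frame with `threshold`, `exceedance`, `triggered`.
#' @export
evaluate_warning <- function(result, thresholds, trigger_mode = c("prob", "max"),
                             prob_cutoff = 0.001) {
  trigger_mode <- match.arg(trigger_mode)
  if (any(diff(thresholds) <= 0) && length(thresholds) > 1)
    stop("thresholds must be strictly increasing")
  exc <- vapply(thresholds, function(t) mean(result$phi > t), numeric(1))
  trig <- if (trigger_mode == "prob") exc > prob_cutoff
          else result$max > thresholds
  data.frame(threshold = thresholds, exceedance = exc, triggered = trig)
}
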
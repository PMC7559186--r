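#' Round a comparison ratio to the Saaty nine-point scale
#'
#' Nearest admissible value in `{1/9..1/2, 1, 2..9}` in log space.
#'
#' @param r positive ratio(s).
#' @return Saaty-scale value(s).
#' @export
saaty_round <- function(r) {
  grid <- saaty_values()
  grid[vapply(r, function(ri) which.min(abs(log(ri) - log(grid))), integer(1))]
}

#' Generate a synthetic expert panel of judgment matrices
#'
#' Each expert's matrix starts from the perfectly consistent comparison
#' `a_ij = w_i / w_j` of a ground-truth weight vector, rounded to the Saaty
#' scale in log space, then perturbed by shifting each upper-triangle entry a
#' random number of Saaty steps in `[-perturb_steps, perturb_steps]`
#' (reciprocity preserved). With zero perturbation every expert passes the
#' consistency screen and aggregation recovers the truth up to Saaty
#' rounding error.
#'
#' @param truth strictly positive ground-truth weight vector.
#' @param n_experts panel size (default 25, a typical elicitation panel).
#' @param perturb_steps maximum Saaty-step perturbation (default 0).
#' @param node node id stamped on the matrices.
#' @param seed optional RNG seed.
#' @return list of [judgment_matrix()] objects.
#' @export
gen_expert_panel <- function(truth, n_experts = 25, perturb_steps = 0,
                             node = NA_character_, seed = NULL) {
  stopifnot(all(truth > 0), n_experts >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- saaty_values()
  n <- length(truth)
  lapply(seq_len(n_experts), function(e) {
    A <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- saaty_round(truth[i] / truth[j])
      if (perturb_steps > 0) {
        idx <- which(grid == v) +
          sample.int(2 * perturb_steps + 1, 1) - perturb_steps - 1L
        v <- grid[min(max(idx, 1L), length(grid))]
      }
      A[i, j] <- v
      A[j, i] <- 1 / v
    }
    judgment_matrix(A, node = node, expert = paste0("E", e))
  })
}

#' Generate synthetic hazard detection records
#'
#' Draws seeded measurement values per hazard from a stated contamination
#' law, by default a BetaGeneral over `[0, q5 + 0.2 * (q5 - q1)]` with shapes
#' (1.5, 4): contamination concentrated in the low bands with a thinning
#' tail into the higher ones, the pattern routine enterprise testing data
#' shows. The expected fuzzy score under any such law is available from
#' [expected_score()] for ground-truth checks.
#'
#' @param hazards named list of [hazard_definition()]s.
#' @param n_per_hazard records per hazard (default 100; roughly monthly
#'   testing over a three-year retention window across product lines).
#' @param dists optional named list overriding the contamination law per
#'   hazard: `list(family = , params = )` or a single number (point mass).
#' @param seed optional RNG seed.
#' @param start,end date range stamped on records.
#' @return data.frame with columns `hazard_id`, `value`, `unit`, `date`.
#' @export
gen_detections <- function(hazards, n_per_hazard = 100, dists = NULL,
                           seed = NULL, start = "2010-01-01", end = "2012-12-31") {
  if (!is.null(seed)) set.seed(seed)
  days <- seq(as.Date(start), as.Date(end), by = "day")
  out <- lapply(hazards, function(hz) {
    dspec <- dists[[hz$id]]
    if (is.null(dspec)) dspec <- default_contamination(hz)
    vals <- if (is.numeric(dspec) && length(dspec) == 1L) {
      rep(dspec, n_per_hazard)
    } else {
      fam <- distribution_families(dspec$family)[[1]]
      v <- fam$quantile(runif(n_per_hazard), unname(as.numeric(dspec$params)))
      if (any(v < 0))
        stop("hazard '", hz$id,
             "': contamination law produces negative concentrations")
      v
    }
    data.frame(hazard_id = hz$id, value = vals, unit = hz$unit,
               date = as.character(sample(days, n_per_hazard, replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

default_contamination <- function(hz) {
  q <- hz$cutoffs
  list(family = "betageneral",
       params = c(shape1 = 1.5, shape2 = 4, min = 0,
                  max = q[length(q)] + 0.2 * (q[length(q)] - q[1])))
}

#' Expected fuzzy risk score under a contamination law
#'
#' Numerically integrates `RV(x)` against the stated contamination density —
#' the ground truth that seeded [gen_detections()] + [score_series()] samples
#' should recover.
#'
#' @param dspec `list(family = , params = )` or a point mass.
#' @param hazard a [hazard_definition()].
#' @return the exact expected score.
#' @export
expected_score <- function(dspec, hazard) {
  if (is.numeric(dspec) && length(dspec) == 1L)
    return(risk_score(membership(dspec, hazard), hazard))
  fam <- distribution_families(dspec$family)[[1]]
  p <- unname(as.numeric(dspec$params))
  rv <- function(x) vapply(x, function(xi)
    risk_score(membership(xi, hazard), hazard), numeric(1))
  lo <- fam$quantile(1e-12, p); hi <- fam$quantile(1 - 1e-12, p)
  # integrate piecewise between the ladder kinks, where RV(x) is smooth;
  # saturated tails contribute T_1 / T_k times their probability mass
  q <- sort(hazard$cutoffs)
  Tvals <- hazard$T
  if (!hazard$higher_is_worse) Tvals <- rev(Tvals)
  total <- Tvals[1] * fam$cdf(q[1], p) +
    Tvals[length(Tvals)] * (1 - fam$cdf(q[length(q)], p))
  seg <- sort(unique(pmin(pmax(q, lo), hi)))
  for (i in seq_len(length(seg) - 1)) {
    if (seg[i + 1] > seg[i])
      total <- total + stats::integrate(
        function(x) rv(x) * fam$dens(x, p),
        lower = seg[i], upper = seg[i + 1],
        subdivisions = 200L, rel.tol = 1e-9)$value
  }
  total
}

#' Generate synthetic questionnaire responses
#'
#' One-factor latent model: respondent i's latent risk attitude `F_i` drives
#' every item through a common loading chosen so that Cronbach's alpha of
#' the generated items hits `target_alpha` in expectation. The latent
#' normals are mapped through the normal cdf onto the response scales
#' (p in \[0, 1\], E in \[0, 10\]); the latent correlation is pre-corrected
#' by `rho = 2 sin(pi r / 6)` so the post-transform correlation is exactly
#' the `r` the alpha target requires. A configured fraction of respondents
#' is made invalid (missing, out-of-range or straight-lined) to exercise the
#' screening rules.
#'
#' @param n_respondents questionnaires issued (default 500).
#' @param n_items risk factors rated (default 12, one per default leaf).
#' @param target_alpha Cronbach alpha target (default 0.834, a typical
#'   acceptable instrument).
#' @param invalid_fraction expected fraction of invalid questionnaires
#'   (default 0.048, i.e. ~476 valid out of 500).
#' @param item_shift optional per-item mean shift on the latent scale
#'   (length `n_items`), controlling which factors elicit higher risk.
#' @param seed optional RNG seed.
#' @return data.frame `respondent_id`, `factor_id`, `p`, `E`.
#' @export
gen_questionnaire <- function(n_respondents = 500, n_items = 12,
                              target_alpha = 0.834, invalid_fraction = 0.048,
                              item_shift = NULL, seed = NULL) {
  stopifnot(n_respondents >= 2, n_items >= 2,
            target_alpha >= 0, target_alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  K <- n_items
  r <- target_alpha / (K - target_alpha * (K - 1))
  if (r >= 1 || r < 0)
    stop("alpha target ", target_alpha, " infeasible for ", K,
         " items (max feasible < ", round(K / (K + 1) + 1e-4, 3), ")")
  rho <- 2 * sin(pi * r / 6)           # so corr(pnorm(z_i), pnorm(z_j)) = r
  l <- sqrt(rho)
  if (is.null(item_shift)) item_shift <- rep(0, K)
  stopifnot(length(item_shift) == K)
  draw <- function() {
    f <- rnorm(n_respondents)
    z <- outer(f, rep(l, K)) +
      matrix(rnorm(n_respondents * K), n_respondents) * sqrt(1 - l^2)
    sweep(z, 2, item_shift, "+")
  }
  p <- pnorm(draw())
  E <- 10 * pnorm(draw())
  factor_ids <- paste0("u", seq_len(K))
  d <- data.frame(
    respondent_id = rep(sprintf("R%03d", seq_len(n_respondents)), each = K),
    factor_id = rep(factor_ids, n_respondents),
    p = as.vector(t(p)), E = as.vector(t(E)),
    stringsAsFactors = FALSE)
  n_bad <- stats::rbinom(1, n_respondents, invalid_fraction)
  if (n_bad > 0) {
    bad <- sample(unique(d$respondent_id), n_bad)
    kind <- sample(c("missing", "range", "straight"), n_bad, replace = TRUE)
    for (i in seq_len(n_bad)) {
      rows <- d$respondent_id == bad[i]
      if (kind[i] == "missing") d$p[rows][1] <- NA
      else if (kind[i] == "range") d$p[rows][1] <- 1.5
      else { d$p[rows] <- 0.5; d$E[rows] <- 5 }
    }
  }
  d
}
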
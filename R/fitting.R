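#' Fit a distribution family to a risk-score sample by maximum likelihood
#'
#' Closed-form MLEs are used where they exist (normal, lognormal, uniform);
#' the remaining families are maximized numerically by Nelder-Mead from a
#' moment-matched start with restarts. The four-parameter BetaGeneral is
#' handled by profiling its support bounds over a grid of margins around the
#' sample range (bound MLEs are irregular), maximizing the two shapes inside
#' each candidate support, then polishing all four parameters jointly.
#'
#' @param sample numeric vector of risk scores.
#' @param family a family name (see [distribution_families()]) or descriptor.
#' @param bound_margins candidate support margins for bounded families, as
#'   fractions of the sample range.
#' @param restarts number of jittered optimizer restarts.
#' @return A `fitted_distribution`: list with `family`, `params` (named),
#'   `loglik`, `n`, plus `cdf`/`quantile`/`dens` closures.
#' @export
fit_mle <- function(sample, family,
                    bound_margins = c(0.001, 0.01, 0.05, 0.1, 0.25),
                    restarts = 3L) {
  x <- as.numeric(sample[is.finite(sample)])
  if (is.character(family)) family <- distribution_families(family)[[1]]
  if (length(x) < family$n_params + 1L)
    stop("sample too small to fit ", family$name, " (need > ",
         family$n_params, " observations)")
  if (diff(range(x)) == 0) stop("degenerate (constant) sample")
  n <- length(x)
  r <- diff(range(x))

  ll <- function(p) {
    d <- family$dens(x, p, log = TRUE)
    if (any(!is.finite(d))) -Inf else sum(d)
  }
  nm <- function(par, fn) {
    best <- NULL
    for (k in seq_len(restarts)) {
      # deterministic jitters: fitting must not consume the global RNG stream
      start <- if (k == 1) par
               else par * exp(0.1 * sin(k * seq_along(par) + k))
      o <- tryCatch(
        optim(start, fn, control = list(fnscale = -1, maxit = 2000,
                                        reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value > best$value)) best <- o
    }
    if (is.null(best) || !is.finite(best$value))
      stop("MLE optimization failed to converge for family ", family$name)
    best
  }

  params <- switch(family$name,
    normal = c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2))),
    lognormal = {
      if (any(x <= 0)) stop("lognormal requires positive sample values")
      c(meanlog = mean(log(x)), sdlog = sqrt(mean((log(x) - mean(log(x)))^2)))
    },
    uniform = c(min = min(x), max = max(x)),
    gamma = {
      if (any(x <= 0)) stop("gamma requires positive sample values")
      s0 <- mean(x)^2 / var(x)
      o <- nm(log(c(s0, s0 / mean(x))), function(t) ll(exp(t)))
      stats::setNames(exp(o$par), c("shape", "rate"))
    },
    weibull = {
      if (any(x <= 0)) stop("weibull requires positive sample values")
      o <- nm(log(c(1.2, mean(x))), function(t) ll(exp(t)))
      stats::setNames(exp(o$par), c("shape", "scale"))
    },
    triangular = {
      # bounds must lie strictly outside the data; profile small margins
      best <- NULL
      for (eps in bound_margins) {
        lo <- min(x) - eps * r; hi <- max(x) + eps * r
        om <- stats::optimize(function(m) ll(c(lo, m, hi)),
                              lower = lo, upper = hi, maximum = TRUE)
        if (is.null(best) || om$objective > best$val)
          best <- list(val = om$objective, p = c(min = lo, mode = om$maximum, max = hi))
      }
      best$p
    },
    betageneral = fit_betageneral(x, ll, nm, bound_margins, r),
    stop("no fitting rule for family ", family$name))

  structure(list(family = family$name, params = params,
                 loglik = ll(unname(params)), n = n,
                 n_params = family$n_params,
                 dens = function(z, log = FALSE) family$dens(z, unname(params), log = log),
                 cdf = function(q) family$cdf(q, unname(params)),
                 quantile = function(u) family$quantile(u, unname(params))),
            class = "fitted_distribution")
}

# Profile the support bounds on a margin grid (fractions of the sample
# range), optimize shapes inside each candidate support from a
# moment-matched start, then polish all four parameters jointly with the
# margins box-constrained to [1e-4, max_margin] sample ranges. The cap is a
# deliberate regularization: the joint likelihood is unbounded along the
# shape2/max ridge where the rescaled beta degenerates to a gamma, so the
# support is restricted to a neighbourhood of the data.
fit_betageneral <- function(x, ll, nm, bound_margins, r, max_margin = 2) {
  grid <- sort(unique(c(bound_margins, 0.5, 1, 1.5, max_margin)))
  grid <- grid[grid <= max_margin]
  shape_start <- function(lo, hi) {
    z <- (x - lo) / (hi - lo)
    m <- mean(z); v <- var(z)
    v <- min(v, m * (1 - m) * 0.99)
    k <- m * (1 - m) / v - 1
    pmax(c(m * k, (1 - m) * k), 0.05)
  }
  best <- NULL
  for (el in grid) for (eu in grid) {
    lo <- min(x) - el * r; hi <- max(x) + eu * r
    o <- tryCatch(
      optim(log(shape_start(lo, hi)),
            function(t) ll(c(exp(t), lo, hi)),
            control = list(fnscale = -1, maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value > best$value))
      best <- list(value = o$value, shapes = exp(o$par), el = el, eu = eu)
  }
  if (is.null(best)) stop("BetaGeneral profile fit failed")
  par <- c(log(best$shapes),
           log(max(best$el, 1e-4)), log(max(best$eu, 1e-4)))
  o <- tryCatch(
    optim(par,
          function(t) ll(c(exp(t[1]), exp(t[2]),
                           min(x) - exp(t[3]) * r, max(x) + exp(t[4]) * r)),
          method = "L-BFGS-B",
          lower = c(-10, -10, log(1e-4), log(1e-4)),
          upper = c(10, 10, log(max_margin), log(max_margin)),
          control = list(fnscale = -1, maxit = 500)),
    error = function(e) NULL)
  p <- if (!is.null(o) && is.finite(o$value) && o$value >= best$value)
    c(exp(o$par[1]), exp(o$par[2]),
      min(x) - exp(o$par[3]) * r, max(x) + exp(o$par[4]) * r)
  else c(best$shapes, min(x) - best$el * r, max(x) + best$eu * r)
  stats::setNames(p, c("shape1", "shape2", "min", "max"))
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat("<fitted_distribution>", x$family, "(",
      paste(sprintf("%s = %.4f", names(x$params), x$params), collapse = ", "),
      ")\n  logLik =", format(x$loglik, digits = 6), " n =", x$n, "\n")
  invisible(x)
}

#' Chi-square goodness of fit with equal-probability binning
#'
#' Bins are equiprobable under the fitted model (edges at model quantiles),
#' so every bin has expected count `n / n_bins`. The statistic is
#' `sum((O - E)^2 / E)` with `df = n_bins - 1 - n_params`; the default 33
#' bins give df = 28 for the four-parameter BetaGeneral.
#'
#' @param sample numeric sample.
#' @param fitted a `fitted_distribution`.
#' @param n_bins number of equal-probability bins (default 33).
#' @param alpha significance level for the critical value (default 0.05).
#' @param min_expected minimum expected count per bin (default 5); violated
#'   -> error suggesting a feasible bin count.
#' @return A `goodness_of_fit`: list with `chi2_stat`, `df`,
#'   `critical_value`, `p_value`, `edges`, `observed`, `expected`, `alpha`.
#' @export
chi_square_gof <- function(sample, fitted, n_bins = 33, alpha = 0.05,
                           min_expected = 5) {
  x <- as.numeric(sample[is.finite(sample)])
  n <- length(x)
  if (n / n_bins < min_expected)
    stop("expected count per bin ", round(n / n_bins, 2), " below floor ",
         min_expected, "; use at most ", floor(n / min_expected), " bins")
  df <- n_bins - 1L - fitted$n_params
  if (df < 1) stop("n_bins too small: df = ", df, " < 1")
  edges <- fitted$quantile(seq(0, 1, length.out = n_bins + 1))
  edges[1] <- -Inf; edges[n_bins + 1] <- Inf
  observed <- tabulate(findInterval(x, edges, left.open = FALSE), n_bins)
  expected <- rep(n / n_bins, n_bins)
  stat <- sum((observed - expected)^2 / expected)
  structure(list(chi2_stat = stat, df = df, alpha = alpha,
                 critical_value = qchisq(1 - alpha, df),
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 edges = edges, observed = observed, expected = expected),
            class = "goodness_of_fit")
}

#' @export
print.goodness_of_fit <- function(x, ...) {
  cat(sprintf("<goodness_of_fit> chi2 = %.4f, df = %d, critical(%.2f) = %.4f, p = %.4f\n",
              x$chi2_stat, x$df, 1 - x$alpha, x$critical_value, x$p_value))
  invisible(x)
}

#' Fit and rank candidate families
#'
#' Fits each family by [fit_mle()], tests each with [chi_square_gof()] (bin
#' count reduced automatically if the sample is small), and orders by the
#' chi-square statistic ascending, breaking ties by AIC. Families that fail
#' to fit (e.g. support mismatch) are dropped with their error recorded.
#'
#' @param sample numeric sample.
#' @param families character vector of family names; default all seven.
#' @param n_bins,alpha,min_expected passed to [chi_square_gof()].
#' @return list: `fits` (data.frame ranking), `best` (the winning
#'   `fitted_distribution`), `details` (per-family fit + gof), `errors`.
#' @export
rank_fits <- function(sample, families = names(distribution_families()),
                      n_bins = 33, alpha = 0.05, min_expected = 5) {
  x <- as.numeric(sample[is.finite(sample)])
  nb <- min(n_bins, max(6L, floor(length(x) / min_expected)))
  details <- list(); errors <- list()
  for (f in families) {
    res <- tryCatch({
      fit <- fit_mle(x, f)
      nbf <- max(fit$n_params + 2L, nb)
      if (length(x) / nbf < min_expected) nbf <- nb
      gof <- chi_square_gof(x, fit, n_bins = nbf, alpha = alpha,
                            min_expected = min(min_expected, length(x) / nbf))
      list(fit = fit, gof = gof)
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[f]] <- conditionMessage(res)
    else details[[f]] <- res
  }
  if (!length(details))
    stop("all candidate fits failed: ",
         paste(sprintf("%s: %s", names(errors), unlist(errors)), collapse = "; "))
  tab <- do.call(rbind, lapply(names(details), function(f) {
    d <- details[[f]]
    data.frame(family = f, chi2 = d$gof$chi2_stat, df = d$gof$df,
               p_value = d$gof$p_value,
               aic = 2 * d$fit$n_params - 2 * d$fit$loglik,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$chi2, tab$aic), ]
  rownames(tab) <- NULL
  list(fits = tab, best = details[[tab$family[1]]]$fit,
       details = details, errors = errors)
}

#' P-P and Q-Q diagnostic points
#'
#' P-P pairs plot the model cdf at the order statistics against the plotting
#' positions `(i - 0.5)/n`; Q-Q pairs plot the model quantiles at those
#' positions against the order statistics. A good fit puts both sequences
#' near the identity line.
#'
#' @param sample numeric sample.
#' @param fitted a `fitted_distribution`.
#' @return list of two data.frames, `pp` (`theoretical`, `empirical`) and
#'   `qq` (`theoretical`, `empirical`).
#' @export
diagnostics <- function(sample, fitted) {
  x <- sort(as.numeric(sample[is.finite(sample)]))
  if (!length(x)) stop("empty sample")
  pos <- (seq_along(x) - 0.5) / length(x)
  list(pp = data.frame(theoretical = fitted$cdf(x), empirical = pos),
       qq = data.frame(theoretical = fitted$quantile(pos), empirical = x))
}
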
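#' The BetaGeneral distribution
#'
#' A beta distribution rescaled to an arbitrary support, parameterized
#' `(shape1, shape2, min, max)` with density proportional to
#' `(x - min)^(shape1 - 1) * (max - x)^(shape2 - 1)` on `[min, max]`.
#'
#' @param x,q quantile vector.
#' @param p probability vector.
#' @param n number of draws.
#' @param shape1,shape2 positive shape parameters.
#' @param min,max support bounds, `min < max`.
#' @param log,log.p,lower.tail as in the base distribution functions.
#' @return `dbetagen` density, `pbetagen` cdf, `qbetagen` quantile,
#'   `rbetagen` random draws.
#' @examples
#' pbetagen(40, 3.5954, 23.116, 6.3774, 126.35, lower.tail = FALSE)
#' @name betageneral
NULL

check_bg <- function(shape1, shape2, min, max) {
  if (any(shape1 <= 0) || any(shape2 <= 0))
    stop("BetaGeneral shapes must be positive")
  if (any(min >= max)) stop("BetaGeneral requires min < max")
}

#' @rdname betageneral
#' @export
dbetagen <- function(x, shape1, shape2, min = 0, max = 1, log = FALSE) {
  check_bg(shape1, shape2, min, max)
  d <- dbeta((x - min) / (max - min), shape1, shape2, log = TRUE) - log(max - min)
  if (log) d else exp(d)
}

#' @rdname betageneral
#' @export
pbetagen <- function(q, shape1, shape2, min = 0, max = 1,
                     lower.tail = TRUE, log.p = FALSE) {
  check_bg(shape1, shape2, min, max)
  pbeta((q - min) / (max - min), shape1, shape2,
        lower.tail = lower.tail, log.p = log.p)
}

#' @rdname betageneral
#' @export
qbetagen <- function(p, shape1, shape2, min = 0, max = 1,
                     lower.tail = TRUE, log.p = FALSE) {
  check_bg(shape1, shape2, min, max)
  min + (max - min) * qbeta(p, shape1, shape2,
                            lower.tail = lower.tail, log.p = log.p)
}

#' @rdname betageneral
#' @export
rbetagen <- function(n, shape1, shape2, min = 0, max = 1) {
  check_bg(shape1, shape2, min, max)
  min + (max - min) * rbeta(n, shape1, shape2)
}

#' Moments and evaluators of a BetaGeneral distribution
#'
#' @param shape1,shape2,min,max BetaGeneral parameters.
#' @return list with analytic `mean` and `variance` plus vectorized `cdf` and
#'   `quantile` functions.
#' @examples
#' s <- betageneral_stats(3.5954, 23.116, 6.3774, 126.35)
#' s$mean         # 22.526
#' s$cdf(10)      # P(X < 10)
#' @export
betageneral_stats <- function(shape1, shape2, min, max) {
  check_bg(shape1, shape2, min, max)
  s <- shape1 + shape2
  list(mean = min + (max - min) * shape1 / s,
       variance = (max - min)^2 * shape1 * shape2 / (s^2 * (s + 1)),
       cdf = function(x) pbetagen(x, shape1, shape2, min, max),
       quantile = function(p) qbetagen(p, shape1, shape2, min, max))
}

# Density for the triangular distribution (min, mode, max)
dtriang <- function(x, min, mode, max, log = FALSE) {
  d <- ifelse(x < min | x > max, 0,
        ifelse(x < mode, 2 * (x - min) / ((max - min) * (mode - min)),
          ifelse(x > mode, 2 * (max - x) / ((max - min) * (max - mode)),
                 2 / (max - min))))
  if (log) base::log(d) else d
}

ptriang <- function(q, min, mode, max) {
  ifelse(q <= min, 0,
    ifelse(q >= max, 1,
      ifelse(q <= mode, (q - min)^2 / ((max - min) * (mode - min)),
             1 - (max - q)^2 / ((max - min) * (max - mode)))))
}

qtriang <- function(p, min, mode, max) {
  pc <- (mode - min) / (max - min)
  ifelse(p <= pc, min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' Candidate distribution families
#'
#' The default battery of parametric families fitted to risk-score samples:
#' BetaGeneral, Normal, Lognormal, Gamma, Weibull, Triangular and Uniform.
#' Each family bundles its density, cdf and quantile functions, parameter
#' count, and a moment-matched starting point for the optimizer.
#'
#' @param names character vector selecting a subset (case-insensitive);
#'   default all seven.
#' @return named list of family descriptors.
#' @export
distribution_families <- function(names = NULL) {
  fam <- list(
    betageneral = list(
      name = "betageneral", n_params = 4L,
      par_names = c("shape1", "shape2", "min", "max"),
      dens = function(x, p, log = FALSE) dbetagen(x, p[1], p[2], p[3], p[4], log = log),
      cdf = function(q, p) pbetagen(q, p[1], p[2], p[3], p[4]),
      quantile = function(u, p) qbetagen(u, p[1], p[2], p[3], p[4])),
    normal = list(
      name = "normal", n_params = 2L, par_names = c("mean", "sd"),
      dens = function(x, p, log = FALSE) dnorm(x, p[1], p[2], log = log),
      cdf = function(q, p) pnorm(q, p[1], p[2]),
      quantile = function(u, p) qnorm(u, p[1], p[2])),
    lognormal = list(
      name = "lognormal", n_params = 2L, par_names = c("meanlog", "sdlog"),
      dens = function(x, p, log = FALSE) dlnorm(x, p[1], p[2], log = log),
      cdf = function(q, p) plnorm(q, p[1], p[2]),
      quantile = function(u, p) qlnorm(u, p[1], p[2])),
    gamma = list(
      name = "gamma", n_params = 2L, par_names = c("shape", "rate"),
      dens = function(x, p, log = FALSE) dgamma(x, p[1], p[2], log = log),
      cdf = function(q, p) pgamma(q, p[1], p[2]),
      quantile = function(u, p) qgamma(u, p[1], p[2])),
    weibull = list(
      name = "weibull", n_params = 2L, par_names = c("shape", "scale"),
      dens = function(x, p, log = FALSE) dweibull(x, p[1], p[2], log = log),
      cdf = function(q, p) pweibull(q, p[1], p[2]),
      quantile = function(u, p) qweibull(u, p[1], p[2])),
    triangular = list(
      name = "triangular", n_params = 3L, par_names = c("min", "mode", "max"),
      dens = function(x, p, log = FALSE) dtriang(x, p[1], p[2], p[3], log = log),
      cdf = function(q, p) ptriang(q, p[1], p[2], p[3]),
      quantile = function(u, p) qtriang(u, p[1], p[2], p[3])),
    uniform = list(
      name = "uniform", n_params = 2L, par_names = c("min", "max"),
      dens = function(x, p, log = FALSE) dunif(x, p[1], p[2], log = log),
      cdf = function(q, p) punif(q, p[1], p[2]),
      quantile = function(u, p) qunif(u, p[1], p[2]))
  )
  if (is.null(names)) return(fam)
  names <- tolower(names)
  unknown <- setdiff(names, base::names(fam))
  if (length(unknown))
    stop("unknown distribution family: ", paste(unknown, collapse = ", "))
  fam[names]
}
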
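#' Published case-study fixtures
#'
#' Reference values from the meat-processing enterprise case study that
#' motivated this engine, kept for documentation and invariant checks:
#'
#' * `casestudy_global_weights`: the 18-element composed global weight vector of
#'   the expert panel (the mapping of its components to named indicators was
#'   not published; only its sum-to-one invariant is usable).
#' * `casestudy_betageneral`: the fitted overall-risk distribution,
#'   BetaGeneral(shape1 = 3.5954, shape2 = 23.116, min = 6.3774,
#'   max = 126.35), together with the reported chi-square record
#'   (statistic 20.3360, critical value 41.3371 at the 0.05 level, p 0.8519).
#'
#' The case study's raw inputs (detection records, questionnaires, expert
#' matrices) were not published, so these are opaque outputs, not
#' reproducible targets.
#'
#' @return `casestudy_global_weights()` a numeric vector of length 18;
#'   `casestudy_betageneral()` a list with `params` and `gof`.
#' @export
casestudy_global_weights <- function() {
  c(0.137455964, 0.108826553, 0.040800586, 0.117854333, 0.024376977,
    0.023713985, 0.01271776, 0.014183814, 0.010006234, 0.009234366,
    0.020952994, 0.017363897, 0.004244048, 0.034688485, 0.139479073,
    0.214638755, 0.032430207, 0.037031968)
}

#' @rdname casestudy_global_weights
#' @export
casestudy_betageneral <- function() {
  list(params = c(shape1 = 3.5954, shape2 = 23.116,
                  min = 6.3774, max = 126.35),
       gof = list(chi2_stat = 20.3360, critical_value = 41.3371,
                  alpha = 0.05, p_value = 0.8519),
       reported = list(mean = 22.5257, min = 7.2260, max = 56.0929,
                       enterprise_threshold = 70, ideal_value = 40))
}
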
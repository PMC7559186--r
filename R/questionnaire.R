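#' Risk value of a probability-impact elicitation
#'
#' A respondent rates each risk factor by its probability of occurring
#' (`p` in \[0, 1\]) and its impact on food quality if it occurs
#' (`E` in \[0, 10\]). The raw product `p * E` lives on \[0, 10\]; it is
#' multiplied by `scale` (default 10) to place questionnaire risk values on
#' the same 0-100 scale as the fuzzy detection scores before fitting and
#' aggregation.
#'
#' @param p probability in \[0, 1\]; vectorized.
#' @param E impact in \[0, 10\]; vectorized.
#' @param scale common-scale factor (the `questionnaire_scale_factor` config
#'   option; default 10).
#' @param respondent optional ids used in error messages.
#' @return numeric risk values in \[0, 100\] under the default scale.
#' @export
risk_value <- function(p, E, scale = 10, respondent = NULL) {
  bad <- !is.finite(p) | p < 0 | p > 1 | !is.finite(E) | E < 0 | E > 10
  if (any(bad)) {
    who <- if (!is.null(respondent)) paste(unique(respondent[bad]), collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("out-of-range p or E for respondent(s)/row(s): ", who)
  }
  p * E * scale
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = K/(K-1) * (1 - sum(item variances)/variance(total score))` with
#' unbiased sample variances, computed over a respondents x items score
#' matrix.
#'
#' @param m numeric matrix or data.frame, rows = respondents, columns = items;
#'   at least 2 of each. Rows with any missing value are dropped.
#' @return list with `alpha`, `n_items`, `n_respondents`.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  K <- ncol(m)
  if (K < 2 || nrow(m) < 2)
    stop("Cronbach's alpha needs at least 2 items and 2 complete respondents")
  tot_var <- var(rowSums(m))
  if (tot_var <= 0)
    stop("total score is constant; alpha undefined")
  alpha <- K / (K - 1) * (1 - sum(apply(m, 2, var)) / tot_var)
  list(alpha = alpha, n_items = K, n_respondents = nrow(m))
}

#' Valid-questionnaire rate
#'
#' @param issued number of questionnaires issued (> 0).
#' @param valid number collected as valid (0 <= valid <= issued).
#' @return list with `fraction` and `percent` (percent rounded to one
#'   decimal, the conventional reporting precision).
#' @examples
#' valid_rate(500, 476)$percent  # 95.2
#' @export
valid_rate <- function(issued, valid) {
  if (issued <= 0) stop("issued must be positive")
  if (valid < 0 || valid > issued) stop("valid must lie in [0, issued]")
  f <- valid / issued
  list(fraction = f, percent = round(100 * f, 1))
}

#' Screen questionnaire responses for validity
#'
#' Flags respondents as invalid by three toggleable rules: missing fields,
#' out-of-range values (p outside \[0, 1\] or E outside \[0, 10\]), and
#' straight-lining (identical answers across every item on both scales,
#' which signals a careless respondent).
#'
#' @param responses long data.frame with columns `respondent_id`, `factor_id`,
#'   `p`, `E`.
#' @param drop_missing,drop_out_of_range,drop_straightline rule toggles.
#' @return list: `valid` (cleaned data.frame), `invalid_ids`, `report`
#'   (per-rule counts plus the [valid_rate()]).
#' @export
screen_responses <- function(responses, drop_missing = TRUE,
                             drop_out_of_range = TRUE,
                             drop_straightline = TRUE) {
  stopifnot(all(c("respondent_id", "factor_id", "p", "E") %in% names(responses)))
  if (nrow(responses) == 0L) stop("no questionnaire responses to screen")
  by_resp <- split(responses, responses$respondent_id)
  n_items <- max(vapply(by_resp, nrow, integer(1)))
  rule <- function(f) names(Filter(isTRUE, lapply(by_resp, f)))
  missing_ids <- if (drop_missing)
    rule(function(d) anyNA(d[c("p", "E")]) || nrow(d) < n_items) else character(0)
  range_ids <- if (drop_out_of_range)
    rule(function(d) any(stats::na.omit(d$p < 0 | d$p > 1 | d$E < 0 | d$E > 10)))
    else character(0)
  straight_ids <- if (drop_straightline)
    rule(function(d) nrow(d) >= 3 &&
           length(unique(stats::na.omit(d$p))) == 1L &&
           length(unique(stats::na.omit(d$E))) == 1L)
    else character(0)
  invalid <- unique(c(missing_ids, range_ids, straight_ids))
  issued <- length(by_resp)
  rep <- list(n_missing = length(missing_ids),
              n_out_of_range = length(range_ids),
              n_straightline = length(straight_ids),
              rate = valid_rate(issued, issued - length(invalid)))
  list(valid = responses[!(responses$respondent_id %in% invalid), ],
       invalid_ids = invalid, report = rep)
}

#' Questionnaire risk values with a reliability report
#'
#' Screens responses, computes RV = p x E (rescaled to the common 0-100
#' scale) per response, and reports Cronbach's alpha over the p items, the E
#' items and the RV items separately (the instrument does not say which of
#' the three a single published alpha refers to, so all are labelled).
#'
#' @param responses long data.frame as in [screen_responses()].
#' @param scale common-scale factor passed to [risk_value()].
#' @param screen logical; apply validity screening first (default TRUE).
#' @return list: `values` (data.frame with `rv` column), `reliability`
#'   (alphas for p/E/rv matrices), `screening` report.
#' @export
survey_risk_values <- function(responses, scale = 10, screen = TRUE) {
  scr <- if (screen) screen_responses(responses)
         else list(valid = responses, invalid_ids = character(0), report = NULL)
  d <- scr$valid
  d$rv <- risk_value(d$p, d$E, scale = scale, respondent = d$respondent_id)
  wide <- function(col) {
    m <- tapply(d[[col]], list(d$respondent_id, d$factor_id), mean)
    m[stats::complete.cases(m), , drop = FALSE]
  }
  rel <- lapply(c(p = "p", E = "E", rv = "rv"), function(col) {
    w <- wide(col)
    if (ncol(w) >= 2 && nrow(w) >= 2 && var(rowSums(w)) > 0)
      cronbach_alpha(w)$alpha else NA_real_
  })
  list(values = d, reliability = rel, screening = scr$report)
}
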
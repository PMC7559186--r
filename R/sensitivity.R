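#' Correlation (tornado) sensitivity of the overall risk to each input
#'
#' Ranks simulation inputs by the absolute correlation of their sampled
#' values with the overall risk value Phi. The default is Spearman rank
#' correlation (robust to monotone transformations of the inputs); Pearson
#' is available for a linear reading. Constant inputs get coefficient 0 with
#' a warning.
#'
#' @param samples N x n input matrix (columns named by input id).
#' @param phi numeric Phi vector (or a `simulation_result`).
#' @param method `"rank"` (Spearman, default) or `"linear"` (Pearson).
#' @return A `sensitivity_report` data.frame with `input`, `coefficient`,
#'   `rank`, sorted by `abs(coefficient)` descending; `method` attribute.
#' @export
correlation_sensitivity <- function(samples, phi, method = c("rank", "linear")) {
  method <- match.arg(method)
  if (inherits(phi, "simulation_result")) phi <- phi$phi
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(phi))
  if (sd(phi) == 0) stop("Phi is constant; sensitivity undefined")
  cm <- if (method == "rank") "spearman" else "pearson"
  coefs <- apply(samples, 2, function(col) {
    if (sd(col) == 0) {
      warning("constant input column; coefficient reported as 0")
      return(0)
    }
    cor(col, phi, method = cm)
  })
  ids <- colnames(samples)
  if (is.null(ids)) ids <- paste0("input", seq_along(coefs))
  ord <- order(abs(coefs), decreasing = TRUE)
  out <- data.frame(input = ids[ord], coefficient = unname(coefs[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Scenario analysis: drivers of high-risk outcomes
#'
#' Conditions on the high-risk subset `Phi >= threshold` and flags the
#' inputs whose conditional median shifts from their unconditional median by
#' more than `shift_cutoff` unconditional standard deviations — the inputs
#' that must be controlled to keep the overall risk below the target.
#'
#' @param samples N x n input matrix.
#' @param phi numeric Phi vector (or a `simulation_result`).
#' @param threshold scenario condition on the Phi scale (e.g. ideal value 40).
#' @param shift_cutoff flagging cut-off in SD units (default 0.5).
#' @return A `scenario_report`: list with `threshold`, `subset_probability`,
#'   `subset_size`, `shifts` (data.frame: `input`, `shift_sd`, `flagged`),
#'   `flagged` (character).
#' @export
scenario_analysis <- function(samples, phi, threshold, shift_cutoff = 0.5) {
  if (inherits(phi, "simulation_result")) phi <- phi$phi
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(phi))
  sel <- phi >= threshold
  if (!any(sel))
    stop("no sample with Phi >= ", threshold,
         "; lower the threshold or increase the iteration count")
  shifts <- apply(samples, 2, function(col) {
    s <- sd(col)
    if (s == 0) return(0)
    (median(col[sel]) - median(col)) / s
  })
  ids <- colnames(samples)
  if (is.null(ids)) ids <- paste0("input", seq_along(shifts))
  ord <- order(abs(shifts), decreasing = TRUE)
  tab <- data.frame(input = ids[ord], shift_sd = unname(shifts[ord]),
                    flagged = abs(unname(shifts[ord])) > shift_cutoff,
                    stringsAsFactors = FALSE)
  structure(list(threshold = threshold,
                 subset_probability = mean(sel),
                 subset_size = sum(sel),
                 shift_cutoff = shift_cutoff,
                 shifts = tab,
                 flagged = tab$input[tab$flagged]),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> Phi >= %g: probability %.4f (%d samples)\n",
              x$threshold, x$subset_probability, x$subset_size))
  cat("flagged drivers:", if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
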
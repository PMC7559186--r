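#' Define a hazard's five-level warning ladder
#'
#' Each hazard (e.g. nitrite, lead, colony count) carries five strictly
#' increasing anchor cut-offs `q1 < ... < q5` in its own measurement unit,
#' one per risk level (low, medium-low, medium, medium-high, high), and the
#' dimensionless risk-level weights `T` (default 10, 30, 50, 70, 90) that
#' place all hazards on a common scale.
#'
#' @param id hazard identifier.
#' @param cutoffs numeric, strictly increasing, one per level.
#' @param T risk-level weights, strictly increasing, same length as `cutoffs`.
#' @param unit measurement unit string (informational).
#' @param higher_is_worse direction flag; if `FALSE` the measurement axis is
#'   reversed before scoring (rare; e.g. a depletion-type indicator).
#' @return A `hazard_definition` object.
#' @export
hazard_definition <- function(id, cutoffs, T = c(10, 30, 50, 70, 90),
                              unit = "", higher_is_worse = TRUE) {
  cutoffs <- as.numeric(cutoffs)
  T <- as.numeric(T)
  if (any(diff(cutoffs) <= 0))
    stop("hazard '", id, "': cutoffs must be strictly increasing")
  if (length(T) != length(cutoffs) || any(diff(T) <= 0))
    stop("hazard '", id, "': T must be strictly increasing and match the cutoffs in length")
  structure(list(id = as.character(id), cutoffs = cutoffs, T = T,
                 unit = unit, higher_is_worse = isTRUE(higher_is_worse)),
            class = "hazard_definition")
}

#' Fuzzy five-level membership of a measurement
#'
#' Triangular partition-of-unity memberships on the hazard's anchor ladder:
#' full membership in the lowest level at or below `q1`, full membership in
#' the highest at or above `q5`, and for `q_j < x < q_{j+1}` linear
#' interpolation `h_j = (q_{j+1} - x)/(q_{j+1} - q_j)`, `h_{j+1} = 1 - h_j`.
#' At most two adjacent components are nonzero and the memberships always sum
#' to one.
#'
#' @param x measured value(s); vectorized.
#' @param hazard a [hazard_definition()].
#' @return a numeric matrix, one row per value, columns `h1..h5` (or however
#'   many levels the ladder has); a single value yields a plain vector.
#' @examples
#' hz <- hazard_definition("nitrite", c(1, 2, 3, 4, 5))
#' membership(2.5, hz)  # (0, .5, .5, 0, 0)
#' @export
membership <- function(x, hazard) {
  stopifnot(inherits(hazard, "hazard_definition"))
  q <- hazard$cutoffs
  if (!hazard$higher_is_worse) {
    x <- -x
    q <- rev(-q)
  }
  k <- length(q)
  one <- function(xi) {
    h <- numeric(k)
    if (!is.finite(xi)) return(rep(NA_real_, k))
    if (xi <= q[1]) h[1] <- 1
    else if (xi >= q[k]) h[k] <- 1
    else {
      j <- findInterval(xi, q)      # q[j] <= xi < q[j+1]
      h[j] <- (q[j + 1] - xi) / (q[j + 1] - q[j])
      h[j + 1] <- 1 - h[j]
    }
    h
  }
  out <- t(vapply(x, one, numeric(k)))
  colnames(out) <- paste0("h", seq_len(k))
  if (length(x) == 1L) out[1, ] else out
}

#' Risk score of a membership vector
#'
#' `RV = sum_j h_j T_j`: the membership-weighted average of the risk-level
#' weights, a dimensionless score in `[T_1, T_k]` (10..90 by default).
#'
#' @param h membership vector or matrix (rows summing to 1).
#' @param hazard a [hazard_definition()] supplying `T`.
#' @return numeric score(s).
#' @export
risk_score <- function(h, hazard) {
  stopifnot(inherits(hazard, "hazard_definition"))
  h <- rbind(h)
  if (ncol(h) != length(hazard$T))
    stop("membership length does not match the hazard's level count")
  if (any(abs(rowSums(h) - 1) > 1e-9))
    stop("membership rows must sum to 1")
  as.vector(h %*% hazard$T)
}

#' Score a table of detection records
#'
#' Converts raw detection measurements to dimensionless fuzzy risk scores,
#' grouped by hazard, ready for distribution fitting.
#'
#' @param records data.frame with columns `hazard_id` and `value` (extra
#'   columns are carried through).
#' @param hazards a named list of [hazard_definition()]s (the hazard catalog).
#' @return the input data.frame with an added `score` column.
#' @export
score_series <- function(records, hazards) {
  stopifnot(is.data.frame(records),
            all(c("hazard_id", "value") %in% names(records)))
  if (nrow(records) == 0L) {
    warning("empty detection series; returning empty scores")
    records$score <- numeric(0)
    return(records)
  }
  ids <- vapply(hazards, function(h) h$id, character(1))
  names(hazards) <- ids
  unknown <- setdiff(unique(records$hazard_id), ids)
  if (length(unknown))
    stop("unknown hazard id(s): ", paste(unknown, collapse = ", "))
  records$score <- vapply(seq_len(nrow(records)), function(i) {
    hz <- hazards[[records$hazard_id[i]]]
    risk_score(membership(records$value[i], hz), hz)
  }, numeric(1))
  records
}
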
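#' Fraction of liposomes containing at least one active channel
#'
#' End-point chloride flux quantification:
#' \deqn{A = 100 (1 - \Delta Cl / \Delta Cl_{PF})}
#' where \eqn{\Delta Cl} is the chloride released on detergent addition and
#' \eqn{\Delta Cl_{PF}} the protein-free reference. A is scale-invariant in
#' the common units of the two measurements. Values below 0 (sample
#' releasing more chloride than the reference, usually a reference
#' mismatch) are retained but flagged with a warning.
#'
#' @param deltaCl chloride change on detergent addition (sample), vectorized
#' @param deltaClPF protein-free reference (same units), > 0
#' @return activity fraction A in percent
#' @examples
#' activityFraction(0.15, 1)   # 85
#' @export
activityFraction <- function(deltaCl, deltaClPF) {
  if (any(!is.finite(deltaClPF)) || any(deltaClPF <= 0))
    stop("protein-free reference must be positive")
  if (any(!is.finite(deltaCl)) || any(deltaCl < 0))
    stop("deltaCl must be nonnegative")
  A <- 100 * (1 - deltaCl / deltaClPF)
  if (any(A < 0))
    warning("negative activity fraction: sample released more chloride ",
            "than the protein-free reference (possible reference mismatch)")
  A
}

#' Summarize a table of flux measurements
#'
#' Computes the activity fraction per record and its mean and standard
#' deviation per construct and Ca2+ condition.
#'
#' @param records data.frame with columns \code{construct}, \code{ca_state},
#'   \code{replicate}, \code{delta_cl}, \code{delta_cl_pf}
#' @return list with \code{records} (input plus an \code{activity} column)
#'   and \code{summary} (one row per construct x condition with \code{mean},
#'   \code{sd}, \code{n})
#' @export
fluxReport <- function(records) {
  need <- c("construct", "ca_state", "replicate", "delta_cl", "delta_cl_pf")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  records$activity <- activityFraction(records$delta_cl, records$delta_cl_pf)
  agg <- stats::aggregate(activity ~ construct + ca_state, data = records,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  summary <- data.frame(agg[c("construct", "ca_state")],
                        mean = agg$activity[, "mean"],
                        sd = agg$activity[, "sd"],
                        n = agg$activity[, "n"])
  list(records = records, summary = summary)
}
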
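# Cost-effectiveness summarisation: QALY area-under-the-curve, ICER with
# dominance labels, incremental net health/monetary benefit.

#' QALYs by the area-under-the-curve method
#'
#' Trapezoidal integration of utility over the follow-up visits, in years.
#' With the default visit schedule (months 0, 6, 12, 18) this is the
#' within-trial 18-month QALY total.
#'
#' @param utilities Utility values at the visit times.
#' @param months Visit times in months (strictly increasing, same length).
#' @return QALYs (years).
#' @export
qaly_auc <- function(utilities, months = c(0, 6, 12, 18)) {
  if (length(utilities) != length(months)) {
    stop("utilities and months must have the same length", call. = FALSE)
  }
  if (anyNA(utilities)) {
    stop("missing utility values; impute before computing QALYs", call. = FALSE)
  }
  if (any(diff(months) <= 0)) stop("months must be increasing", call. = FALSE)
  t_years <- months / 12
  sum(diff(t_years) * (head(utilities, -1) + tail(utilities, -1)) / 2)
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' @param inc_cost Incremental cost (FT minus TAU), GBP.
#' @param inc_qaly Incremental QALYs.
#' @return A list with `label` (`"dominated"` if costlier and less
#'   effective, `"dominant"` if cheaper and more effective, `"undefined"`
#'   if the QALY difference is exactly zero, else `"ratio"`) and `value`
#'   (GBP/QALY; signed infinity when undefined with a cost difference).
#' @export
icer <- function(inc_cost, inc_qaly) {
  if (inc_qaly == 0) {
    value <- if (inc_cost == 0) NaN else sign(inc_cost) * Inf
    return(list(label = "undefined", value = value))
  }
  label <- if (inc_cost > 0 && inc_qaly < 0) "dominated"
  else if (inc_cost < 0 && inc_qaly > 0) "dominant"
  else "ratio"
  list(label = label, value = inc_cost / inc_qaly)
}

#' Incremental net health benefit
#'
#' `INHB(lambda) = dQ - dC / lambda`, in QALYs.
#'
#' @param inc_cost Incremental cost (GBP).
#' @param inc_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold lambda (GBP/QALY, > 0).
#' @return Net health benefit in QALYs.
#' @export
inhb <- function(inc_cost, inc_qaly, wtp = 30000) {
  if (any(wtp <= 0)) stop("willingness-to-pay must be > 0", call. = FALSE)
  inc_qaly - inc_cost / wtp
}

#' Incremental net monetary benefit
#'
#' `INMB(lambda) = lambda * dQ - dC = lambda * INHB(lambda)`, in GBP.
#'
#' @inheritParams inhb
#' @return Net monetary benefit in GBP.
#' @export
inmb <- function(inc_cost, inc_qaly, wtp = 30000) {
  wtp * inc_qaly - inc_cost
}

#' Cost-effectiveness summary from per-arm totals
#'
#' @param totals Tibble from [discount_and_sum()] (`arm`, `horizon`,
#'   `cost`, `qaly`).
#' @param wtp Willingness-to-pay for the net-benefit columns.
#' @return A tibble with one row per horizon: per-arm costs and QALYs,
#'   increments (FT minus TAU), ICER label and value, `inhb` and `inmb`.
#' @export
econ_result <- function(totals, wtp = 30000) {
  out <- lapply(unique(totals$horizon), function(h) {
    t_h <- totals[totals$horizon == h, ]
    ft <- t_h[t_h$arm == "FT", ]
    tau <- t_h[t_h$arm == "TAU", ]
    dc <- ft$cost - tau$cost
    dq <- ft$qaly - tau$qaly
    ic <- icer(dc, dq)
    tibble::tibble(
      horizon = h,
      cost_tau = tau$cost, cost_ft = ft$cost,
      qaly_tau = tau$qaly, qaly_ft = ft$qaly,
      inc_cost = dc, inc_qaly = dq,
      icer_label = ic$label, icer = ic$value,
      wtp = wtp, inhb = inhb(dc, dq, wtp), inmb = inmb(dc, dq, wtp)
    )
  })
  dplyr::bind_rows(out)
}
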
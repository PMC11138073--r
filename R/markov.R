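# The quasi-Markov engine. Three mutually exclusive states per 6-month
# cycle: repeated self-harm (RSH), no repeated self-harm (non-RSH), death.
# State-occupancy probabilities come directly from the fitted per-cycle
# event probabilities (conditional on being alive) scaled by the
# Kaplan-Meier survival curve -- not from a transition matrix.

#' Decision-model configuration
#'
#' @param rsh_definition State-event definition: `"sh"` (at least one
#'   self-harm hospitalisation in the cycle; base case) or `"any"` (any
#'   hospitalisation; secondary analysis).
#' @param horizon_cycles Number of 6-month cycles (default 10 = 60 months).
#' @param discount_rate Annual discount rate (default 0.035, the NICE
#'   reference case).
#' @param discount_from Within-cycle time point used in the discount
#'   exponent: `"start"` (default; cycle c is discounted by
#'   `(1+r)^(-c/2)`), `"midpoint"` or `"end"`.
#' @param include_mortality Include the death state (one-way analysis turns
#'   it off)?
#' @param include_post_trial_nonhosp Extrapolate non-hospital costs beyond
#'   the trial window through the hospitalisation-status models (one-way
#'   analysis sets them to zero)?
#' @param value_source `"empirical"` (suite cost/utility models) or
#'   `"nice"` (NICE evidence-review state utilities and RSH excess cost).
#' @param intervention_cost Named vector `c(FT=, TAU=)`: per-patient
#'   intervention cost, split equally over cycles 0-1 (first 12 months).
#' @param wtp Willingness-to-pay grid in GBP/QALY (default 0-50,000 by 500).
#' @param wtp_threshold Headline threshold for net-benefit summaries
#'   (default 30,000).
#' @param nice_params NICE parameter list (see [nice_parameters()]).
#' @return An object of class `model_config`.
#' @export
model_config <- function(rsh_definition = c("sh", "any"),
                         horizon_cycles = 10,
                         discount_rate = 0.035,
                         discount_from = c("start", "midpoint", "end"),
                         include_mortality = TRUE,
                         include_post_trial_nonhosp = TRUE,
                         value_source = c("empirical", "nice"),
                         intervention_cost = c(FT = 1745, TAU = 250),
                         wtp = seq(0, 50000, by = 500),
                         wtp_threshold = 30000,
                         nice_params = nice_parameters()) {
  rsh_definition <- match.arg(rsh_definition)
  discount_from <- match.arg(discount_from)
  value_source <- match.arg(value_source)
  assert_count(horizon_cycles, "horizon_cycles")
  assert_pos(discount_rate, "discount_rate", strict = FALSE)
  assert_pos(intervention_cost, "intervention_cost", strict = FALSE)
  stopifnot(all(c("FT", "TAU") %in% names(intervention_cost)))
  structure(
    list(rsh_definition = rsh_definition,
         horizon_cycles = as.integer(horizon_cycles),
         discount_rate = discount_rate, discount_from = discount_from,
         include_mortality = include_mortality,
         include_post_trial_nonhosp = include_post_trial_nonhosp,
         value_source = value_source,
         intervention_cost = intervention_cost,
         wtp = wtp, wtp_threshold = wtp_threshold,
         nice_params = nice_params),
    class = "model_config"
  )
}

#' Three-state occupancy from predicted event probabilities
#'
#' For each arm and cycle: `pi_death` from the Kaplan-Meier curve (zero when
#' mortality is excluded), `pi_rsh = P(state event | alive) * (1 -
#' pi_death)`, `pi_nonrsh` the remainder. Rows sum to one by construction
#' and are validated.
#'
#' @param pred Prediction grid from [suite_predictions()] (or
#'   [params_to_predictions()]), with columns `arm`, `cycle`, `p_sh`,
#'   `p_any`, `p_death`.
#' @param config A [model_config()].
#' @return A tibble `arm`, `cycle`, `pi_rsh`, `pi_nonrsh`, `pi_death`.
#' @export
build_occupancy <- function(pred, config = model_config()) {
  nc <- config$horizon_cycles
  pred <- pred[pred$cycle < nc, ]
  if (!all(0:(nc - 1) %in% pred$cycle)) {
    stop("predictions must cover every cycle of the horizon", call. = FALSE)
  }
  p_event <- if (config$rsh_definition == "sh") pred$p_sh else pred$p_any
  pi_death <- if (config$include_mortality) pred$p_death else rep(0, nrow(pred))
  occ <- tibble::tibble(
    arm = pred$arm, cycle = pred$cycle,
    pi_rsh = p_event * (1 - pi_death),
    pi_nonrsh = 1 - p_event * (1 - pi_death) - pi_death,
    pi_death = pi_death
  )
  bad <- with(occ, pi_rsh < -1e-12 | pi_rsh > 1 + 1e-12 |
                pi_nonrsh < -1e-12 | pi_nonrsh > 1 + 1e-12 |
                pi_death < -1e-12 | pi_death > 1 + 1e-12)
  if (any(bad)) stop("state probabilities outside [0, 1]", call. = FALSE)
  if (any(abs(occ$pi_rsh + occ$pi_nonrsh + occ$pi_death - 1) > 1e-12)) {
    stop("state occupancy rows do not sum to 1", call. = FALSE)
  }
  occ
}

#' Per-cycle expected costs and utilities
#'
#' Empirical mode composes, per arm and cycle, the expected hospital cost
#' (event probability times conditional cost, plus the non-self-harm
#' hospitalisation mixture), the expected non-hospital cost (occurrence
#' probability times conditional magnitude, mixed over event status), and
#' the expected utility (state-conditional means). Everything alive-scaled
#' by `1 - pi_death`; death contributes zero cost and zero utility. NICE
#' mode instead applies the evidence-review state utilities and RSH excess
#' cost. Intervention costs load onto cycles 0-1. Each cycle contributes
#' `utility * 0.5` QALYs (6-month cycles).
#'
#' @param pred Prediction grid (see [build_occupancy()]).
#' @param occupancy Output of [build_occupancy()].
#' @param config A [model_config()].
#' @return A tibble `arm`, `cycle`, `hosp_cost`, `nonhosp_cost`,
#'   `intervention_cost`, `total_cost`, `utility`, `qaly`.
#' @export
cycle_payoffs <- function(pred, occupancy, config = model_config()) {
  nc <- config$horizon_cycles
  pred <- pred[pred$cycle < nc, ]
  stopifnot(nrow(pred) == nrow(occupancy))
  alive <- 1 - occupancy$pi_death
  interv <- ifelse(pred$cycle <= 1,
                   config$intervention_cost[pred$arm] / 2, 0)

  if (config$value_source == "nice") {
    np <- config$nice_params
    hosp <- occupancy$pi_rsh * np$excess_cost$mean
    nonhosp <- rep(0, nrow(pred))
    utility <- occupancy$pi_rsh * np$u_rsh$mean +
      occupancy$pi_nonrsh * np$u_nonrsh$mean
  } else {
    p_ev <- if (config$rsh_definition == "sh") pred$p_sh else pred$p_any
    if (config$rsh_definition == "sh") {
      p_nonsh_mix <- pred$p_sh * pred$p_nonsh_given_sh +
        (1 - pred$p_sh) * pred$p_nonsh_given_nosh
      hosp_alive <- pred$p_sh * pred$cost_sh + p_nonsh_mix * pred$cost_nonsh
    } else {
      hosp_alive <- pred$p_any * pred$cost_any
    }
    nonhosp_alive <- p_ev * pred$p_nonhosp_given_ev * pred$cost_nonhosp_given_ev +
      (1 - p_ev) * pred$p_nonhosp_given_noev * pred$cost_nonhosp_given_noev
    if (!config$include_post_trial_nonhosp) {
      trial_cycles <- attr(pred, "n_trial_cycles") %||% 3L
      nonhosp_alive[pred$cycle >= trial_cycles] <- 0
    }
    u_alive <- p_ev * pred$u_ev + (1 - p_ev) * pred$u_noev
    hosp <- alive * hosp_alive
    nonhosp <- alive * nonhosp_alive
    utility <- alive * u_alive
  }

  tibble::tibble(
    arm = pred$arm, cycle = pred$cycle,
    hosp_cost = unname(hosp), nonhosp_cost = unname(nonhosp),
    intervention_cost = unname(interv),
    total_cost = unname(hosp + nonhosp + interv),
    utility = unname(utility), qaly = unname(utility * 0.5)
  )
}

#' Discount and accumulate per-arm totals
#'
#' Cycle c (starting at month 6c) is weighted by `(1 + r)^(-t)` with `t`
#' the cycle's start (default), midpoint or end time in years. Totals are
#' returned at the 18-month (cycles 0-2) and full-horizon (60-month)
#' cut-offs.
#'
#' @param payoffs Output of [cycle_payoffs()].
#' @param config A [model_config()].
#' @return A tibble `arm`, `horizon` (`"18m"`, `"60m"`), `cost`, `qaly`.
#' @export
discount_and_sum <- function(payoffs, config = model_config()) {
  r <- config$discount_rate
  t_years <- switch(config$discount_from,
                    start = payoffs$cycle / 2,
                    midpoint = (payoffs$cycle + 0.5) / 2,
                    end = (payoffs$cycle + 1) / 2)
  w <- (1 + r)^(-t_years)
  dc <- payoffs$total_cost * w
  dq <- payoffs$qaly * w
  horizons <- list("18m" = 2L, "60m" = config$horizon_cycles - 1L)
  out <- lapply(names(horizons), function(h) {
    keep <- payoffs$cycle <= horizons[[h]]
    tibble::tibble(
      arm = c("TAU", "FT"), horizon = h,
      cost = c(sum(dc[keep & payoffs$arm == "TAU"]),
               sum(dc[keep & payoffs$arm == "FT"])),
      qaly = c(sum(dq[keep & payoffs$arm == "TAU"]),
               sum(dq[keep & payoffs$arm == "FT"]))
    )
  })
  dplyr::bind_rows(out)
}

#' Run the full engine from a fitted suite or a prediction grid
#'
#' @param x A `gee_suite` or a prediction grid tibble.
#' @param config A [model_config()].
#' @param profile Optional covariate profile (suites only).
#' @return A list of class `markov_result`: `predictions`, `occupancy`,
#'   `payoffs`, `totals`, and `result` (the [econ_result()] summary at the
#'   configured willingness-to-pay threshold).
#' @export
run_markov <- function(x, config = model_config(), profile = NULL) {
  pred <- if (inherits(x, "gee_suite")) suite_predictions(x, profile) else x
  occ <- build_occupancy(pred, config)
  pay <- cycle_payoffs(pred, occ, config)
  tot <- discount_and_sum(pay, config)
  structure(
    list(predictions = pred, occupancy = occ, payoffs = pay, totals = tot,
         result = econ_result(tot, wtp = config$wtp_threshold),
         config = config),
    class = "markov_result"
  )
}

#' @export
print.markov_result <- function(x, ...) {
  cat("<markov_result>\n")
  print(x$result)
  invisible(x)
}

#' Prediction grid directly from generating parameters
#'
#' Builds the engine's input grid from a [trajectory_params()] object
#' instead of fitted models -- the "truth" path used to study the engine in
#' isolation and to verify parameter recovery.
#'
#' @param params A [trajectory_params()].
#' @return A prediction grid tibble as from [suite_predictions()].
#' @export
params_to_predictions <- function(params) {
  nc <- params$n_cycles
  ntc <- params$n_trial_cycles
  grid <- tidyr::expand_grid(arm = c("TAU", "FT"), cycle = 0:(nc - 1))
  tc <- pmin(grid$cycle, ntc - 1) + 1L
  ri <- match(grid$arm, rownames(params$p_sh))
  ai <- cbind(ri, grid$cycle + 1L)
  at <- cbind(ri, tc)
  p_sh <- params$p_sh[ai]
  p_nonsh_sh <- params$p_nonsh_given_sh[grid$cycle + 1L]
  p_nonsh_nosh <- params$p_nonsh_given_nosh[grid$cycle + 1L]
  # "any hospitalisation" implied by the generating mechanism
  p_any <- p_sh + (1 - p_sh) * p_nonsh_nosh
  cum_death <- apply(params$death_hazard, 1, function(h) 1 - cumprod(1 - h))
  out <- tibble::tibble(
    arm = grid$arm, cycle = grid$cycle,
    p_sh = p_sh, p_any = p_any,
    p_nonsh_given_sh = p_nonsh_sh, p_nonsh_given_nosh = p_nonsh_nosh,
    cost_sh = params$cost_sh_mean[ai],
    cost_any = (p_sh * params$cost_sh_mean[ai] +
                  (p_sh * p_nonsh_sh + (1 - p_sh) * p_nonsh_nosh) *
                  params$cost_nonsh_mean[ai]) / pmax(p_any, 1e-12),
    cost_nonsh = params$cost_nonsh_mean[ai],
    p_nonhosp_given_ev = params$p_nonhosp$sh[at],
    p_nonhosp_given_noev = params$p_nonhosp$nosh[at],
    cost_nonhosp_given_ev = rep(params$nonhosp_mean[["sh"]], nrow(grid)),
    cost_nonhosp_given_noev = rep(params$nonhosp_mean[["nosh"]], nrow(grid)),
    u_ev = rep(params$u_mean[["sh"]], nrow(grid)),
    u_noev = rep(params$u_mean[["nosh"]], nrow(grid)),
    p_death = cum_death[cbind(grid$cycle + 1L, match(grid$arm, colnames(cum_death)))]
  )
  attr(out, "n_trial_cycles") <- ntc
  out
}
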
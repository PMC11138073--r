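# Probabilistic sensitivity analysis: Monte-Carlo propagation of parameter
# uncertainty. Each draw samples every model's coefficient vector from a
# multivariate normal on the link scale (mean = fitted coefficients,
# covariance = robust/pooled covariance), re-runs the quasi-Markov engine,
# and records the incremental cost and QALY pair. NICE mode instead draws
# the state utilities from their Beta distributions and the excess cost
# from its Gamma distribution.

# precompute the design matrices behind suite_predictions() so a draw is a
# handful of matrix-vector products
prediction_designs <- function(suite, profile = NULL) {
  grid <- tidyr::expand_grid(arm = c("TAU", "FT"),
                             cycle = 0:(suite$n_cycles - 1))
  nd0 <- profile_frame(suite, grid$arm, grid$cycle, profile, event = 0)
  nd1 <- profile_frame(suite, grid$arm, grid$cycle, profile, event = 1)
  m <- suite$models
  X <- list(
    p_sh = gee_design(m$p_sh, nd0),
    p_any = gee_design(m$p_any, nd0),
    p_nonsh_sh = gee_design(m$p_nonsh, dplyr::mutate(nd0, sh_hosp = 1)),
    p_nonsh_nosh = gee_design(m$p_nonsh, dplyr::mutate(nd0, sh_hosp = 0)),
    cost_sh = gee_design(m$cost_sh, nd0),
    cost_any = gee_design(m$cost_any, nd0),
    cost_nonsh = gee_design(m$cost_nonsh, nd0),
    p_nonhosp_ev = gee_design(m$p_nonhosp, nd1),
    p_nonhosp_noev = gee_design(m$p_nonhosp, nd0),
    cost_nonhosp_ev = gee_design(m$cost_nonhosp, nd1),
    cost_nonhosp_noev = gee_design(m$cost_nonhosp, nd0),
    u_ev = gee_design(m$utility, nd1),
    u_noev = gee_design(m$utility, nd0)
  )
  km <- suite$km$curve
  p_death <- km$p_death[match(paste(grid$arm, grid$cycle),
                              paste(km$arm, km$cycle))]
  list(grid = grid, X = X, p_death = p_death,
       n_trial_cycles = suite$n_trial_cycles)
}

# prediction grid from (possibly perturbed) coefficient vectors
designs_to_pred <- function(des, beta) {
  inv <- function(nm, family, b) {
    eta <- drop(des$X[[nm]] %*% b)
    switch(family, binomial = plogis(eta), gamma = exp(eta), gaussian = eta)
  }
  out <- tibble::tibble(
    arm = des$grid$arm, cycle = des$grid$cycle,
    p_sh = inv("p_sh", "binomial", beta$p_sh),
    p_any = inv("p_any", "binomial", beta$p_any),
    p_nonsh_given_sh = inv("p_nonsh_sh", "binomial", beta$p_nonsh),
    p_nonsh_given_nosh = inv("p_nonsh_nosh", "binomial", beta$p_nonsh),
    cost_sh = inv("cost_sh", "gamma", beta$cost_sh),
    cost_any = inv("cost_any", "gamma", beta$cost_any),
    cost_nonsh = inv("cost_nonsh", "gamma", beta$cost_nonsh),
    p_nonhosp_given_ev = inv("p_nonhosp_ev", "binomial", beta$p_nonhosp),
    p_nonhosp_given_noev = inv("p_nonhosp_noev", "binomial", beta$p_nonhosp),
    cost_nonhosp_given_ev = inv("cost_nonhosp_ev", "gamma", beta$cost_nonhosp),
    cost_nonhosp_given_noev = inv("cost_nonhosp_noev", "gamma", beta$cost_nonhosp),
    u_ev = pmin(inv("u_ev", "gaussian", beta$utility), 1),
    u_noev = pmin(inv("u_noev", "gaussian", beta$utility), 1)
  )
  out$p_death <- des$p_death
  attr(out, "n_trial_cycles") <- des$n_trial_cycles
  out
}

# eigen-decomposition sampler factors; repairs non-PSD covariances by
# clipping negative eigenvalues at zero (with a warning)
mvn_factor <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1))) {
    warning("covariance matrix not positive semi-definite; using nearest PSD repair")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
}

#' Probabilistic sensitivity analysis
#'
#' @param suite A fitted (optionally pooled) `gee_suite`.
#' @param config A [model_config()]; `value_source = "nice"` switches the
#'   utility/cost draws to the NICE Beta/Gamma distributions (event
#'   probabilities still come from coefficient draws).
#' @param n_sims Number of Monte-Carlo draws (default 10,000).
#' @param seed Master seed; each draw uses its own sub-stream, so extending
#'   `n_sims` never changes earlier draws.
#' @param horizon `"60m"` (default) or `"18m"`.
#' @param profile Optional covariate profile.
#' @return A tibble of class `psa_draws` with columns `sim`, `inc_cost`,
#'   `inc_qaly`, plus attributes `horizon`, `seed`, `deterministic` (the
#'   draw-free engine result).
#' @export
psa_run <- function(suite, config = model_config(), n_sims = 10000,
                    seed = 1L, horizon = c("60m", "18m"), profile = NULL) {
  stopifnot(inherits(suite, "gee_suite"))
  horizon <- match.arg(horizon)
  des <- prediction_designs(suite, profile)
  model_names <- names(suite$models)
  betas <- lapply(suite$models, coef)
  factors <- lapply(suite$models, function(f) mvn_factor(vcov(f)))
  nice <- config$value_source == "nice"
  np <- config$nice_params

  det_pred <- designs_to_pred(des, betas)
  det_tot <- discount_and_sum(
    cycle_payoffs(det_pred, build_occupancy(det_pred, config), config), config)

  seeds <- sub_seeds(seed, n_sims)
  dc <- dq <- numeric(n_sims)
  cfg <- config
  for (s in seq_len(n_sims)) {
    set.seed(seeds[s])
    b <- betas
    for (nm in model_names) {
      z <- rnorm(length(b[[nm]]))
      b[[nm]] <- b[[nm]] + drop(factors[[nm]] %*% z)
    }
    if (nice) {
      cfg$nice_params$u_rsh$mean <- rbeta(1, np$u_rsh$alpha, np$u_rsh$beta)
      cfg$nice_params$u_nonrsh$mean <- rbeta(1, np$u_nonrsh$alpha,
                                             np$u_nonrsh$beta)
      cfg$nice_params$excess_cost$mean <- rgamma(1, shape = np$excess_cost$shape,
                                                 scale = np$excess_cost$scale)
    }
    pred <- designs_to_pred(des, b)
    tot <- discount_and_sum(
      cycle_payoffs(pred, build_occupancy(pred, cfg), cfg), cfg)
    t_h <- tot[tot$horizon == horizon, ]
    dc[s] <- t_h$cost[t_h$arm == "FT"] - t_h$cost[t_h$arm == "TAU"]
    dq[s] <- t_h$qaly[t_h$arm == "FT"] - t_h$qaly[t_h$arm == "TAU"]
  }
  structure(
    tibble::tibble(sim = seq_len(n_sims), inc_cost = dc, inc_qaly = dq),
    class = c("psa_draws", class(tibble::tibble())),
    horizon = horizon, seed = seed,
    deterministic = econ_result(det_tot, wtp = config$wtp_threshold)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that FT is cost-effective at each willingness-to-pay value:
#' the fraction of draws with positive incremental net monetary benefit.
#'
#' @param draws A `psa_draws` tibble (or any tibble with `inc_cost`,
#'   `inc_qaly`).
#' @param wtp Willingness-to-pay grid (default GBP 0-50,000 in steps of 500).
#' @return A tibble `wtp`, `prob_ce`.
#' @export
ceac <- function(draws, wtp = seq(0, 50000, by = 500)) {
  stopifnot(nrow(draws) >= 1)
  tibble::tibble(
    wtp = wtp,
    prob_ce = vapply(wtp, function(l) {
      mean(l * draws$inc_qaly - draws$inc_cost > 0)
    }, numeric(1))
  )
}

#' Cost-effectiveness plane summary
#'
#' Quadrant counts of the PSA cloud (incremental QALYs on x, incremental
#' cost on y). `NE`: more effective & more costly; `NW`: less effective &
#' more costly (FT dominated); `SE`: more effective & cheaper (FT
#' dominant); `SW`: less effective & cheaper. Points with `inc_qaly > 0`
#' count as east, `inc_cost > 0` as north.
#'
#' @param draws A `psa_draws` tibble.
#' @return A list with `draws` and `quadrants` (tibble `quadrant`, `n`,
#'   `prop`).
#' @export
ce_plane <- function(draws) {
  stopifnot(nrow(draws) >= 1)
  east <- draws$inc_qaly > 0
  north <- draws$inc_cost > 0
  q <- factor(ifelse(north, ifelse(east, "NE", "NW"),
                     ifelse(east, "SE", "SW")),
              levels = c("NE", "NW", "SE", "SW"))
  tab <- table(q)
  list(
    draws = draws,
    quadrants = tibble::tibble(
      quadrant = names(tab),
      n = as.integer(tab),
      prop = as.numeric(tab) / nrow(draws)
    )
  )
}

#' Plot the cost-effectiveness plane
#'
#' @param draws A `psa_draws` tibble.
#' @param wtp Threshold line slope (GBP/QALY); `NULL` for none.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, wtp = 30000) {
  p <- ggplot2::ggplot(draws, ggplot2::aes(x = .data$inc_qaly,
                                           y = .data$inc_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs (FT vs TAU)",
                  y = "Incremental cost (£, FT vs TAU)") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_tbl Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl) {
  ggplot2::ggplot(ceac_tbl, ggplot2::aes(x = .data$wtp, y = .data$prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (£/QALY)",
                  y = "Probability FT is cost-effective") +
    ggplot2::theme_minimal()
}
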
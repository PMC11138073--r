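# The regression suite behind the quasi-Markov engine: per-cycle state-event
# probabilities, conditional hospital and non-hospital costs, non-hospital
# cost occurrence, utilities, and the Kaplan-Meier death curve. All
# regressions are GEE fits clustered on patient with a saturated
# arm-by-cycle interaction design on top of the baseline covariates.

suite_covariates <- c("female", "age_15_17", "cause_poisoning", "hosp_referred")

# analysis frame: factors, derived outcomes
prepare_analysis_data <- function(data) {
  nc <- data$n_cycles
  ntc <- data$n_trial_cycles
  d <- data$cycles
  d$arm <- factor(d$arm, levels = c("TAU", "FT"))
  d$cycle_f <- factor(d$cycle, levels = 0:(nc - 1))
  d$cycle_tf <- factor(pmin(d$cycle, ntc - 1), levels = 0:(ntc - 1))
  d$any_hosp <- ifelse(is.na(d$sh_hosp) | is.na(d$nonsh_hosp), NA,
                       pmax(d$sh_hosp, d$nonsh_hosp))
  d$any_hosp_cost <- d$sh_hosp_cost + d$nonsh_hosp_cost
  if (!"nonhosp_occ" %in% names(d) || all(is.na(d$nonhosp_occ))) {
    d$nonhosp_occ <- as.integer(d$nonhosp_cost > 0)
  }
  d
}

suite_model_specs <- function(event_var) {
  covs <- paste(suite_covariates, collapse = " + ")
  full <- function(lhs, extra = NULL) {
    rhs <- paste(c(extra, covs, "cycle_f", "arm:cycle_f"), collapse = " + ")
    stats::as.formula(paste(lhs, "~", rhs))
  }
  trialf <- function(lhs, extra = NULL) {
    rhs <- paste(c(extra, covs, "cycle_tf", "arm:cycle_tf"), collapse = " + ")
    stats::as.formula(paste(lhs, "~", rhs))
  }
  list(
    p_sh = list(formula = full("sh_hosp"), family = "binomial",
                subset = quote(!is.na(sh_hosp)), window = "full",
                prune = "none", time_var = "cycle_f"),
    p_any = list(formula = full("any_hosp"), family = "binomial",
                 subset = quote(!is.na(any_hosp)), window = "full",
                 prune = "none", time_var = "cycle_f"),
    cost_sh = list(formula = full("sh_hosp_cost"), family = "gamma",
                   subset = quote(sh_hosp %in% 1 & sh_hosp_cost > 0),
                   window = "full", prune = "none", time_var = "cycle_f"),
    cost_any = list(formula = full("any_hosp_cost"), family = "gamma",
                    subset = quote(any_hosp %in% 1 & any_hosp_cost > 0),
                    window = "full", prune = "none", time_var = "cycle_f"),
    p_nonsh = list(formula = full("nonsh_hosp", "sh_hosp"), family = "binomial",
                   subset = quote(!is.na(nonsh_hosp) & !is.na(sh_hosp)),
                   window = "full", prune = "interactions", time_var = "cycle_f"),
    cost_nonsh = list(formula = full("nonsh_hosp_cost"), family = "gamma",
                      subset = quote(nonsh_hosp %in% 1 & nonsh_hosp_cost > 0),
                      window = "full", prune = "none", time_var = "cycle_f"),
    p_nonhosp = list(formula = trialf("nonhosp_occ", event_var),
                     family = "binomial",
                     subset = quote(!is.na(nonhosp_occ)),
                     window = "trial", prune = "interactions",
                     time_var = "cycle_tf"),
    cost_nonhosp = list(formula = trialf("nonhosp_cost", event_var),
                        family = "gamma",
                        subset = quote(nonhosp_occ %in% 1 & nonhosp_cost > 0),
                        window = "trial", prune = "interactions+time",
                        time_var = "cycle_tf"),
    utility = list(formula = trialf("utility", event_var), family = "gaussian",
                   subset = quote(!is.na(utility)),
                   window = "trial", prune = "interactions+time",
                   time_var = "cycle_tf")
  )
}

#' Fit the full regression suite
#'
#' Fits the probability, conditional-cost and utility GEE models and the
#' Kaplan-Meier death curve that together supply every quantity the
#' quasi-Markov engine consumes. The state-event definition (`"sh"`:
#' self-harm hospitalisation, base case; `"any"`: any hospitalisation,
#' secondary analysis) selects the conditioning indicator for the
#' non-hospital cost and utility models.
#'
#' Pruning: the per-cycle state-probability and conditional hospital-cost
#' models keep the saturated arm-by-cycle interactions (maximum flexibility
#' over the record period); the non-self-harm hospitalisation and
#' non-hospital-cost occurrence models prune non-significant arm
#' interactions; the conditional non-hospital-cost and utility models may
#' additionally prune cycle dummies (collapsing to state-only means).
#'
#' @param data A `trial_data` (complete or one imputed copy).
#' @param rsh_definition `"sh"` (base case) or `"any"` (secondary).
#' @param corstr Working correlation for all fits.
#' @param prune Apply Wald pruning (default `TRUE`)?
#' @param alpha Pruning significance level.
#' @param drop_spec Optional named list of pre-decided `drop_cols` per model
#'   (overrides `prune`; used when refitting imputed datasets under a pooled
#'   pruning decision).
#' @return An object of class `gee_suite`.
#' @export
fit_suite <- function(data, rsh_definition = c("sh", "any"),
                      corstr = c("independence", "exchangeable"),
                      prune = TRUE, alpha = 0.05, drop_spec = NULL) {
  rsh_definition <- match.arg(rsh_definition)
  corstr <- match.arg(corstr)
  event_var <- if (rsh_definition == "sh") "sh_hosp" else "any_hosp"
  d <- prepare_analysis_data(data)
  trial <- d[d$cycle < data$n_trial_cycles, ]
  specs <- suite_model_specs(event_var)

  models <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    frame <- if (sp$window == "trial") trial else d
    rows <- eval(sp$subset, frame)
    rows[is.na(rows)] <- FALSE
    drops <- drop_spec[[nm]] %||% character(0)
    if (sp$family == "binomial") {
      drops <- union(drops,
                     degenerate_cell_drops(frame[rows, ], sp$formula,
                                           sp$time_var))
    }
    # refit with inestimable directions merged out if the data cannot
    # identify them (quasi-separation at small samples / rare outcomes)
    tries <- 0L
    repeat {
      fit <- tryCatch(fit_gee(sp$formula, frame[rows, ], id = "id",
                              family = sp$family, corstr = corstr,
                              drop_cols = drops),
                      qmcea_separation = identity)
      if (!inherits(fit, "qmcea_separation")) break
      new_drops <- setdiff(fit$columns, "(Intercept)")
      tries <- tries + 1L
      if (!length(new_drops) || tries > 5L) stop(fit)
      warning(sprintf("model '%s': merging inestimable terms (%s)", nm,
                      paste(new_drops, collapse = ", ")), call. = FALSE)
      drops <- union(drops, new_drops)
    }
    if (is.null(drop_spec) && prune && sp$prune != "none") {
      fit <- prune_interactions(fit, frame[rows, ], alpha = alpha,
                                prune_time = sp$prune == "interactions+time",
                                time_var = sp$time_var)
    }
    fit
  })
  names(models) <- names(specs)

  structure(
    list(models = models,
         km = km_death(data),
         covar_means = colMeans(data$patients[, suite_covariates]),
         event_var = event_var, rsh_definition = rsh_definition,
         n_cycles = data$n_cycles, n_trial_cycles = data$n_trial_cycles,
         corstr = corstr, alpha = alpha, pooled = FALSE),
    class = "gee_suite"
  )
}

#' @export
print.gee_suite <- function(x, ...) {
  cat(sprintf("<gee_suite> %d GEE models + Kaplan-Meier deaths (%s state definition%s)\n",
              length(x$models), x$rsh_definition,
              if (x$pooled) sprintf(", pooled over %d imputations", x$m) else ""))
  invisible(x)
}

# Saturated logistic designs are unidentifiable in arm-by-cycle cells whose
# outcome is constant (the cell log-odds is infinite). Merge such cells into
# their neighbours by dropping the corresponding interaction dummy (and, if
# the pooled cycle is still constant, the cycle dummy), instead of letting
# the fit diverge.
degenerate_cell_drops <- function(frame, formula, time_var) {
  y <- frame[[all.vars(formula)[1]]]
  tv <- as.integer(as.character(frame[[time_var]]))
  drops <- character(0)
  for (cyc in sort(unique(tv))) {
    in_c <- tv == cyc
    y_ft <- y[in_c & frame$arm == "FT"]
    y_tau <- y[in_c & frame$arm == "TAU"]
    const <- function(v) length(v) > 0 && (all(v == 0) || all(v == 1))
    if (const(y_ft) || const(y_tau)) {
      drops <- c(drops, sprintf("%s%d:armFT", time_var, cyc))
    }
    if (const(y[in_c]) && cyc > min(tv)) {
      drops <- c(drops, sprintf("%s%d", time_var, cyc))
    }
  }
  drops
}

#' Kaplan-Meier cumulative death probability per arm and cycle
#'
#' Product-limit estimate of the probability of having died by the end of
#' each cycle, with a log-rank test between arms. Time is measured in cycles;
#' a patient dying during cycle c contributes an event at time c, others are
#' censored at their hospital-record censoring cycle.
#'
#' @param data A `trial_data`, or a patient table with columns `arm`,
#'   `death_cycle`, `censor_cycle`.
#' @param n_cycles Number of cycles (taken from `data` when it is a
#'   `trial_data`).
#' @return A list with `curve` (tibble `arm`, `cycle`, `p_death`),
#'   `logrank_p`, and the underlying `survfit` object.
#' @export
km_death <- function(data, n_cycles = NULL) {
  if (inherits(data, "trial_data")) {
    n_cycles <- n_cycles %||% data$n_cycles
    p <- data$patients
  } else {
    p <- data
    n_cycles <- n_cycles %||% max(p$censor_cycle)
  }
  event <- as.integer(!is.na(p$death_cycle))
  time <- ifelse(event == 1, p$death_cycle, pmin(p$censor_cycle, n_cycles))
  if (any(time < 0)) stop("negative event/censoring times", call. = FALSE)
  sdat <- data.frame(time = time, event = event,
                     arm = factor(p$arm, levels = c("TAU", "FT")))
  sdat$arm <- droplevels(sdat$arm)
  sf <- survival::survfit(survival::Surv(time, event) ~ arm, data = sdat)
  cycles <- 0:(n_cycles - 1)
  sm <- summary(sf, times = cycles, extend = TRUE)
  strata <- if (is.null(sm$strata)) {
    rep(levels(sdat$arm), length.out = length(sm$time))
  } else {
    sub("^arm=", "", as.character(sm$strata))
  }
  curve <- tibble::tibble(arm = strata, cycle = sm$time, p_death = 1 - sm$surv)
  # arms absent from the data contribute a zero death curve
  missing_arms <- setdiff(c("TAU", "FT"), unique(curve$arm))
  if (length(missing_arms)) {
    curve <- dplyr::bind_rows(
      curve,
      tidyr::expand_grid(arm = missing_arms, cycle = cycles, p_death = 0)
    )
  }
  curve <- dplyr::arrange(curve, .data$arm, .data$cycle)
  logrank_p <- NA_real_
  if (sum(event) > 0 && length(unique(sdat$arm[!is.na(sdat$arm)])) == 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = sdat)
    logrank_p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
  }
  list(curve = curve, logrank_p = logrank_p, fit = sf)
}

# --- predictions --------------------------------------------------------

# newdata row(s) at the covariate means for a given arm/cycle and, for the
# conditional models, event status
profile_frame <- function(suite, arm, cycle, profile = NULL, event = NULL) {
  prof <- as.list(profile %||% suite$covar_means)
  nd <- tibble::tibble(
    arm = factor(arm, levels = c("TAU", "FT")),
    cycle_f = factor(cycle, levels = 0:(suite$n_cycles - 1)),
    cycle_tf = factor(pmin(cycle, suite$n_trial_cycles - 1),
                      levels = 0:(suite$n_trial_cycles - 1))
  )
  for (nm in suite_covariates) nd[[nm]] <- prof[[nm]]
  if (!is.null(event)) nd[[suite$event_var]] <- event
  nd
}

#' Predicted quantities for one arm and cycle (or the full grid)
#'
#' Inverse-link predictions from every model of the suite at the "average
#' participant" covariate profile (covariate means on the linear-predictor
#' scale). Post-trial cycles reuse the final trial-cycle dummies of the
#' trial-window models (non-hospital costs and utilities are extrapolated
#' through the hospitalisation-status relationship observed in the trial);
#' the hospital-record models cover every cycle directly, so there is no
#' extrapolation beyond the record period and cycles outside it are an error.
#'
#' @param suite A `gee_suite`.
#' @param arm `"FT"` or `"TAU"`; `NULL` for the full arm-by-cycle grid.
#' @param cycle Cycle index 0..(n_cycles-1); `NULL` for the grid.
#' @param profile Optional named list of covariate values (defaults to the
#'   cohort means).
#' @return For a single (arm, cycle): a named list with elements `p_sh`,
#'   `p_any`, `p_nonsh_given_sh`, `p_nonsh_given_nosh`, `cost_sh`,
#'   `cost_any`, `cost_nonsh`, `p_nonhosp_given_ev`, `p_nonhosp_given_noev`,
#'   `cost_nonhosp_given_ev`, `cost_nonhosp_given_noev`, `u_ev`, `u_noev`,
#'   `p_death`. Otherwise a tibble with those columns for every arm and
#'   cycle (`suite_predictions()`).
#' @export
predict_suite <- function(suite, arm = NULL, cycle = NULL, profile = NULL) {
  stopifnot(inherits(suite, "gee_suite"))
  if (is.null(arm) && is.null(cycle)) return(suite_predictions(suite, profile))
  if (!arm %in% c("FT", "TAU")) stop("arm must be 'FT' or 'TAU'", call. = FALSE)
  if (!cycle %in% 0:(suite$n_cycles - 1)) {
    stop(sprintf("cycle %s outside the modelled record period 0..%d (no extrapolation)",
                 cycle, suite$n_cycles - 1), call. = FALSE)
  }
  g <- suite_predictions(suite, profile)
  as.list(g[g$arm == arm & g$cycle == cycle, setdiff(names(g), c("arm", "cycle"))])
}

#' @rdname predict_suite
#' @export
suite_predictions <- function(suite, profile = NULL) {
  grid <- tidyr::expand_grid(arm = c("TAU", "FT"),
                             cycle = 0:(suite$n_cycles - 1))
  m <- suite$models
  nd0 <- profile_frame(suite, grid$arm, grid$cycle, profile, event = 0)
  nd1 <- profile_frame(suite, grid$arm, grid$cycle, profile, event = 1)
  km <- suite$km$curve
  out <- tibble::tibble(
    arm = grid$arm, cycle = grid$cycle,
    p_sh = predict(m$p_sh, nd0),
    p_any = predict(m$p_any, nd0),
    p_nonsh_given_sh = predict(m$p_nonsh,
                               dplyr::mutate(nd0, sh_hosp = 1)),
    p_nonsh_given_nosh = predict(m$p_nonsh,
                                 dplyr::mutate(nd0, sh_hosp = 0)),
    cost_sh = predict(m$cost_sh, nd0),
    cost_any = predict(m$cost_any, nd0),
    cost_nonsh = predict(m$cost_nonsh, nd0),
    p_nonhosp_given_ev = predict(m$p_nonhosp, nd1),
    p_nonhosp_given_noev = predict(m$p_nonhosp, nd0),
    cost_nonhosp_given_ev = predict(m$cost_nonhosp, nd1),
    cost_nonhosp_given_noev = predict(m$cost_nonhosp, nd0),
    u_ev = predict(m$utility, nd1),
    u_noev = predict(m$utility, nd0)
  )
  out$p_death <- km$p_death[match(paste(out$arm, out$cycle),
                                  paste(km$arm, km$cycle))]
  attr(out, "n_trial_cycles") <- suite$n_trial_cycles
  out
}

#' Fit and pool the suite over multiply-imputed datasets
#'
#' Fits the saturated suite within every imputed dataset, pools coefficients
#' and covariances by Rubin's rules, decides the pruning drop-set once from
#' the pooled Wald tests, refits every imputed dataset under that common
#' reduced design, and pools again. The returned suite carries pooled
#' coefficients and total (within + between imputation) covariances, so
#' downstream predictions and probabilistic sensitivity draws reflect
#' imputation uncertainty.
#'
#' @param imputations A `trial_imputations` list from [multiple_impute()].
#' @inheritParams fit_suite
#' @return A pooled `gee_suite`.
#' @export
fit_suite_mi <- function(imputations, rsh_definition = c("sh", "any"),
                         corstr = c("independence", "exchangeable"),
                         prune = TRUE, alpha = 0.05) {
  rsh_definition <- match.arg(rsh_definition)
  corstr <- match.arg(corstr)
  stopifnot(length(imputations) >= 2)
  suites <- lapply(imputations, fit_suite, rsh_definition = rsh_definition,
                   corstr = corstr, prune = FALSE)
  pooled <- pool_suites(suites)
  if (prune) {
    specs <- suite_model_specs(pooled$event_var)
    drops <- lapply(names(pooled$models), function(nm) {
      sp <- specs[[nm]]
      if (sp$prune == "none") return(character(0))
      wald_drop_set(pooled$models[[nm]], alpha = alpha,
                    prune_time = sp$prune == "interactions+time",
                    time_var = sp$time_var)
    })
    names(drops) <- names(pooled$models)
    if (any(lengths(drops) > 0)) {
      suites <- lapply(imputations, fit_suite, rsh_definition = rsh_definition,
                       corstr = corstr, prune = FALSE, drop_spec = drops)
      pooled <- pool_suites(suites)
    }
  }
  pooled
}

pool_suites <- function(suites) {
  pooled <- suites[[1]]
  for (nm in names(pooled$models)) {
    pm <- rubin_pool_matrix(lapply(suites, function(s) coef(s$models[[nm]])),
                            lapply(suites, function(s) vcov(s$models[[nm]])))
    fit <- pooled$models[[nm]]
    fit$coefficients <- pm$coefficients
    fit$vcov <- pm$vcov
    pooled$models[[nm]] <- fit
  }
  pooled$pooled <- TRUE
  pooled$m <- length(suites)
  pooled
}
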
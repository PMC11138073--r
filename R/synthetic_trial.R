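# Synthetic two-arm trial generator. Emulates the statistical structure the
# long-term analysis consumes: ~400 adolescents per arm, ten 6-month cycles,
# declining hospitalisation probabilities, gamma conditional costs,
# state-dependent utilities, rare deaths, monotone questionnaire dropout and
# administrative censoring of hospital records.

#' Cohort specification for the synthetic trial
#'
#' @param n_per_arm Patients per arm; a scalar (equal arms) or a length-2
#'   vector `c(FT, TAU)`. Default 398 per arm, the scale of the source trial.
#' @param n_cycles Number of 6-month cycles (default 10, i.e. 60 months).
#' @param seed Integer seed for the cohort draw.
#' @param p_female,p_age_15_17,p_poisoning,p_hosp_referred Marginal
#'   probabilities of the baseline covariates: gender, older age group
#'   (15-17 vs 11-14), index hospitalisation cause self-poisoning (vs
#'   self-injury), and hospital-referred flag. Covariates are sampled
#'   independently.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_arm = 398, n_cycles = 10, seed = 1L,
                        p_female = 0.85, p_age_15_17 = 0.60,
                        p_poisoning = 0.75, p_hosp_referred = 0.55) {
  if (length(n_per_arm) == 1) n_per_arm <- c(FT = n_per_arm, TAU = n_per_arm)
  if (length(n_per_arm) != 2) {
    stop("configuration error: 'n_per_arm' must have length 1 or 2", call. = FALSE)
  }
  n_per_arm <- setNames(as.numeric(n_per_arm), c("FT", "TAU"))
  assert_count(n_per_arm, "n_per_arm")
  assert_count(n_cycles, "n_cycles")
  mix <- c(p_female = p_female, p_age_15_17 = p_age_15_17,
           p_poisoning = p_poisoning, p_hosp_referred = p_hosp_referred)
  assert_prob(mix, "covariate_mix")
  structure(
    list(n_per_arm = n_per_arm, n_cycles = as.integer(n_cycles),
         seed = as.integer(seed), covariate_mix = mix),
    class = "cohort_spec"
  )
}

#' Generating parameters for synthetic patient trajectories
#'
#' Defaults are the published summary values of the source trial
#' (see [shift_p_sh()] and friends), so the default fixture regenerates
#' trial-like data.
#'
#' @param n_cycles Number of 6-month cycles.
#' @param p_sh 2 x `n_cycles` matrix (rows `FT`, `TAU`) of per-cycle
#'   probabilities of at least one self-harm hospitalisation.
#' @param beta_cov Named log-odds offsets for the baseline covariates applied
#'   to the self-harm hospitalisation model (default all 0: the published
#'   rates are population-level).
#' @param p_nonsh_given_sh,p_nonsh_given_nosh Per-cycle probability of a
#'   hospitalisation without evidence of self-harm, conditional on self-harm
#'   hospitalisation status (treatment-invariant).
#' @param cost_sh_mean,cost_nonsh_mean 2 x `n_cycles` matrices of conditional
#'   mean hospital costs (GBP).
#' @param cost_shape Gamma shape for conditional hospital costs.
#' @param p_nonhosp List of two 2 x `n_trial_cycles` matrices (`sh`, `nosh`):
#'   probability that any non-hospital cost occurs, by arm and self-harm
#'   status, within the trial window.
#' @param nonhosp_mean Named vector `c(sh=, nosh=)` of conditional mean
#'   non-hospital costs (GBP).
#' @param nonhosp_shape Gamma shape for non-hospital costs.
#' @param u_mean Named vector `c(sh=, nosh=)` of mean utilities by self-harm
#'   status (defaults 0.674 / 0.792).
#' @param u_sd Gaussian utility noise SD (truncated to `u_range`).
#' @param u_range Valid utility range; default the EQ-5D-3L tariff range
#'   `c(-0.594, 1)`.
#' @param death_hazard 2 x `n_cycles` matrix of per-cycle death hazards.
#' @param dropout_hazard Per-trial-cycle hazard of monotone questionnaire
#'   dropout (utilities and self-reported costs).
#' @param censor_pmf Length `n_cycles + 1` distribution of the hospital-record
#'   censoring cycle (last element = never censored).
#' @param n_trial_cycles Cycles covered by trial questionnaires (default 3,
#'   months 0-18).
#' @param intervention_cost Named vector `c(FT=, TAU=)` of per-patient
#'   intervention costs (GBP) incurred over the first 12 months. The source
#'   micro-costing is not public; these are configurable placeholders.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(n_cycles = 10,
                              p_sh = shift_p_sh(),
                              beta_cov = c(female = 0, age_15_17 = 0,
                                           cause_poisoning = 0, hosp_referred = 0),
                              p_nonsh_given_sh = shift_p_nonsh()$sh,
                              p_nonsh_given_nosh = shift_p_nonsh()$nosh,
                              cost_sh_mean = shift_cost_sh(),
                              cost_nonsh_mean = shift_cost_nonsh(),
                              cost_shape = 1.5,
                              p_nonhosp = shift_p_nonhosp(),
                              nonhosp_mean = c(sh = 933.35, nosh = 705.03),
                              nonhosp_shape = 2,
                              u_mean = c(sh = 0.674, nosh = 0.792),
                              u_sd = 0.22,
                              u_range = c(-0.594, 1),
                              death_hazard = shift_death_hazard(),
                              dropout_hazard = c(0.40, 0.08, 0.06),
                              censor_pmf = shift_censor_pmf(),
                              n_trial_cycles = 3,
                              intervention_cost = c(FT = 1745, TAU = 250)) {
  assert_count(n_cycles, "n_cycles")
  n_trial_cycles <- min(n_trial_cycles, n_cycles)
  stopifnot(is.matrix(p_sh), nrow(p_sh) == 2, ncol(p_sh) >= n_cycles,
            is.matrix(cost_sh_mean), is.matrix(cost_nonsh_mean),
            is.matrix(death_hazard))
  assert_prob(p_sh, "p_sh")
  assert_prob(p_nonsh_given_sh, "p_nonsh_given_sh")
  assert_prob(p_nonsh_given_nosh, "p_nonsh_given_nosh")
  assert_prob(unlist(p_nonhosp), "p_nonhosp")
  assert_pos(cost_sh_mean, "cost_sh_mean", strict = FALSE)
  assert_pos(cost_nonsh_mean, "cost_nonsh_mean", strict = FALSE)
  assert_pos(cost_shape, "cost_shape")
  assert_pos(nonhosp_shape, "nonhosp_shape")
  assert_pos(nonhosp_mean, "nonhosp_mean", strict = FALSE)
  assert_pos(u_sd, "u_sd", strict = FALSE)
  if (any(u_mean < u_range[1] | u_mean > u_range[2])) {
    stop("configuration error: 'u_mean' outside the valid utility range",
         call. = FALSE)
  }
  assert_pos(death_hazard, "death_hazard", strict = FALSE)
  assert_prob(dropout_hazard, "dropout_hazard")
  assert_prob(censor_pmf, "censor_pmf")
  if (length(censor_pmf) != n_cycles + 1 ||
      abs(sum(censor_pmf) - 1) > 1e-8) {
    stop("configuration error: 'censor_pmf' must have length n_cycles + 1 and sum to 1",
         call. = FALSE)
  }
  structure(
    list(n_cycles = as.integer(n_cycles), p_sh = p_sh[, 1:n_cycles, drop = FALSE],
         beta_cov = beta_cov,
         p_nonsh_given_sh = p_nonsh_given_sh[1:n_cycles],
         p_nonsh_given_nosh = p_nonsh_given_nosh[1:n_cycles],
         cost_sh_mean = cost_sh_mean[, 1:n_cycles, drop = FALSE],
         cost_nonsh_mean = cost_nonsh_mean[, 1:n_cycles, drop = FALSE],
         cost_shape = cost_shape, p_nonhosp = p_nonhosp,
         nonhosp_mean = nonhosp_mean, nonhosp_shape = nonhosp_shape,
         u_mean = u_mean, u_sd = u_sd, u_range = u_range,
         death_hazard = death_hazard[, 1:n_cycles, drop = FALSE],
         dropout_hazard = dropout_hazard,
         censor_pmf = censor_pmf,
         n_trial_cycles = as.integer(n_trial_cycles),
         intervention_cost = intervention_cost),
    class = "trajectory_params"
  )
}

#' Trial-like default generating parameters
#'
#' Convenience wrapper: [trajectory_params()] with all defaults, i.e. the
#' published summary values of the source trial.
#'
#' @param ... Overrides passed on to [trajectory_params()].
#' @return A `trajectory_params` object.
#' @export
shift_params <- function(...) trajectory_params(...)

new_trial_data <- function(patients, cycles, params = NULL) {
  structure(
    list(patients = patients, cycles = cycles,
         n_cycles = if (!is.null(params)) params$n_cycles else max(cycles$cycle) + 1L,
         n_trial_cycles = if (!is.null(params)) params$n_trial_cycles else 3L,
         params = params),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %d patients, %d patient-cycle records, %d cycles\n",
              nrow(x$patients), nrow(x$cycles), x$n_cycles))
  invisible(x)
}

#' Generate a randomised cohort roster
#'
#' Draws baseline covariates i.i.d. from the covariate mix and assigns arms
#' 1:1 (exactly `n_per_arm` per arm, in randomised order).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: `id`, `arm` (factor, `TAU`
#'   reference), and 0/1 covariates `female`, `age_15_17`, `cause_poisoning`,
#'   `hosp_referred`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- sum(spec$n_per_arm)
  arm <- sample(rep(factor(c("FT", "TAU"), levels = c("TAU", "FT")),
                    times = spec$n_per_arm))
  mix <- spec$covariate_mix
  tibble::tibble(
    id = seq_len(n),
    arm = arm,
    female = rbinom(n, 1, mix[["p_female"]]),
    age_15_17 = rbinom(n, 1, mix[["p_age_15_17"]]),
    cause_poisoning = rbinom(n, 1, mix[["p_poisoning"]]),
    hosp_referred = rbinom(n, 1, mix[["p_hosp_referred"]])
  )
}

#' Simulate complete (pre-missingness) patient trajectories
#'
#' For each surviving patient-cycle: a self-harm hospitalisation indicator
#' from its logistic model, a non-self-harm hospitalisation from the
#' SH-conditional probability, gamma conditional costs only when events occur,
#' non-hospital cost occurrence and gamma magnitude, and (within the trial
#' window) a truncated-normal utility around the state mean. Deaths absorb
#' the patient at cycle granularity; no records are produced after death.
#'
#' @param roster Cohort roster from [generate_cohort()].
#' @param params A [trajectory_params()].
#' @param seed Integer seed.
#' @return A `trial_data` object (complete: censoring and dropout not yet
#'   applied; `censor_cycle` is set to `n_cycles`, `dropout_cycle` to
#'   `n_trial_cycles`).
#' @export
generate_trajectories <- function(roster, params, seed = 1L) {
  force(roster)  # evaluate before seeding: callers may pass generator calls
  stopifnot(inherits(params, "trajectory_params"))
  set.seed(seed)
  nc <- params$n_cycles
  ntc <- params$n_trial_cycles
  n <- nrow(roster)
  armc <- as.character(roster$arm)

  # Death cycle per patient from per-cycle hazards (absorbing, at most once).
  death_cycle <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (c in seq_len(nc) - 1L) {
    h <- params$death_hazard[armc, c + 1L]
    dies <- alive & (rbinom(n, 1, h) == 1L)
    death_cycle[dies] <- c
    alive <- alive & !dies
  }

  grid <- tidyr::expand_grid(roster, cycle = seq_len(nc) - 1L)
  gdeath <- death_cycle[match(grid$id, roster$id)]
  grid <- grid[is.na(gdeath) | grid$cycle < gdeath, ]
  m <- nrow(grid)
  garm <- as.character(grid$arm)
  gri <- match(garm, rownames(params$p_sh))
  ci <- grid$cycle + 1L
  ai <- cbind(gri, ci)

  X <- as.matrix(grid[, names(params$beta_cov)])
  p0 <- params$p_sh[ai]
  lp <- qlogis(pmin(pmax(p0, 1e-12), 1 - 1e-12)) + drop(X %*% params$beta_cov)
  sh <- rbinom(m, 1, plogis(lp))
  # degenerate probabilities stay degenerate regardless of covariate offsets
  sh[p0 == 0] <- 0L
  sh[p0 == 1] <- 1L

  p_ns <- ifelse(sh == 1, params$p_nonsh_given_sh[ci], params$p_nonsh_given_nosh[ci])
  nonsh <- rbinom(m, 1, p_ns)

  shp <- params$cost_shape
  sh_cost <- numeric(m)
  i <- sh == 1
  sh_cost[i] <- rgamma(sum(i), shape = shp,
                       scale = params$cost_sh_mean[ai[i, , drop = FALSE]] / shp)
  ns_cost <- numeric(m)
  i <- nonsh == 1
  ns_cost[i] <- rgamma(sum(i), shape = shp,
                       scale = params$cost_nonsh_mean[ai[i, , drop = FALSE]] / shp)

  # Trial-window fields: non-hospital costs and utilities (cycles 0..ntc-1).
  tw <- grid$cycle < ntc
  nonhosp_occ <- rep(NA_integer_, m)
  nonhosp_cost <- rep(NA_real_, m)
  utility <- rep(NA_real_, m)
  if (any(tw)) {
    atw <- cbind(gri[tw], ci[tw])
    p_occ <- ifelse(sh[tw] == 1,
                    params$p_nonhosp$sh[atw],
                    params$p_nonhosp$nosh[atw])
    occ <- rbinom(sum(tw), 1, p_occ)
    mu_nh <- ifelse(sh[tw] == 1, params$nonhosp_mean[["sh"]],
                    params$nonhosp_mean[["nosh"]])
    cost <- numeric(sum(tw))
    cost[occ == 1] <- rgamma(sum(occ == 1), shape = params$nonhosp_shape,
                             scale = mu_nh[occ == 1] / params$nonhosp_shape)
    nonhosp_occ[tw] <- occ
    nonhosp_cost[tw] <- cost
    # locations are moment-matched so the truncated draws average to the
    # stated state means despite the utility ceiling at 1
    loc <- vapply(params$u_mean, trunc_norm_location, numeric(1),
                  sd = params$u_sd, lo = params$u_range[1],
                  hi = params$u_range[2])
    mu_u <- ifelse(sh[tw] == 1, loc[["sh"]], loc[["nosh"]])
    utility[tw] <- rtrunc_norm(sum(tw), mu_u, params$u_sd,
                               params$u_range[1], params$u_range[2])
  }

  cycles <- tibble::tibble(
    id = grid$id, arm = grid$arm,
    female = grid$female, age_15_17 = grid$age_15_17,
    cause_poisoning = grid$cause_poisoning, hosp_referred = grid$hosp_referred,
    cycle = grid$cycle,
    sh_hosp = sh, nonsh_hosp = nonsh,
    sh_hosp_cost = sh_cost, nonsh_hosp_cost = ns_cost,
    nonhosp_occ = nonhosp_occ, nonhosp_cost = nonhosp_cost,
    utility = utility
  )
  patients <- dplyr::mutate(roster,
    death_cycle = death_cycle,
    censor_cycle = nc,
    dropout_cycle = ntc
  )
  new_trial_data(patients, cycles, params)
}

#' Apply questionnaire dropout and hospital-record censoring
#'
#' Trial-collected fields (utility, non-hospital costs) drop out monotonically
#' from a per-patient dropout cycle drawn from `dropout_hazard`; hospital
#' record fields are censored from a censoring cycle drawn from `censor_pmf`.
#' Patient-cycle rows in which every field is unobserved are removed.
#'
#' @param data Complete `trial_data` from [generate_trajectories()].
#' @param params A [trajectory_params()]; defaults to the generating ones.
#' @param seed Integer seed.
#' @return A `trial_data` object with missing fields and updated
#'   `dropout_cycle` / `censor_cycle` in the patient table.
#' @export
apply_missingness <- function(data, params = data$params, seed = 1L) {
  force(data)
  force(params)  # evaluate before seeding: callers may pass generator calls
  stopifnot(inherits(data, "trial_data"), inherits(params, "trajectory_params"))
  set.seed(seed)
  n <- nrow(data$patients)
  nc <- params$n_cycles
  ntc <- params$n_trial_cycles

  # Monotone questionnaire dropout: first missing trial cycle (ntc = none).
  dropout_cycle <- rep(ntc, n)
  still_in <- rep(TRUE, n)
  for (c in seq_len(ntc) - 1L) {
    drops <- still_in & (rbinom(n, 1, params$dropout_hazard[c + 1L]) == 1L)
    dropout_cycle[drops] <- c
    still_in <- still_in & !drops
  }

  censor_cycle <- sample(0:nc, n, replace = TRUE, prob = params$censor_pmf)

  cyc <- data$cycles
  pos <- match(cyc$id, data$patients$id)
  dc <- dropout_cycle[pos]
  cc <- censor_cycle[pos]
  trial_gone <- cyc$cycle >= dc
  cyc$utility[trial_gone] <- NA_real_
  cyc$nonhosp_occ[trial_gone] <- NA_integer_
  cyc$nonhosp_cost[trial_gone] <- NA_real_
  hosp_gone <- cyc$cycle >= cc
  cyc$sh_hosp[hosp_gone] <- NA_integer_
  cyc$nonsh_hosp[hosp_gone] <- NA_integer_
  cyc$sh_hosp_cost[hosp_gone] <- NA_real_
  cyc$nonsh_hosp_cost[hosp_gone] <- NA_real_

  all_missing <- is.na(cyc$sh_hosp) & is.na(cyc$nonsh_hosp) &
    is.na(cyc$utility) & is.na(cyc$nonhosp_cost)
  cyc <- cyc[!all_missing, ]

  patients <- dplyr::mutate(data$patients,
    dropout_cycle = dropout_cycle,
    censor_cycle = pmin(censor_cycle,
                        ifelse(is.na(death_cycle), nc, death_cycle))
  )
  new_trial_data(patients, cyc, params)
}

#' Simulate a full synthetic trial dataset
#'
#' Convenience wrapper: cohort, trajectories, then missingness, with
#' operation-level seeds derived from one master seed.
#'
#' @param spec A [cohort_spec()].
#' @param params A [trajectory_params()] (defaults to [shift_params()] at the
#'   spec's cycle count).
#' @param missingness Apply dropout and censoring (default `TRUE`)?
#' @return A `trial_data` object.
#' @export
simulate_trial <- function(spec = cohort_spec(),
                           params = shift_params(n_cycles = spec$n_cycles),
                           missingness = TRUE) {
  seeds <- sub_seeds(spec$seed, 3L)
  spec$seed <- seeds[1]
  roster <- generate_cohort(spec)
  data <- generate_trajectories(roster, params, seed = seeds[2])
  if (missingness) data <- apply_missingness(data, params, seed = seeds[3])
  data
}

#' Write / read a trial dataset as plain CSV
#'
#' Two files: `cycles.csv` (one row per patient-cycle) and `patients.csv`
#' (one row per patient). Missing values are written as empty fields.
#'
#' @param data A `trial_data` object.
#' @param dir Directory (created if needed).
#' @return `write_trial_data()` returns the file paths invisibly;
#'   `read_trial_data()` returns a `trial_data` object.
#' @export
write_trial_data <- function(data, dir) {
  stopifnot(inherits(data, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cycles = file.path(dir, "cycles.csv"),
             patients = file.path(dir, "patients.csv"))
  readr::write_csv(data$cycles, paths["cycles"], na = "")
  readr::write_csv(data$patients, paths["patients"], na = "")
  invisible(paths)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(dir) {
  cyc <- readr::read_csv(file.path(dir, "cycles.csv"),
                         show_col_types = FALSE, na = "")
  pat <- readr::read_csv(file.path(dir, "patients.csv"),
                         show_col_types = FALSE, na = "")
  cyc$arm <- factor(cyc$arm, levels = c("TAU", "FT"))
  pat$arm <- factor(pat$arm, levels = c("TAU", "FT"))
  for (col in c("sh_hosp", "nonsh_hosp", "nonhosp_occ")) {
    cyc[[col]] <- as.integer(cyc[[col]])
  }
  cyc$utility <- as.numeric(cyc$utility)
  cyc$nonhosp_cost <- as.numeric(cyc$nonhosp_cost)
  pat$death_cycle <- as.integer(pat$death_cycle)
  out <- new_trial_data(pat, cyc)
  out$n_cycles <- max(pat$censor_cycle, cyc$cycle + 1L)
  out
}
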
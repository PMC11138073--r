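# Shared fixtures, all generated in code.

# small flat-rate parameter set for fast, predictable tests
flat_params <- function(n_cycles = 4, p_sh = 0.3, death = 0,
                        dropout = c(0, 0, 0), censor_never = TRUE, ...) {
  arm_mat <- function(v) {
    m <- rbind(FT = rep(v, n_cycles)[1:n_cycles],
               TAU = rep(v, n_cycles)[1:n_cycles])
    colnames(m) <- paste0("cycle", 0:(n_cycles - 1))
    m
  }
  pmf <- if (censor_never) {
    c(rep(0, n_cycles), 1)
  } else {
    c(rep(0.03, n_cycles), 1 - 0.03 * n_cycles)
  }
  trajectory_params(
    n_cycles = n_cycles,
    p_sh = arm_mat(p_sh),
    p_nonsh_given_sh = rep(0.3, n_cycles),
    p_nonsh_given_nosh = rep(0.2, n_cycles),
    cost_sh_mean = arm_mat(1000),
    cost_nonsh_mean = arm_mat(500),
    p_nonhosp = list(sh = arm_mat(0.9)[, 1:3], nosh = arm_mat(0.8)[, 1:3]),
    death_hazard = arm_mat(death),
    dropout_hazard = dropout,
    censor_pmf = pmf,
    n_trial_cycles = min(3, n_cycles),
    ...
  )
}

# quick simulated dataset
quick_trial <- function(n = 80, seed = 1, params = flat_params(),
                        missingness = FALSE) {
  spec <- cohort_spec(n_per_arm = n, n_cycles = params$n_cycles, seed = seed)
  roster <- generate_cohort(spec)
  d <- generate_trajectories(roster, params, seed = seed + 1)
  if (missingness) d <- apply_missingness(d, params, seed = seed + 2)
  d
}

# patient table for Kaplan-Meier tests (no cycle records needed)
km_patients <- function(death_cycles, censor_cycles, arm = "FT",
                        n_other = 100) {
  n <- length(censor_cycles)
  tibble::tibble(
    id = seq_len(n + n_other),
    arm = factor(c(rep(arm, n), rep(if (arm == "FT") "TAU" else "FT", n_other)),
                 levels = c("TAU", "FT")),
    death_cycle = c(death_cycles, rep(NA_integer_, n_other)),
    censor_cycle = c(censor_cycles, rep(10L, n_other))
  )
}

# clustered logistic data with known per-arm-cycle log-odds
sim_logit_panel <- function(n_pat = 200, n_cycles = 3, p_ft, p_tau, seed = 1) {
  set.seed(seed)
  arm <- rep(c("TAU", "FT"), each = n_pat)
  grid <- expand.grid(id = seq_len(2 * n_pat), cycle = 0:(n_cycles - 1))
  grid$arm <- factor(arm[grid$id], levels = c("TAU", "FT"))
  p <- ifelse(grid$arm == "FT", p_ft[grid$cycle + 1], p_tau[grid$cycle + 1])
  grid$y <- rbinom(nrow(grid), 1, p)
  grid$cycle_f <- factor(grid$cycle)
  grid
}
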
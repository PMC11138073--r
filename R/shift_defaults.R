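# Published SHIFT-trial summary values used as default generating parameters
# for the synthetic-trial module and as benchmark inputs. All values are
# transcribed from the published long-term cost-utility summary tables of the
# trial; the patient-level data themselves are confidential (NHS Digital) and
# are never shipped -- the generator emulates their statistical structure.

arm_matrix <- function(ft, tau) {
  m <- rbind(FT = ft, TAU = tau)
  colnames(m) <- paste0("cycle", seq_len(ncol(m)) - 1L)
  m
}

#' Per-cycle probability of at least one self-harm hospitalisation, by arm
#'
#' Ten 6-month cycles (months 0-60), published imputed hospitalisation rates
#' per arm. These decline from ~43-47% in the first half-year to ~6-8% at
#' months 54-60.
#'
#' @return A 2 x 10 matrix with rows `FT`, `TAU`.
#' @export
shift_p_sh <- function() {
  arm_matrix(
    ft  = c(0.430, 0.297, 0.218, 0.209, 0.167, 0.112, 0.113, 0.098, 0.093, 0.058),
    tau = c(0.470, 0.250, 0.259, 0.211, 0.163, 0.138, 0.123, 0.092, 0.089, 0.075)
  )
}

#' Probability of a non-self-harm hospitalisation, conditional on self-harm
#' hospitalisation status in the same cycle (treatment-invariant)
#'
#' @return A list with numeric vectors `sh` (given a self-harm
#'   hospitalisation occurred) and `nosh` (given none), one value per cycle.
#' @export
shift_p_nonsh <- function() {
  list(
    sh   = c(0.338, 0.296, 0.255, 0.219, 0.188, 0.146, 0.132, 0.124, 0.122, 0.087),
    nosh = c(0.268, 0.232, 0.197, 0.167, 0.143, 0.109, 0.098, 0.092, 0.091, 0.064)
  )
}

#' Conditional mean cost (GBP) of self-harm hospitalisation per arm and cycle
#' @return A 2 x 10 matrix with rows `FT`, `TAU`.
#' @export
shift_cost_sh <- function() {
  arm_matrix(
    ft  = c(1050.65, 1692.41, 1431.47, 1697.69, 1042.65, 657.86, 489.10, 785.75, 187.67, 146.19),
    tau = c(684.43, 980.63, 667.83, 553.13, 1042.65, 657.86, 489.10, 785.75, 187.67, 146.19)
  )
}

#' Conditional mean cost (GBP) of hospitalisation without evidence of
#' self-harm per arm and cycle
#' @return A 2 x 10 matrix with rows `FT`, `TAU`.
#' @export
shift_cost_nonsh <- function() {
  arm_matrix(
    ft  = c(648.29, 940.25, 727.97, 437.16, 562.54, 901.23, 734.25, 440.37, 416.66, 436.28),
    tau = c(1076.22, 1156.76, 1204.11, 568.07, 415.30, 328.53, 372.74, 460.23, 1248.69, 252.06)
  )
}

#' Probability that any non-hospital cost occurs in a trial cycle, by arm and
#' self-harm hospitalisation status
#'
#' Observed for the three within-trial cycles only (months 0-18); the model
#' extrapolates the final trial cycle beyond month 18.
#'
#' @return A list of two 2 x 3 matrices, `sh` and `nosh`, rows `FT`, `TAU`.
#' @export
shift_p_nonhosp <- function() {
  list(
    sh   = arm_matrix(ft = c(0.963, 0.872, 0.879), tau = c(0.980, 0.872, 0.879)),
    nosh = arm_matrix(ft = c(0.925, 0.762, 0.773), tau = c(0.958, 0.762, 0.773))
  )
}

#' Per-cycle death hazard by arm
#'
#' Two deaths were observed over 60 months, both in the FT arm between 3 and
#' 4 years post-randomisation (cycles 6 and 7); none in TAU. Default hazards
#' place that expectation at cycle granularity.
#'
#' @return A 2 x 10 matrix with rows `FT`, `TAU`.
#' @export
shift_death_hazard <- function() {
  ft <- numeric(10)
  ft[7:8] <- c(0.0029, 0.0034)
  arm_matrix(ft = ft, tau = numeric(10))
}

#' Hospital-record censoring distribution over cycles
#'
#' Probability that a patient's hospital-record follow-up ends at the start of
#' each cycle (administrative censoring), plus a final mass for complete
#' 60-month follow-up. Derived from the published per-cycle missing-data
#' counts: near-complete early records, <20% missing at 42 months, ~60%
#' missing at 54-60 months (so ~40% observed at cycle 9).
#'
#' @return Numeric vector of length 11 summing to 1; element `c + 1` is
#'   P(censored at cycle c), the last element is P(never censored).
#' @export
shift_censor_pmf <- function() {
  inc <- c(8, 2, 8, 12, 6, 4, 65, 106, 142, 133)  # newly censored per cycle
  c(inc, 795 - sum(inc)) / 795
}

#' Parameters of the NICE evidence-review economic model
#'
#' State utilities and the excess cost of the repeated self-harm state with
#' their probabilistic distributions: Beta(2025.242, 152.438) for the
#' non-self-harm state (mean 0.93), Beta(1529.743, 719.879) for the self-harm
#' state (mean 0.68), Gamma(shape 4, scale 533.38) for the per-cycle excess
#' cost (mean ~GBP 2,134).
#'
#' @return Named list with elements `u_nonrsh`, `u_rsh` (each `alpha`,
#'   `beta`, `mean`) and `excess_cost` (`shape`, `scale`, `mean`).
#' @export
nice_parameters <- function() {
  list(
    u_nonrsh = list(alpha = 2025.242, beta = 152.438,
                    mean = beta_mean(2025.242, 152.438)),
    u_rsh = list(alpha = 1529.743, beta = 719.879,
                 mean = beta_mean(1529.743, 719.879)),
    excess_cost = list(shape = 4, scale = 533.38, mean = 4 * 533.38)
  )
}

#' Mean of a Beta distribution
#'
#' @param alpha,beta Positive shape parameters.
#' @return `alpha / (alpha + beta)`.
#' @export
beta_mean <- function(alpha, beta) {
  assert_pos(alpha, "alpha")
  assert_pos(beta, "beta")
  alpha / (alpha + beta)
}

#' Published per-arm discounted totals of the long-term cost-utility analysis
#'
#' The published deterministic cost-effectiveness summary: per-arm discounted
#' total costs (GBP) and QALYs by scenario and horizon. Scenarios:
#' `within_trial` (original 18-month trial analysis), `base` (self-harm
#' hospitalisations define the repeated self-harm state), `nice` (NICE
#' evidence-review cost and utility values), `any_hosp` (any hospitalisation
#' defines the state).
#'
#' @return A tibble with columns `scenario`, `horizon`, `arm`, `cost`, `qaly`.
#' @export
shift_reported_totals <- function() {
  tibble::tribble(
    ~scenario,      ~horizon, ~arm,  ~cost,   ~qaly,
    "within_trial", "18m",    "TAU", 3725.49, 1.122,
    "within_trial", "18m",    "FT",  4991.72, 1.157,
    "base",         "18m",    "TAU", 3281,    1.160,
    "base",         "18m",    "FT",  4986,    1.159,
    "base",         "60m",    "TAU", 7283,    3.68,
    "base",         "60m",    "FT",  8975,    3.67,
    "nice",         "18m",    "TAU", 1268.82, 1.349,
    "nice",         "18m",    "FT",  2618.50, 1.346,
    "nice",         "60m",    "TAU", 1512.79, 4.30,
    "nice",         "60m",    "FT",  2845.35, 4.29,
    "any_hosp",     "18m",    "TAU", 3278,    1.16,
    "any_hosp",     "18m",    "FT",  4989,    1.16,
    "any_hosp",     "60m",    "TAU", 7159,    3.66,
    "any_hosp",     "60m",    "FT",  8878,    3.68
  )
}

#' Published incremental results (FT vs TAU) of the long-term analysis
#'
#' Incremental discounted cost and QALYs as printed in the published summary
#' (computed there from unrounded per-arm totals, hence not always equal to
#' differences of the rounded totals above).
#'
#' @return A tibble with columns `scenario`, `horizon`, `inc_cost`, `inc_qaly`.
#' @export
shift_reported_increments <- function() {
  tibble::tribble(
    ~scenario,  ~horizon, ~inc_cost, ~inc_qaly,
    "base",     "18m",    1705,      -0.001,
    "base",     "60m",    1693,      -0.010,
    "nice",     "18m",    1349.68,   -0.002,
    "nice",     "60m",    1332.56,   -0.001,
    "any_hosp", "18m",    1712,      0.00004,
    "any_hosp", "60m",    1718,      0.010
  )
}
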
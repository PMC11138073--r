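# Engine tests run on prediction grids built directly from generating
# parameters (the truth path), so every expectation is closed-form.

pred_const <- function(p_sh = 0.43, p_death = 0, n_cycles = 10,
                       u_ev = 0.674, u_noev = 0.792) {
  g <- tidyr::expand_grid(arm = c("TAU", "FT"), cycle = 0:(n_cycles - 1))
  out <- tibble::tibble(
    arm = g$arm, cycle = g$cycle,
    p_sh = p_sh, p_any = p_sh,
    p_nonsh_given_sh = 0, p_nonsh_given_nosh = 0,
    cost_sh = 1000, cost_any = 1000, cost_nonsh = 500,
    p_nonhosp_given_ev = 0, p_nonhosp_given_noev = 0,
    cost_nonhosp_given_ev = 900, cost_nonhosp_given_noev = 700,
    u_ev = u_ev, u_noev = u_noev,
    p_death = p_death
  )
  attr(out, "n_trial_cycles") <- 3L
  out
}

no_interv <- function(...) {
  model_config(intervention_cost = c(FT = 0, TAU = 0), ...)
}

test_that("occupancy composes event probabilities with survival", {
  # no mortality, P(RSH) = 0.43 -> (0.43, 0.57, 0)
  occ <- build_occupancy(pred_const(0.43), no_interv(include_mortality = FALSE))
  expect_equal(occ$pi_rsh, rep(0.43, 20))
  expect_equal(occ$pi_nonrsh, rep(0.57, 20))
  expect_equal(occ$pi_death, rep(0, 20))

  # P(RSH) = 0 and no deaths -> everyone in non-RSH
  occ0 <- build_occupancy(pred_const(0), no_interv())
  expect_equal(occ0$pi_nonrsh, rep(1, 20))

  # the two-death Kaplan-Meier value still leaves rows summing to 1
  pred <- pred_const(0.2)
  pred$p_death[pred$arm == "FT" & pred$cycle >= 7] <-
    1 - (345 / 346) * (296 / 297)
  occ2 <- build_occupancy(pred, no_interv())
  r <- occ2[occ2$arm == "FT" & occ2$cycle == 7, ]
  expect_equal(r$pi_death, 0.00625, tolerance = 1e-3)
  expect_equal(r$pi_rsh + r$pi_nonrsh + r$pi_death, 1, tolerance = 1e-12)
})

test_that("occupancy invariants hold on the trial-scale truth path", {
  pred <- params_to_predictions(shift_params())
  for (def in c("sh", "any")) {
    occ <- build_occupancy(pred, no_interv(rsh_definition = def))
    expect_true(all(abs(occ$pi_rsh + occ$pi_nonrsh + occ$pi_death - 1) < 1e-12))
    expect_true(all(occ$pi_rsh >= 0 & occ$pi_nonrsh >= 0 & occ$pi_death >= 0))
    for (a in c("FT", "TAU")) {
      expect_true(all(diff(occ$pi_death[occ$arm == a]) >= 0))
    }
  }
})

test_that("cycle payoffs follow the cost and utility compositions", {
  # NICE mode with pi = (1, 0, 0): 0.68 * 0.5 QALYs and the excess cost
  pred <- pred_const(1)
  cfg <- no_interv(value_source = "nice")
  occ <- build_occupancy(pred, cfg)
  pay <- cycle_payoffs(pred, occ, cfg)
  expect_equal(pay$qaly, rep(0.68 * 0.5, 20), tolerance = 1e-6)
  expect_equal(pay$total_cost, rep(4 * 533.38, 20), tolerance = 1e-9)

  # all-death occupancy: zero costs and zero QALYs
  predd <- pred_const(0.3, p_death = 1)
  cfgd <- no_interv()
  payd <- cycle_payoffs(predd, build_occupancy(predd, cfgd), cfgd)
  expect_true(all(payd$hosp_cost == 0 & payd$nonhosp_cost == 0))
  expect_true(all(payd$qaly == 0))

  # empirical utilities mix by state: 0.5/0.5 -> 0.733
  pred5 <- pred_const(0.5)
  cfg5 <- no_interv()
  pay5 <- cycle_payoffs(pred5, build_occupancy(pred5, cfg5), cfg5)
  expect_equal(pay5$utility, rep(0.5 * 0.674 + 0.5 * 0.792, 20),
               tolerance = 1e-12)

  # expected hospital cost: P(SH) E[c_SH] + mixture x E[c_nonSH]
  predm <- pred_const(0.4)
  predm$p_nonsh_given_sh <- 0.3
  predm$p_nonsh_given_nosh <- 0.2
  cfgm <- no_interv()
  paym <- cycle_payoffs(predm, build_occupancy(predm, cfgm), cfgm)
  expect_equal(paym$hosp_cost,
               rep(0.4 * 1000 + (0.4 * 0.3 + 0.6 * 0.2) * 500, 20),
               tolerance = 1e-12)

  # intervention costs load half on each of cycles 0 and 1
  cfgi <- model_config(intervention_cost = c(FT = 1745, TAU = 250))
  payi <- cycle_payoffs(pred5, build_occupancy(pred5, cfgi), cfgi)
  expect_equal(payi$intervention_cost[payi$arm == "FT" & payi$cycle <= 1],
               rep(872.5, 2))
  expect_true(all(payi$intervention_cost[payi$cycle > 1] == 0))
})

test_that("discounting weights and horizon sums are correct", {
  pay <- tibble::tibble(
    arm = rep(c("TAU", "FT"), each = 10), cycle = rep(0:9, 2),
    total_cost = rep(c(0, 0, 1, rep(0, 7)), 2),
    qaly = rep(0.5, 20)
  )
  # cycle-2 weight at 3.5%: 1.035^-1
  tot <- discount_and_sum(pay, no_interv(discount_rate = 0.035))
  expect_equal(tot$cost[tot$horizon == "60m"][1], 1.035^-1, tolerance = 1e-12)

  # zero discount rate: plain sums; constant utility 1 gives 5 QALYs
  pay1 <- dplyr::mutate(pay, qaly = 0.5)
  tot0 <- discount_and_sum(pay1, no_interv(discount_rate = 0))
  expect_equal(tot0$qaly[tot0$horizon == "60m"], rep(5, 2))
  expect_equal(tot0$qaly[tot0$horizon == "18m"], rep(1.5, 2))
  # the published TAU total must respect the 5-QALY ceiling
  expect_lt(shift_reported_totals()$qaly[5], 5)

  # discounted <= undiscounted, equality iff r = 0
  totr <- discount_and_sum(pay1, no_interv(discount_rate = 0.035))
  expect_true(all(totr$qaly < tot0$qaly))
  expect_equal(discount_and_sum(pay1, no_interv(discount_rate = 0)),
               tot0)
})

test_that("the state-event definition switches inputs, not mechanics", {
  # when the two indicators coincide the two definitions give identical
  # results (no non-SH mixture, matching conditional quantities)
  pred <- pred_const(0.35)
  r_sh <- run_markov(pred, no_interv(rsh_definition = "sh"))
  r_any <- run_markov(pred, no_interv(rsh_definition = "any"))
  expect_equal(r_sh$totals, r_any$totals, tolerance = 1e-12)
})

test_that("one-way toggles act as documented", {
  pred <- params_to_predictions(shift_params())
  base <- run_markov(pred, model_config())

  no_mort <- run_markov(pred, model_config(include_mortality = FALSE))
  expect_true(all(no_mort$occupancy$pi_death == 0))

  no_post <- run_markov(pred, model_config(include_post_trial_nonhosp = FALSE))
  expect_true(all(no_post$payoffs$nonhosp_cost[no_post$payoffs$cycle >= 3] == 0))
  expect_true(all(no_post$totals$cost <= base$totals$cost))

  r0 <- run_markov(pred, model_config(discount_rate = 0))
  expect_true(all(r0$totals$cost >= base$totals$cost))

  nice <- run_markov(pred, model_config(value_source = "nice"))
  expect_true(all(nice$payoffs$utility >= 0.68 - 1e-9))
})

test_that("the trial-scale fixture reproduces the published cost scale", {
  # deterministic truth path: FT costs ~GBP 1,700 more, QALY difference ~0
  res <- run_markov(params_to_predictions(shift_params()), model_config())
  r18 <- res$result[res$result$horizon == "18m", ]
  r60 <- res$result[res$result$horizon == "60m", ]
  expect_gt(r18$inc_cost, 1400)
  expect_lt(r18$inc_cost, 2000)
  expect_lt(abs(r18$inc_qaly), 0.02)
  expect_gt(r60$inc_cost, 1400)
  expect_lt(abs(r60$inc_qaly), 0.02)
  expect_true(r60$icer_label == "dominated" ||
                (is.finite(r60$icer) && abs(r60$icer) > 30000))
})
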
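test_that("QALY area under the curve matches trapezoid arithmetic", {
  expect_equal(qaly_auc(c(1, 1, 1, 1)), 1.5)
  expect_equal(qaly_auc(rep(0.8, 4)), 1.2)
  # observed TAU utility means carried forward from baseline
  expect_equal(qaly_auc(c(0.7536, 0.7536, 0.7835, 0.8097)),
               0.5 * ((0.7536 + 0.7536) / 2 + (0.7536 + 0.7835) / 2 +
                        (0.7835 + 0.8097) / 2))
  expect_equal(qaly_auc(c(0.7536, 0.7536, 0.7835, 0.8097)), 1.159375)
  expect_error(qaly_auc(c(1, NA, 1, 1)), "impute")
  expect_error(qaly_auc(c(1, 1, 1), c(0, 6, 6)), "increasing")
})

test_that("ICER labels dominance correctly", {
  expect_equal(icer(1693, -0.010)$label, "dominated")
  expect_equal(icer(-100, 0.01)$label, "dominant")
  ratio <- icer(1000, 0.05)
  expect_equal(ratio$label, "ratio")
  expect_equal(ratio$value, 20000)
  und <- icer(500, 0)
  expect_equal(und$label, "undefined")
  expect_equal(und$value, Inf)
  expect_equal(icer(-500, 0)$value, -Inf)
})

test_that("net benefit arithmetic and the INMB/INHB identity hold", {
  expect_equal(inhb(0, 0, 30000), 0)
  expect_equal(inhb(1693, -0.010, 30000), -0.010 - 1693 / 30000)
  expect_equal(round(inhb(1693, -0.010, 30000), 4), -0.0664)
  expect_equal(round(inhb(1349.68, -0.002, 30000), 4), -0.047)
  expect_error(inhb(1, 1, 0), "> 0")

  set.seed(3)
  for (i in 1:25) {
    dc <- rnorm(1, 0, 2000); dq <- rnorm(1, 0, 0.05)
    l <- runif(1, 100, 50000)
    expect_equal(inmb(dc, dq, l), l * inhb(dc, dq, l), tolerance = 1e-12)
  }
})

test_that("CEAC equals brute-force draw counting", {
  draws <- tibble::tibble(inc_cost = c(1000, 1000), inc_qaly = c(0.1, -0.1))
  expect_equal(ceac(draws, 30000)$prob_ce, 0.5)

  # all dominant draws: probability 1 everywhere
  dom <- tibble::tibble(inc_cost = rep(-5, 4), inc_qaly = rep(0.1, 4))
  expect_true(all(ceac(dom)$prob_ce == 1))

  # single dominated draw: 0 across the grid
  one <- tibble::tibble(inc_cost = 1693, inc_qaly = -0.010)
  expect_true(all(ceac(one, seq(0, 50000, 500))$prob_ce == 0))

  # random cloud vs an explicit counting oracle
  set.seed(8)
  cloud <- tibble::tibble(inc_cost = rnorm(500, 500, 800),
                          inc_qaly = rnorm(500, 0, 0.05))
  grid <- seq(0, 50000, 2500)
  got <- ceac(cloud, grid)$prob_ce
  oracle <- vapply(grid, function(l) {
    sum(l * cloud$inc_qaly - cloud$inc_cost > 0) / nrow(cloud)
  }, numeric(1))
  expect_identical(got, oracle)
})

test_that("cost-effectiveness plane quadrants count correctly", {
  nw <- tibble::tibble(inc_cost = rep(10, 5), inc_qaly = rep(-0.1, 5))
  q <- ce_plane(nw)$quadrants
  expect_equal(q$prop[q$quadrant == "NW"], 1)

  set.seed(12)
  sym <- tibble::tibble(inc_cost = rnorm(4000), inc_qaly = rnorm(4000))
  qs <- ce_plane(sym)$quadrants
  expect_true(all(abs(qs$prop - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))
  expect_equal(sum(qs$n), 4000)
})

test_that("degenerate PSA reproduces the deterministic result exactly", {
  d <- quick_trial(n = 120, seed = 51, params = flat_params(n_cycles = 4))
  suite <- fit_suite(d, prune = FALSE)
  for (nm in names(suite$models)) {
    v <- suite$models[[nm]]$vcov
    suite$models[[nm]]$vcov <- v * 0
  }
  cfg <- model_config(horizon_cycles = 4)
  draws <- psa_run(suite, cfg, n_sims = 25, seed = 99)
  det <- attr(draws, "deterministic")
  det60 <- det[det$horizon == "60m", ]
  expect_equal(draws$inc_cost, rep(det60$inc_cost, 25), tolerance = 1e-12)
  expect_equal(draws$inc_qaly, rep(det60$inc_qaly, 25), tolerance = 1e-12)
  # and the deterministic attribute equals the engine run
  eng <- run_markov(suite, cfg)
  expect_equal(det, eng$result, tolerance = 1e-9)
})

test_that("PSA draws are seed-reproducible and extendable", {
  d <- quick_trial(n = 100, seed = 53, params = flat_params(n_cycles = 4))
  suite <- fit_suite(d, prune = FALSE)
  cfg <- model_config(horizon_cycles = 4)
  a <- psa_run(suite, cfg, n_sims = 10, seed = 7)
  b <- psa_run(suite, cfg, n_sims = 10, seed = 7)
  expect_equal(a$inc_cost, b$inc_cost)
  # adding draws never changes earlier draws
  c30 <- psa_run(suite, cfg, n_sims = 30, seed = 7)
  expect_equal(c30$inc_cost[1:10], a$inc_cost)
  expect_equal(c30$inc_qaly[1:10], a$inc_qaly)
})

test_that("NICE-mode PSA centres on the deterministic NICE result", {
  d <- quick_trial(n = 150, seed = 57, params = flat_params(n_cycles = 4))
  suite <- fit_suite(d, prune = FALSE)
  # freeze the regression coefficients so only the Beta/Gamma value draws
  # vary; the increments are linear in those, so their means are the
  # published point values and the cloud centres on the deterministic run
  for (nm in names(suite$models)) {
    suite$models[[nm]]$vcov <- suite$models[[nm]]$vcov * 0
  }
  cfg <- model_config(horizon_cycles = 4, value_source = "nice")
  draws <- psa_run(suite, cfg, n_sims = 400, seed = 17)
  det <- attr(draws, "deterministic")
  det60 <- det[det$horizon == "60m", ]
  # Beta/Gamma draw means equal the point values, so the PSA cloud centres
  # on the deterministic increments within Monte-Carlo error
  expect_lt(abs(mean(draws$inc_cost) - det60$inc_cost),
            4 * sd(draws$inc_cost) / sqrt(400))
  expect_lt(abs(mean(draws$inc_qaly) - det60$inc_qaly),
            4 * sd(draws$inc_qaly) / sqrt(400))
})

test_that("plot helpers return ggplot objects", {
  draws <- tibble::tibble(inc_cost = rnorm(50), inc_qaly = rnorm(50, 0, 0.01))
  expect_s3_class(plot_ce_plane(draws), "ggplot")
  expect_s3_class(plot_ceac(ceac(draws)), "ggplot")
})
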
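# The GEE fitter is checked against independent routes: closed-form MLEs,
# glm()/lm() on stacked data (equal under independence working correlation),
# and sandwich::vcovCL for the cluster-robust covariance.

test_that("intercept-only fits match closed-form estimates", {
  d <- data.frame(id = 1:100, y = rep(c(1, 0), c(43, 57)))
  fit <- fit_gee(y ~ 1, d, id = "id", family = "binomial")
  expect_equal(unname(coef(fit)), qlogis(0.43), tolerance = 1e-7)

  dg <- data.frame(id = 1:20, y = rep(7.5, 20))
  fitg <- fit_gee(y ~ 1, dg, id = "id", family = "gamma")
  expect_equal(unname(coef(fitg)), log(7.5), tolerance = 1e-7)
})

test_that("independence working correlation reproduces GLM and OLS", {
  d <- quick_trial(n = 120, seed = 7)$cycles
  d$cycle_f <- factor(d$cycle)

  f <- sh_hosp ~ female + age_15_17 + cycle_f + arm:cycle_f
  fit <- fit_gee(f, d, id = "id", family = "binomial")
  ref <- glm(f, data = d, family = binomial())
  expect_equal(coef(fit)[names(coef(ref))], coef(ref), tolerance = 1e-6)

  # gaussian-identity: coefficients equal OLS on the stacked data
  du <- d[!is.na(d$utility), ]
  fu <- utility ~ sh_hosp + female + cycle_f
  fitu <- fit_gee(fu, du, id = "id", family = "gaussian")
  refu <- lm(fu, data = du)
  expect_equal(coef(fitu)[names(coef(refu))], coef(refu), tolerance = 1e-8)

  # gamma-log on conditional costs
  dc <- d[d$sh_hosp == 1, ]
  fc <- sh_hosp_cost ~ female + cycle_f
  fitc <- fit_gee(fc, dc, id = "id", family = "gamma")
  refc <- glm(fc, data = dc, family = Gamma(link = "log"),
              control = glm.control(epsilon = 1e-12))
  expect_equal(coef(fitc)[names(coef(refc))], coef(refc), tolerance = 1e-6)
})

test_that("robust covariance matches the clustered sandwich estimator", {
  skip_if_not_installed("sandwich")
  d <- quick_trial(n = 100, seed = 13)$cycles
  d$cycle_f <- factor(d$cycle)
  f <- sh_hosp ~ female + cycle_f
  fit <- fit_gee(f, d, id = "id", family = "binomial")
  ref <- glm(f, data = d, family = binomial())
  vc_ref <- sandwich::vcovCL(ref, cluster = d$id, type = "HC0",
                             cadjust = FALSE)
  expect_equal(fit$vcov[rownames(vc_ref), colnames(vc_ref)],
               vc_ref, tolerance = 1e-5)
})

test_that("sandwich covariance is invariant to cluster ordering", {
  d <- quick_trial(n = 80, seed = 17)$cycles
  d$cycle_f <- factor(d$cycle)
  f <- sh_hosp ~ female + cycle_f
  fit1 <- fit_gee(f, d, id = "id", family = "binomial")
  perm <- withr::with_seed(1, sample(nrow(d)))
  fit2 <- fit_gee(f, d[perm, ], id = "id", family = "binomial")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-9)
  expect_equal(fit1$vcov, fit2$vcov, tolerance = 1e-9)
})

test_that("exchangeable working correlation estimates a sane structure", {
  # strongly clustered binary panel
  set.seed(5)
  n <- 300
  re <- rnorm(n, sd = 1.5)
  d <- expand.grid(id = 1:n, cycle = 0:3)
  d$y <- rbinom(nrow(d), 1, plogis(-0.5 + re[d$id]))
  fit <- fit_gee(y ~ 1, d, id = "id", family = "binomial",
                 corstr = "exchangeable")
  expect_gt(fit$alpha, 0.1)
  expect_lt(fit$alpha, 0.9)
  # intercept-only estimating equations still centre near the marginal rate
  expect_equal(plogis(unname(coef(fit))), mean(d$y), tolerance = 0.05)
})

test_that("coefficient recovery is unbiased at trial scale", {
  p_ft <- c(0.45, 0.30, 0.20)
  p_tau <- c(0.50, 0.25, 0.22)
  reps <- 30
  est <- matrix(NA_real_, reps, 6)
  for (r in seq_len(reps)) {
    d <- sim_logit_panel(400, 3, p_ft, p_tau, seed = 100 + r)
    fit <- fit_gee(y ~ cycle_f + arm:cycle_f, d, id = "id",
                   family = "binomial")
    nd <- expand.grid(arm = factor(c("TAU", "FT"), levels = c("TAU", "FT")),
                      cycle_f = factor(0:2))
    est[r, ] <- predict(fit, nd)
  }
  truth <- c(rbind(p_tau, p_ft))
  bias <- colMeans(est) - truth
  mcse <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) < pmax(3 * mcse, 0.02)))
})

test_that("pruning merges non-significant interactions", {
  # identical arms: every arm-by-cycle interaction should be pruned
  d <- sim_logit_panel(300, 3, c(0.4, 0.3, 0.2), c(0.4, 0.3, 0.2), seed = 9)
  fit <- fit_gee(y ~ cycle_f + arm:cycle_f, d, id = "id", family = "binomial")
  red <- prune_interactions(fit, d, alpha = 0.05)
  expect_false(any(grepl(":", names(coef(red)))))
  # the reduced model carries one arm-invariant trajectory
  nd <- expand.grid(arm = factor(c("TAU", "FT"), levels = c("TAU", "FT")),
                    cycle_f = factor(0:2))
  pr <- matrix(predict(red, nd), nrow = 2)
  expect_equal(pr[1, ], pr[2, ], tolerance = 1e-10)

  # arm effect at cycle 0 only: exactly that interaction survives
  d2 <- sim_logit_panel(2000, 3, c(0.25, 0.30, 0.20), c(0.50, 0.30, 0.20),
                        seed = 10)
  fit2 <- fit_gee(y ~ cycle_f + arm:cycle_f, d2, id = "id",
                  family = "binomial")
  red2 <- prune_interactions(fit2, d2, alpha = 0.05)
  kept <- grep(":", names(coef(red2)), value = TRUE)
  expect_equal(kept, "cycle_f0:armFT")
})

test_that("degenerate inputs fail loudly", {
  d <- data.frame(id = 1:10, y = c(rep(0, 5), rep(2, 5)))
  expect_error(fit_gee(y ~ 1, d, id = "id", family = "binomial"), "0/1")
  expect_error(fit_gee(y ~ 1, data.frame(id = rep(1, 5), y = rnorm(5)),
                       id = "id", family = "gaussian"), "clusters")
  dneg <- data.frame(id = 1:10, y = c(rep(1, 9), -1))
  expect_error(fit_gee(y ~ 1, dneg, id = "id", family = "gamma"), "positive")
})
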
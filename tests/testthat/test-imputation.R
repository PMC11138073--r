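test_that("PMM with no missing values is the identity", {
  df <- data.frame(x = 1:6, y = c(2, 4, 6, 8, 10, 12))
  expect_identical(pmm_impute_variable(df, "y", "x"), df)
})

test_that("PMM draws the nearest-prediction donor (brute-force oracle)", {
  # 6-row table, one missing value, k = 1, no coefficient perturbation
  df <- data.frame(x = c(1, 2, 3, 4, 5, 6),
                   y = c(10, 21, 29, 41, 50, NA))
  out <- pmm_impute_variable(df, "y", "x", k = 1, perturb = FALSE)
  # oracle: fit the line, predict all, nearest observed prediction donates
  fit <- lm(y ~ x, df)
  pred <- predict(fit, df)
  donor <- which.min(abs(pred[1:5] - pred[6]))
  expect_equal(out$y[6], df$y[donor])

  # perturbed imputation still returns an observed donor value
  set.seed(2)
  out2 <- pmm_impute_variable(df, "y", "x", k = 2)
  expect_true(out2$y[6] %in% df$y[1:5])
})

test_that("PMM never leaves the observed support: utilities < 1, costs >= 0", {
  d <- quick_trial(n = 200, seed = 4,
                   params = flat_params(dropout = c(0.3, 0.15, 0.1),
                                        censor_never = FALSE),
                   missingness = TRUE)
  imps <- multiple_impute(d, imputation_spec(M = 3, seed = 7))
  for (imp in imps) {
    tw <- imp$cycles[imp$cycles$cycle < 3, ]
    expect_false(anyNA(tw$utility))
    expect_false(anyNA(tw$nonhosp_cost))
    expect_false(anyNA(tw$sh_hosp))
    expect_true(all(tw$utility < 1))
    expect_true(all(tw$utility >= -0.594))
    expect_true(all(tw$nonhosp_cost >= 0))
    expect_true(all(tw$sh_hosp_cost >= 0))
    # conditional-cost convention survives imputation
    expect_true(all((tw$sh_hosp_cost > 0) == (tw$sh_hosp == 1)))
    expect_true(all((tw$nonhosp_cost > 0) == (tw$nonhosp_occ == 1)))
  }
})

test_that("multiple imputation of a complete dataset returns identical copies", {
  d <- quick_trial(n = 40, seed = 3)
  imps <- multiple_impute(d, imputation_spec(M = 2, seed = 1))
  expect_length(imps, 2)
  expect_equal(imps[[1]]$cycles, imps[[2]]$cycles)
  expect_equal(as.data.frame(imps[[1]]$cycles[order(imps[[1]]$cycles$id,
                                                    imps[[1]]$cycles$cycle), ]),
               as.data.frame(d$cycles[order(d$cycles$id, d$cycles$cycle), ]))
})

test_that("imputed utilities recover the generating mean (congeniality)", {
  params <- flat_params(n_cycles = 3, dropout = c(0.35, 0.1, 0.05))
  d <- quick_trial(n = 400, seed = 8, params = params, missingness = TRUE)
  imps <- multiple_impute(d, imputation_spec(M = 20, seed = 9))
  truth <- mean(quick_trial(n = 400, seed = 8, params = params)$cycles$utility)
  means <- vapply(imps, function(x) mean(x$cycles$utility), numeric(1))
  # pooled mean within Monte-Carlo error of the complete-data mean
  expect_lt(abs(mean(means) - truth), 0.02)
})

test_that("too few donors is an informative error", {
  df <- data.frame(x = 1:6, y = c(1, NA, NA, NA, NA, NA))
  expect_error(pmm_impute_variable(df, "y", "x", k = 5), "y")
  expect_error(pmm_impute_variable(df, "y", "x", k = 5), "donors")
})

test_that("Rubin's rules reproduce hand arithmetic and the variance identity", {
  # estimates {1, 3}, variances {1, 1}: point 2, between 2, total 4
  p <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$between, 2)
  expect_equal(p$within, 1)
  expect_equal(p$total, 1 + 1.5 * 2)

  # identical estimates: between 0, total = within, infinite df
  p0 <- rubin_pool(rep(2.5, 10), rep(0.3, 10))
  expect_equal(p0$between, 0)
  expect_equal(p0$total, 0.3)
  expect_equal(p0$df, Inf)

  # pooling identity holds for arbitrary inputs
  set.seed(11)
  for (i in 1:20) {
    M <- sample(2:30, 1)
    est <- rnorm(M)
    v <- rexp(M)
    pp <- rubin_pool(est, v)
    expect_equal(pp$total, pp$within + (1 + 1 / M) * pp$between)
    expect_gte(pp$total, pp$within)
  }

  expect_error(rubin_pool(1, 1), "M >= 2")
})

test_that("pooled utility difference covers the generating arm effect", {
  # fixture with a true between-arm utility difference at cycle 0
  params <- flat_params(n_cycles = 3, dropout = c(0.3, 0.1, 0))
  reps <- 30
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    d <- quick_trial(n = 150, seed = 300 + r, params = params,
                     missingness = TRUE)
    # inject a known arm effect of 0.043 on utilities before dropout is
    # re-applied: shift FT utilities
    d$cycles$utility[d$cycles$arm == "FT"] <-
      pmin(d$cycles$utility[d$cycles$arm == "FT"] + 0.043, 1)
    imps <- multiple_impute(d, imputation_spec(M = 10, seed = 400 + r))
    ests <- vapply(imps, function(x) {
      u0 <- x$cycles[x$cycles$cycle == 0, ]
      diff(tapply(u0$utility, u0$arm, mean))
    }, numeric(1))
    vars <- vapply(imps, function(x) {
      u0 <- x$cycles[x$cycles$cycle == 0, ]
      sum(tapply(u0$utility, u0$arm, var) / tapply(u0$utility, u0$arm, length))
    }, numeric(1))
    p <- rubin_pool(ests, vars)
    covered[r] <- p$conf.low <= 0.043 && 0.043 <= p$conf.high
  }
  expect_gte(mean(covered), 0.85)
})
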
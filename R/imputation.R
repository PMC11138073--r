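# Multiple imputation by predictive mean matching (PMM) under monotone
# missingness, with Rubin's-rules pooling. Trial-collected fields (utilities
# and self-reported non-hospital costs) and the few censored hospital fields
# within the trial window are imputed; post-trial censored cycles stay absent
# and are accommodated by the unbalanced-panel GEE fits (censoring, not
# imputation, handles differential hospital-record follow-up).

#' Imputation specification
#'
#' @param M Number of imputations (default 100).
#' @param donor_pool_k Donor pool size for PMM (default 5).
#' @param seed Integer seed; per-imputation sub-streams are derived from it.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(M = 100, donor_pool_k = 5, seed = 1L) {
  assert_count(M, "M", min = 2L)
  assert_count(donor_pool_k, "donor_pool_k", min = 1L)
  structure(list(M = as.integer(M), donor_pool_k = as.integer(donor_pool_k),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Impute one variable by predictive mean matching
#'
#' Fits a linear model of the target on the (complete) predictors over the
#' observed cases, perturbs the coefficients with a draw from their estimated
#' sampling distribution, and replaces each missing value with the observed
#' value of a donor drawn uniformly from the `k` observed cases whose
#' predicted means are nearest the missing case's prediction. Imputed values
#' therefore never leave the observed support: utilities stay below 1 and
#' costs stay non-negative by construction.
#'
#' @param df Data frame (one row per unit).
#' @param target Name of the variable to impute.
#' @param predictors Character vector of complete predictor columns.
#' @param k Donor pool size.
#' @param perturb Draw the prediction coefficients from their asymptotic
#'   normal distribution ("proper" imputation)? Set `FALSE` for a
#'   deterministic nearest-donor prediction (useful for validation).
#' @param obs_subset,mis_subset Optional logical vectors restricting the
#'   donor pool and the cases to fill (used for costs conditional on an
#'   event indicator).
#' @return `df` with the target filled in.
#' @export
pmm_impute_variable <- function(df, target, predictors, k = 5,
                                perturb = TRUE,
                                obs_subset = NULL, mis_subset = NULL) {
  y <- df[[target]]
  obs <- !is.na(y)
  if (!is.null(obs_subset)) obs <- obs & obs_subset
  mis <- is.na(y)
  if (!is.null(mis_subset)) mis <- mis & mis_subset
  if (!any(mis)) return(df)
  if (sum(obs) < k) {
    stop(sprintf("too few observed donors (%d < k = %d) for variable '%s'",
                 sum(obs), k, target), call. = FALSE)
  }
  X <- model.matrix(~., data = df[predictors])
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  bhat <- fit$coefficients[keep]
  bstar <- bhat
  if (perturb) {
    dfres <- max(sum(obs) - sum(keep), 1)
    s2 <- sum(fit$residuals^2) / dfres
    R <- qr.R(qr(X[obs, keep, drop = FALSE]))
    Vb <- s2 * chol2inv(R)
    bstar <- drop(MASS::mvrnorm(1, bhat, (Vb + t(Vb)) / 2))
  }
  pred_obs <- drop(Xk[obs, , drop = FALSE] %*% bhat)
  pred_mis <- drop(Xk[mis, , drop = FALSE] %*% bstar)
  y_obs <- y[obs]
  fill <- vapply(pred_mis, function(pm) {
    donors <- order(abs(pred_obs - pm))[seq_len(k)]
    y_obs[donors[sample.int(k, 1)]]
  }, numeric(1))
  df[[target]][mis] <- fill
  df
}

# --- wide trial-window view ---------------------------------------------

trial_wide <- function(data) {
  ntc <- data$n_trial_cycles
  tw <- data$cycles[data$cycles$cycle < ntc,
                    c("id", "cycle", "sh_hosp", "nonsh_hosp",
                      "sh_hosp_cost", "nonsh_hosp_cost",
                      "nonhosp_cost", "utility")]
  wide <- tidyr::pivot_wider(
    tw, id_cols = "id", names_from = "cycle",
    values_from = c("sh_hosp", "nonsh_hosp", "sh_hosp_cost",
                    "nonsh_hosp_cost", "nonhosp_cost", "utility"),
    names_sep = "_"
  )
  dplyr::left_join(
    data$patients[, c("id", "arm", "female", "age_15_17",
                      "cause_poisoning", "hosp_referred")],
    wide, by = "id"
  )
}

# imputation sequence: trial-questionnaire variables by time, then hospital
# indicators by time, then the conditional hospital costs
impute_sequence <- function(ntc) {
  cyc <- seq_len(ntc) - 1L
  list(
    plain = c(paste0("utility_", cyc), paste0("nonhosp_cost_", cyc),
              paste0("sh_hosp_", cyc), paste0("nonsh_hosp_", cyc)),
    conditional = list(
      sh_cost = list(target = paste0("sh_hosp_cost_", cyc),
                     indicator = paste0("sh_hosp_", cyc)),
      nonsh_cost = list(target = paste0("nonsh_hosp_cost_", cyc),
                        indicator = paste0("nonsh_hosp_", cyc))
    )
  )
}

baseline_predictors <- c("arm", "female", "age_15_17",
                         "cause_poisoning", "hosp_referred")

impute_once <- function(wide, k) {
  seqs <- impute_sequence(sum(grepl("^utility_", names(wide))))
  done <- character(0)
  for (target in seqs$plain) {
    preds <- c(baseline_predictors, done)
    binary <- grepl("^(sh_hosp|nonsh_hosp)_", target)
    wide <- pmm_impute_variable(wide, target, preds, k = k)
    if (binary) wide[[target]] <- as.integer(round(wide[[target]]))
    done <- c(done, target)
  }
  for (cond in seqs$conditional) {
    for (j in seq_along(cond$target)) {
      tgt <- cond$target[j]
      ind <- wide[[cond$indicator[j]]]
      # conditional-cost convention: cost present iff the event occurred
      wide[[tgt]][ind == 0] <- 0
      need <- ind == 1 & is.na(wide[[tgt]])
      if (any(need)) {
        wide <- pmm_impute_variable(
          wide, tgt, c(baseline_predictors, done), k = k,
          obs_subset = ind == 1 & wide[[tgt]] > 0, mis_subset = need
        )
      }
      done <- c(done, tgt)
    }
  }
  wide
}

wide_to_trial <- function(wide, data) {
  ntc <- data$n_trial_cycles
  long <- tidyr::pivot_longer(
    wide,
    cols = -dplyr::all_of(c("id", baseline_predictors)),
    names_to = c(".value", "cycle"),
    names_pattern = "^(.*)_(\\d+)$"
  )
  long$cycle <- as.integer(long$cycle)
  long$nonhosp_occ <- as.integer(long$nonhosp_cost > 0)
  long <- long[, names(data$cycles)]
  post <- data$cycles[data$cycles$cycle >= ntc, ]
  cyc <- dplyr::arrange(dplyr::bind_rows(long, post), .data$id, .data$cycle)
  # drop resurrected trial-window rows for patients dead before the window end
  dth <- data$patients$death_cycle[match(cyc$id, data$patients$id)]
  cyc <- cyc[is.na(dth) | cyc$cycle < dth, ]
  out <- data
  out$cycles <- cyc
  out
}

#' Check monotone missingness of the trial-collected fields
#'
#' Scans each patient's trial-window cycles: once a field is missing it must
#' stay missing.
#'
#' @param data A `trial_data`.
#' @return `TRUE` (invisibly) if monotone; otherwise the number of violating
#'   patient-field pairs, with a warning.
#' @export
check_monotone <- function(data) {
  ntc <- data$n_trial_cycles
  tw <- data$cycles[data$cycles$cycle < ntc, ]
  viol <- 0L
  for (f in c("utility", "nonhosp_cost", "sh_hosp")) {
    v <- tapply(is.na(tw[[f]])[order(tw$id, tw$cycle)],
                tw$id[order(tw$id, tw$cycle)],
                function(m) any(diff(m) < 0))
    viol <- viol + sum(unlist(v), na.rm = TRUE)
  }
  if (viol > 0) {
    warning(sprintf("missingness is not monotone for %d patient-field pairs; %s",
                    viol, "imputing in the declared ordering regardless"))
    return(viol)
  }
  invisible(TRUE)
}

#' Multiply impute a trial dataset
#'
#' Sequential PMM in the monotone ordering (questionnaire utilities and
#' non-hospital costs by time, then hospital indicators by time, then the
#' event-conditional hospital costs), repeated `M` times with independent
#' seeded sub-streams. Post-trial censored cycles are not imputed.
#'
#' @param data A `trial_data` with missing values.
#' @param spec An [imputation_spec()].
#' @return A list of `M` completed `trial_data` objects (class
#'   `trial_imputations`).
#' @export
multiple_impute <- function(data, spec = imputation_spec()) {
  stopifnot(inherits(data, "trial_data"), inherits(spec, "imputation_spec"))
  check_monotone(data)
  wide <- trial_wide(data)
  seeds <- sub_seeds(spec$seed, spec$M)
  out <- lapply(seq_len(spec$M), function(m) {
    set.seed(seeds[m])
    wide_to_trial(impute_once(wide, k = spec$donor_pool_k), data)
  })
  structure(out, class = c("trial_imputations", "list"), M = spec$M)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation (squared-SE) variances.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `pooled_estimate`: `estimate`, `within`,
#'   `between`, `total` (= within + (1 + 1/M) between), `df`
#'   (Rubin's Satterthwaite-type degrees of freedom), `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `m`.
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  M <- length(estimates)
  if (M < 2) stop("Rubin pooling requires M >= 2 estimates", call. = FALSE)
  stopifnot(length(variances) == M, all(variances >= 0))
  point <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / M) * between
  df <- if (between > 0) {
    (M - 1) * (1 + within / ((1 + 1 / M) * between))^2
  } else {
    Inf
  }
  se <- sqrt(total)
  tq <- qt(1 - (1 - conf_level) / 2, df)
  p <- if (se > 0) 2 * stats::pt(-abs(point / se), df) else as.numeric(point == 0)
  structure(
    list(estimate = point, within = within, between = between, total = total,
         df = df, std.error = se,
         conf.low = point - tq * se, conf.high = point + tq * se,
         p.value = p, m = M),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (SE %.4g, 95%% CI %.4g to %.4g, p = %.3g, M = %d)\n",
              x$estimate, x$std.error, x$conf.low, x$conf.high, x$p.value, x$m))
  invisible(x)
}

# Rubin pooling of full coefficient vectors: pooled coefficients and total
# covariance W + (1 + 1/M) B, with B the between-imputation covariance.
rubin_pool_matrix <- function(coefs, vcovs) {
  M <- length(coefs)
  common <- Reduce(intersect, lapply(coefs, names))
  coefs <- lapply(coefs, function(b) b[common])
  vcovs <- lapply(vcovs, function(v) v[common, common, drop = FALSE])
  B <- do.call(rbind, coefs)
  point <- colMeans(B)
  W <- Reduce(`+`, vcovs) / M
  Bv <- stats::cov(B)
  total <- W + (1 + 1 / M) * Bv
  list(coefficients = point, vcov = (total + t(total)) / 2, m = M)
}
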
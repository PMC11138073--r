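# Generalized estimating equations with cluster-robust (sandwich) covariance.
# Families: binomial-logit, gamma-log, gaussian-identity (canonical links for
# the probability, conditional-cost and utility models). Working correlation:
# independence (default; point estimates then coincide with GLM/OLS on the
# stacked data) or exchangeable.

gee_family <- function(name) {
  switch(name,
    binomial = list(
      linkinv = plogis,
      linkfun = qlogis,
      mu.eta = function(eta) { p <- plogis(eta); p * (1 - p) },
      variance = function(mu) mu * (1 - mu),
      fixed_phi = TRUE
    ),
    gamma = list(
      linkinv = exp,
      linkfun = log,
      mu.eta = exp,
      variance = function(mu) mu^2,
      fixed_phi = FALSE
    ),
    gaussian = list(
      linkinv = identity,
      linkfun = identity,
      mu.eta = function(eta) rep(1, length(eta)),
      variance = function(mu) rep(1, length(mu)),
      fixed_phi = FALSE
    ),
    stop(sprintf("unknown family '%s'", name), call. = FALSE)
  )
}

#' Fit a generalized estimating equation model
#'
#' Iteratively-reweighted estimating-equation solution with a cluster-robust
#' sandwich covariance. With independence working correlation the point
#' estimates equal those of the corresponding GLM fitted to the stacked data
#' (and, for the gaussian-identity family, ordinary least squares).
#'
#' @param formula Model formula.
#' @param data Data frame; rows with missing outcome or covariates are
#'   dropped.
#' @param id Name of the cluster (patient) identifier column.
#' @param family `"binomial"` (logit link), `"gamma"` (log link) or
#'   `"gaussian"` (identity link).
#' @param corstr Working correlation: `"independence"` or `"exchangeable"`.
#' @param drop_cols Design-matrix columns to remove after construction
#'   (used to merge pruned interaction blocks into shared coefficients).
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param max_iter Maximum number of scoring iterations.
#' @return An object of class `gee_fit` with components `coefficients`,
#'   `vcov` (robust), `naive_vcov`, `phi`, `alpha`, `n`, `n_clusters`,
#'   `converged`, plus the terms metadata needed by [predict.gee_fit()].
#' @export
fit_gee <- function(formula, data, id = "id",
                    family = c("binomial", "gamma", "gaussian"),
                    corstr = c("independence", "exchangeable"),
                    drop_cols = character(), tol = 1e-8, max_iter = 100L) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  fam <- gee_family(family)
  stopifnot(id %in% names(data))

  mf <- model.frame(formula, data = data, na.action = na.pass)
  tt <- terms(mf)
  y <- model.response(mf)
  X <- model.matrix(tt, mf)
  idv <- data[[id]]
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- as.numeric(y[ok])
  idv <- idv[ok]

  dropped <- intersect(colnames(X), drop_cols)
  if (length(dropped)) X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  # prune aliased columns (empty cells in saturated designs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    dropped <- c(dropped, aliased)
  }

  cl <- factor(idv, levels = unique(idv))
  n_clusters <- nlevels(cl)
  if (n_clusters < 2L) stop("at least 2 clusters are required", call. = FALSE)
  if (family == "gamma" && any(y <= 0)) {
    stop("gamma family requires strictly positive outcomes", call. = FALSE)
  }
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 outcome", call. = FALSE)
  }

  p <- ncol(X)
  n <- length(y)
  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(X)) {
    mu0 <- mean(y)
    if (family == "binomial") mu0 <- min(max(mu0, 1e-6), 1 - 1e-6)
    beta[match("(Intercept)", colnames(X))] <- fam$linkfun(mu0)
  }

  csize <- as.integer(table(cl))
  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    if (family == "binomial") mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    d <- fam$mu.eta(eta)
    v <- fam$variance(mu)
    if (family == "binomial") v <- pmax(v, 1e-12)
    u <- sqrt(v)
    G <- X * (d / u)              # A^{-1/2} D, row-wise
    rstar <- (y - mu) / u         # Pearson residuals

    if (!fam$fixed_phi) {
      phi <- sum(rstar^2) / max(n - p, 1)
    }
    if (corstr == "exchangeable") {
      S1 <- rowsum(rstar, cl, reorder = FALSE)[, 1]
      Q1 <- rowsum(rstar^2, cl, reorder = FALSE)[, 1]
      denom <- sum(csize * (csize - 1))
      alpha <- if (denom > 0) sum(S1^2 - Q1) / (phi * max(denom - p, 1)) else 0
      amin <- -1 / (max(csize) - 1) + 1e-6
      alpha <- min(max(alpha, max(amin, -0.99)), 0.99)
    }

    if (corstr == "independence" || alpha == 0) {
      A <- crossprod(G)
      b <- crossprod(G, rstar)
    } else {
      CG <- rowsum(G, cl, reorder = FALSE)
      Cr <- rowsum(rstar, cl, reorder = FALSE)[, 1]
      ci <- alpha / ((1 - alpha) * (1 - alpha + csize * alpha))
      A <- crossprod(G) / (1 - alpha) - crossprod(CG * sqrt(ci))
      b <- crossprod(G, rstar) / (1 - alpha) - crossprod(CG, ci * Cr)
    }
    delta <- tryCatch(solve(A, b), error = identity)
    if (inherits(delta, "error")) {
      dA <- diag(A)
      bad <- colnames(X)[dA < max(dA) * 1e-9 | abs(beta) > 10]
      stop(gee_singular_condition(bad, family))
    }
    beta <- beta + drop(delta)
    if (max(abs(delta) / (abs(beta) + 1)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("GEE did not converge after %d iterations (max relative change %.3g)",
                 max_iter, max(abs(delta) / (abs(beta) + 1))), call. = FALSE)
  }
  if (family == "binomial" && max(abs(beta)) > 30) {
    stop(gee_singular_condition(colnames(X)[abs(beta) > 30], family))
  }

  # robust sandwich covariance at the solution
  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  if (family == "binomial") mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  d <- fam$mu.eta(eta)
  v <- fam$variance(mu)
  if (family == "binomial") v <- pmax(v, 1e-12)
  u <- sqrt(v)
  G <- X * (d / u)
  rstar <- (y - mu) / u
  if (!fam$fixed_phi) phi <- sum(rstar^2) / max(n - p, 1)
  if (corstr == "independence" || alpha == 0) {
    A <- crossprod(G)
    S <- rowsum(G * rstar, cl, reorder = FALSE)
  } else {
    CG <- rowsum(G, cl, reorder = FALSE)
    Cr <- rowsum(rstar, cl, reorder = FALSE)[, 1]
    ci <- alpha / ((1 - alpha) * (1 - alpha + csize * alpha))
    A <- crossprod(G) / (1 - alpha) - crossprod(CG * sqrt(ci))
    S <- rowsum(G * rstar, cl, reorder = FALSE) / (1 - alpha) - CG * (ci * Cr)
  }
  Ainv <- solve(A)
  vc <- Ainv %*% crossprod(S) %*% Ainv
  vc <- (vc + t(vc)) / 2

  structure(
    list(coefficients = setNames(drop(beta), colnames(X)),
         vcov = `dimnames<-`(vc, list(colnames(X), colnames(X))),
         naive_vcov = phi * Ainv,
         phi = phi, alpha = if (corstr == "exchangeable") alpha else 0,
         family = family, corstr = corstr,
         n = n, n_clusters = n_clusters, iter = iter, converged = converged,
         dropped = dropped, id = id,
         formula = formula, terms = tt,
         xlevels = stats::.getXlevels(tt, mf),
         contrasts = attr(X, "contrasts"),
         fitted = mu),
    class = "gee_fit"
  )
}

# classed condition for separated / information-free directions so callers
# (e.g. the suite fitter) can merge the offending dummies and refit
gee_singular_condition <- function(columns, family) {
  columns <- unique(columns)
  msg <- if (family == "binomial") {
    sprintf("separation in logistic fit (diverging coefficients: %s)",
            paste(columns, collapse = ", "))
  } else {
    sprintf("singular weighted information (columns: %s)",
            paste(columns, collapse = ", "))
  }
  structure(
    class = c("qmcea_separation", "error", "condition"),
    list(message = msg, call = NULL, columns = columns)
  )
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %s (%s working correlation), %d obs in %d clusters\n",
              x$family, x$corstr, x$n, x$n_clusters))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Coefficient table with robust standard errors
#'
#' @param fit A `gee_fit`.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald z on the robust SE).
#' @export
tidy_gee <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' Predict from a GEE fit
#'
#' @param object A `gee_fit`.
#' @param newdata Data frame of covariate values.
#' @param type `"response"` (inverse-link) or `"link"`.
#' @param se.fit Also return delta-method standard errors (link scale)?
#' @param ... Unused.
#' @return Numeric vector, or a list with `fit` and `se.fit`.
#' @export
predict.gee_fit <- function(object, newdata, type = c("response", "link"),
                            se.fit = FALSE, ...) {
  type <- match.arg(type)
  X <- gee_design(object, newdata)
  eta <- drop(X %*% object$coefficients)
  out <- if (type == "response") gee_family(object$family)$linkinv(eta) else eta
  if (!se.fit) return(out)
  list(fit = out, se.fit = sqrt(rowSums((X %*% object$vcov) * X)))
}

# model matrix for new data, restricted to the fitted (non-dropped) columns
gee_design <- function(object, newdata) {
  tt <- delete.response(object$terms)
  mf <- model.frame(tt, newdata, xlev = object$xlevels, na.action = na.pass)
  X <- model.matrix(tt, mf, contrasts.arg = object$contrasts)
  miss <- setdiff(names(object$coefficients), colnames(X))
  if (length(miss)) {
    stop(sprintf("newdata lacks design columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  X[, names(object$coefficients), drop = FALSE]
}

#' Prune non-significant interaction (and optionally time) dummies
#'
#' Wald tests each arm-by-cycle interaction coefficient (robust SE) and
#' refits with the non-significant ones merged into the shared trajectory;
#' repeats until no further term is dropped. With `prune_time = TRUE` the
#' cycle main-effect dummies are candidates too (for outcomes found constant
#' over time, e.g. conditional non-hospital costs and utilities). Hospital
#' cost models retain all interactions by simply not being pruned.
#'
#' @param fit A saturated `gee_fit`.
#' @param data The data used to fit it (needed to refit).
#' @param alpha Significance level for the Wald tests (default 0.05).
#' @param prune_time Also consider cycle main-effect dummies.
#' @param time_var Name of the cycle factor (default `"cycle_f"`; the trial
#'   window models use `"cycle_tf"`).
#' @return A reduced `gee_fit` (possibly the input if nothing is dropped).
#' @export
prune_interactions <- function(fit, data, alpha = 0.05, prune_time = FALSE,
                               time_var = "cycle_f") {
  stopifnot(inherits(fit, "gee_fit"))
  drop_cols <- setdiff(fit$dropped, character(0))
  repeat {
    cand <- prunable_terms(fit, prune_time, time_var)
    if (!length(cand)) break
    se <- sqrt(diag(fit$vcov)[cand])
    pv <- 2 * pnorm(-abs(fit$coefficients[cand] / se))
    worst <- cand[pv >= alpha]
    if (!length(worst)) break
    drop_cols <- union(drop_cols, worst)
    fit <- fit_gee(fit$formula, data, id = fit$id, family = fit$family,
                   corstr = fit$corstr, drop_cols = drop_cols)
  }
  fit
}

prunable_terms <- function(fit, prune_time, time_var) {
  nm <- names(fit$coefficients)
  cand <- nm[grepl(":", nm, fixed = TRUE)]
  if (prune_time) {
    cand <- c(cand, nm[startsWith(nm, time_var) & !grepl(":", nm, fixed = TRUE)])
  }
  cand
}

# single-pass Wald drop-set decision (used for pooled multiple-imputation
# fits, where iterative refitting happens per imputed dataset afterwards)
wald_drop_set <- function(fit, alpha = 0.05, prune_time = FALSE,
                          time_var = "cycle_f") {
  cand <- prunable_terms(fit, prune_time, time_var)
  if (!length(cand)) return(character(0))
  se <- sqrt(diag(fit$vcov)[cand])
  pv <- 2 * pnorm(-abs(fit$coefficients[cand] / se))
  cand[pv >= alpha]
}
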
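#' Log density of the composed frontier error
#'
#' Density of `eps = v - u` where `v ~ N(0, sigma_v2)` is symmetric noise and
#' `u >= 0` is inefficiency (the downward displacement of a stand from the
#' self-thinning boundary). Three one-sided laws are supported:
#' half-normal (`"NH"`), exponential (`"NE"`, scale `sqrt(sigma_u2)`), and
#' truncated normal (`"NT"`, pre-truncation mean `mu`; reduces to NH at
#' `mu = 0`). Closed forms are the classical normal-half-normal,
#' normal-exponential and Stevenson truncated-normal frontier densities. All
#' three are left-skewed: mass is pulled below the frontier.
#'
#' @param eps numeric vector of composed errors.
#' @param dist `"NH"`, `"NE"` or `"NT"`.
#' @param sigma_v2 two-sided variance (> 0).
#' @param sigma_u2 one-sided variance parameter (>= 0; for NE the squared
#'   exponential scale).
#' @param mu pre-truncation mean (NT only).
#' @return log density values, same length as `eps`.
#' @export
composed_error_logdensity <- function(eps, dist = c("NH", "NE", "NT"),
                                      sigma_v2, sigma_u2, mu = 0) {
  dist <- match.arg(dist)
  if (sigma_v2 <= 0) stopf("sigma_v2 must be positive")
  if (sigma_u2 < 0) stopf("sigma_u2 must be non-negative")
  sv <- sqrt(sigma_v2)
  if (sigma_u2 == 0) return(stats::dnorm(eps, 0, sv, log = TRUE))
  su <- sqrt(sigma_u2)
  switch(dist,
    NH = {
      s <- sqrt(sigma_v2 + sigma_u2); lam <- su / sv
      log(2) - log(s) + stats::dnorm(eps / s, log = TRUE) +
        stats::pnorm(-eps * lam / s, log.p = TRUE)
    },
    NE = {
      -log(su) + eps / su + sigma_v2 / (2 * sigma_u2) +
        stats::pnorm(-eps / sv - sv / su, log.p = TRUE)
    },
    NT = {
      s <- sqrt(sigma_v2 + sigma_u2); lam <- su / sv
      -log(s) + stats::dnorm((eps + mu) / s, log = TRUE) +
        stats::pnorm(mu / (s * lam) - eps * lam / s, log.p = TRUE) -
        stats::pnorm(mu / su, log.p = TRUE)
    }
  )
}

# moment-based (corrected OLS) starting values for the frontier likelihood
sfa_start <- function(b_ols, res, dist) {
  m2 <- mean(res^2); m3 <- mean(res^3)
  if (dist %in% c("NH", "NT")) {
    su3 <- m3 / (sqrt(2 / pi) * (1 - 4 / pi))  # (1 - 4/pi) < 0, m3 < 0 expected
    su <- if (su3 > 0) su3^(1 / 3) else 0.5 * sqrt(m2)
    sv2 <- max(m2 - (1 - 2 / pi) * su^2, 0.1 * m2)
    shift <- sqrt(2 / pi) * su
  } else {
    su <- if (m3 < 0) (-m3 / 2)^(1 / 3) else 0.5 * sqrt(m2)
    sv2 <- max(m2 - su^2, 0.1 * m2)
    shift <- su
  }
  b <- b_ols
  b[1] <- b[1] + shift  # the frontier sits E[u] above the mean line
  c(b, log(sv2), log(max(su^2, 1e-4 * m2)), if (dist == "NT") 0)
}

#' Maximum-likelihood stochastic frontier fit
#'
#' Fits the upper boundary `ln N = X b + v - u` by maximizing the composed
#' error likelihood, so the frontier lies above the data cloud and `u >= 0`
#' measures each stand's shortfall from maximum density. Optimization runs in
#' log-variance space from corrected-OLS starting values plus jittered
#' multi-starts; standard errors come from the observed information at the
#' optimum (delta method for the variance parameters).
#'
#' @param X design matrix with intercept column, e.g. [design_matrix()].
#' @param y log stand density.
#' @param dist composed-error law: `"NH"`, `"NE"` or `"NT"`.
#' @param starts optional list of extra full-length start vectors
#'   `c(b, log sigma_v2, log sigma_u2[, mu])`.
#' @param n_starts jittered multi-starts around the moment start (default 5).
#' @param seed seed for the start jitter.
#' @param se_method `"profile"` (default): frontier-coefficient standard
#'   errors calibrated on the profile likelihood (the drop in log likelihood
#'   when the coefficient is displaced and the remaining parameters refit,
#'   taking the flatter side), which stays honest on the ridge-shaped
#'   surfaces the truncated-normal law can produce; `"hessian"`:
#'   observed-information only; `"none"`: skip (fast, e.g. inside
#'   likelihood-ratio simulations).
#' @return object of class `sfa_fit`: frontier `coefficients`, `sigma_v2`,
#'   `sigma_u2`, `mu`, `loglik`, `aic`, `se` (named), `converged`,
#'   `boundary_u` (TRUE when the inefficiency variance collapsed towards 0 and
#'   the frontier is indistinguishable from OLS), residuals, `n_obs`, and a
#'   [thinning_model_spec()] in `$spec` when the design has 2 or 3 columns.
#' @export
fit_sfa <- function(X, y, dist = c("NH", "NE", "NT"), starts = NULL,
                    n_starts = 5L, seed = 1L,
                    se_method = c("profile", "hessian", "none")) {
  dist <- match.arg(dist)
  se_method <- match.arg(se_method)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("X and y sizes disagree")
  if (n < p + 2) stopf("need at least %d rows to fit %d coefficients plus variances",
                       p + 2, p)
  if (qr(X)$rank < p) stopf("singular design: collinear columns")

  negll <- function(par) {
    b <- par[seq_len(p)]
    sv2 <- exp(par[p + 1]); su2 <- exp(par[p + 2])
    m <- if (dist == "NT") par[p + 3] else 0
    if (!is.finite(sv2) || sv2 <= 0) return(1e10)
    ll <- composed_error_logdensity(y - drop(X %*% b), dist, sv2, su2, m)
    out <- -sum(ll)
    if (!is.finite(out)) 1e10 else out
  }

  qrx <- qr(X)
  b_ols <- qr.coef(qrx, y)
  res <- y - drop(X %*% b_ols)
  base_start <- sfa_start(b_ols, res, dist)
  npar <- length(base_start)

  m2 <- mean(res^2)
  # structured alternatives: noise-dominated and inefficiency-dominated corners
  start_sym <- c(b_ols, log(0.95 * m2), log(0.05 * m2), if (dist == "NT") 0)
  start_ineff <- base_start
  start_ineff[p + 1] <- log(0.2 * m2); start_ineff[p + 2] <- log(m2)
  start_list <- list(base_start, start_sym, start_ineff)
  if (n_starts > 1) {
    jit <- with_seed(seed, matrix(stats::rnorm((n_starts - 1) * npar, 0, 0.3),
                                  n_starts - 1, npar))
    for (i in seq_len(n_starts - 1)) {
      s <- base_start + jit[i, ] * (abs(base_start) * 0.3 + 0.1)
      start_list[[length(start_list) + 1]] <- s
    }
  }
  if (!is.null(starts)) start_list <- c(start_list, starts)

  # box constraints keep the likelihood inside the numerically meaningful
  # region: variance components scaled to the residual variance, and |mu|
  # within 10 residual standard deviations (beyond which the truncated-normal
  # law is indistinguishable from its normal/exponential limits but its
  # closed form loses all floating-point precision)
  lower <- c(rep(-Inf, p), log(m2) - 18, log(m2) - 18, if (dist == "NT") -10 * sqrt(m2))
  upper <- c(rep(Inf, p), log(m2) + 6, log(m2) + 6, if (dist == "NT") 10 * sqrt(m2))
  clamp <- function(s) pmin(pmax(s, lower + 1e-6), upper - 1e-6)

  best <- NULL
  for (s in start_list) {
    opt <- tryCatch(
      stats::optim(clamp(s), negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stopf("stochastic frontier fit failed from all %d starts",
                           length(start_list))

  par <- best$par
  b <- par[seq_len(p)]; names(b) <- colnames(X)
  sv2 <- exp(par[p + 1]); su2 <- exp(par[p + 2])
  m <- if (dist == "NT") par[p + 3] else 0
  loglik <- -best$value
  k_par <- npar
  aic <- 2 * k_par - 2 * loglik

  # observed-information standard errors; delta method maps the log-variance
  # scale back to sigma^2. Variance parameters that collapsed to an effective
  # boundary carry no curvature on the log scale and are excluded; flat
  # (ridge) directions in the remaining information matrix are floored at a
  # tiny positive eigenvalue, so weakly identified coefficients get the very
  # large standard errors the likelihood implies rather than spurious zeros.
  se <- rep(NA_real_, npar)
  if (se_method != "none") {
    H <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      free <- rep(TRUE, npar)
      tot <- sv2 + su2
      if (sv2 < 1e-6 * tot) free[p + 1] <- FALSE
      if (su2 < 1e-6 * tot) free[p + 2] <- FALSE
      Hf <- H[free, free, drop = FALSE]
      Hf <- (Hf + t(Hf)) / 2
      eg <- eigen(Hf, symmetric = TRUE)
      vals <- pmax(eg$values, max(abs(eg$values), 1e-12) * 1e-9)
      V <- eg$vectors %*% (t(eg$vectors) / vals)
      se[free] <- sqrt(pmax(diag(V), 0))
      if (free[p + 1]) se[p + 1] <- se[p + 1] * sv2
      if (free[p + 2]) se[p + 2] <- se[p + 2] * su2
      se[!free] <- NA_real_
    }
    if (se_method == "profile") {
      # Likelihood-calibrated coefficient SEs: displace one coefficient by
      # two curvature-based SEs, refit the rest, and convert the observed
      # log-likelihood drop back to a quadratic-equivalent SE. On a quadratic
      # surface this reproduces the information SE exactly; on a flat ridge
      # (k and mu confounded under the NT law) it widens honestly.
      for (j in seq_len(p)) {
        se0 <- se[j]
        if (!is.finite(se0) || se0 <= 0) next
        delta <- min(2 * se0, 2 + abs(par[j]))
        dll_side <- c(NA_real_, NA_real_)
        for (s_i in 1:2) {
          sgn <- c(-1, 1)[s_i]
          pfix <- par[j] + sgn * delta
          inner <- function(q) {
            full <- numeric(npar); full[j] <- pfix; full[-j] <- q; negll(full)
          }
          o <- tryCatch(
            stats::optim(par[-j], inner, method = "L-BFGS-B",
                         lower = lower[-j], upper = upper[-j],
                         control = list(maxit = 200, factr = 1e7)),
            error = function(e) NULL)
          if (!is.null(o)) dll_side[s_i] <- max(o$value - best$value, 0)
        }
        dll <- suppressWarnings(min(dll_side, na.rm = TRUE))
        # conservative: report the wider of the curvature-based and
        # likelihood-drop-calibrated values
        if (is.finite(dll)) se[j] <- max(se0, delta / sqrt(2 * max(dll, 1e-6)))
      }
    }
  }
  names(se) <- c(colnames(X), "sigma_v2", "sigma_u2", if (dist == "NT") "mu")

  spec <- NULL
  if (p == 2L) spec <- thinning_model_spec("RM", k = b[1], alpha = b[2])
  if (p == 3L) spec <- thinning_model_spec("VDM", k = b[1], alpha = b[2], beta = b[3])

  structure(list(
    dist = dist, coefficients = b, sigma_v2 = sv2, sigma_u2 = su2, mu = m,
    loglik = loglik, aic = aic, n_params = k_par, se = se,
    converged = best$convergence == 0,
    boundary_u = su2 < 1e-4 * (sv2 + su2),
    residuals = y - drop(X %*% b),
    n_obs = n, spec = spec
  ), class = "sfa_fit")
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat(sprintf("Stochastic frontier fit (%s), n = %d\n", x$dist, x$n_obs))
  tab <- cbind(estimate = c(x$coefficients, sigma_v2 = x$sigma_v2,
                            sigma_u2 = x$sigma_u2,
                            if (x$dist == "NT") c(mu = x$mu)),
               se = x$se)
  print(round(tab, 4))
  cat(sprintf("logLik %.3f  AIC %.2f%s%s\n", x$loglik, x$aic,
              if (!x$converged) "  [not converged]" else "",
              if (x$boundary_u) "  [sigma_u2 at boundary: frontier ~ OLS]" else ""))
  invisible(x)
}

#' @export
coef.sfa_fit <- function(object, ...) object$coefficients

#' @export
logLik.sfa_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Compare nested frontier models by likelihood ratio and AIC
#'
#' Reineke's model is the variable density model with the height slope fixed
#' at zero, so the two fits (same data, same composed-error law) are compared
#' with a 1-df likelihood-ratio test and their AIC difference. If the larger
#' model's optimum falls below the nested one's (an optimizer artifact), the
#' larger model is refit from the nested solution so the statistic is
#' non-negative.
#'
#' @param fit_rm,fit_vdm `sfa_fit` objects for the nested (RM) and full (VDM)
#'   model on the same observations.
#' @param X_vdm,y data used for the VDM fit; only needed for the refit
#'   safeguard.
#' @return list with `lrt_stat`, `lrt_p`, `df`, `delta_aic`
#'   (`AIC_vdm - AIC_rm`), and the (possibly refit) `fit_vdm`.
#' @export
compare_models <- function(fit_rm, fit_vdm, X_vdm = NULL, y = NULL) {
  if (!inherits(fit_rm, "sfa_fit") || !inherits(fit_vdm, "sfa_fit")) {
    stopf("both arguments must be sfa_fit objects")
  }
  if (fit_rm$dist != fit_vdm$dist) stopf("fits use different error laws")
  if (fit_rm$n_obs != fit_vdm$n_obs) stopf("fits use different numbers of observations")
  if (fit_vdm$loglik < fit_rm$loglik && !is.null(X_vdm) && !is.null(y)) {
    nested_start <- c(fit_rm$coefficients[1], fit_rm$coefficients[2], 0,
                      log(fit_rm$sigma_v2), log(max(fit_rm$sigma_u2, 1e-8)),
                      if (fit_rm$dist == "NT") fit_rm$mu)
    fit_vdm2 <- fit_sfa(X_vdm, y, fit_vdm$dist, starts = list(unname(nested_start)))
    if (fit_vdm2$loglik > fit_vdm$loglik) fit_vdm <- fit_vdm2
  }
  stat <- max(2 * (fit_vdm$loglik - fit_rm$loglik), 0)
  list(
    lrt_stat = stat,
    lrt_p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    df = 1L,
    delta_aic = fit_vdm$aic - fit_rm$aic,
    fit_vdm = fit_vdm
  )
}

#' Conditional expected inefficiency
#'
#' Jondrow-type predictor `E[u | eps]` for the fitted composed-error law: the
#' expected downward displacement of a stand from the frontier given its
#' composed residual. More negative residuals imply larger expected
#' inefficiency.
#'
#' @param fit converged `sfa_fit`.
#' @param eps composed residuals; defaults to the fit's own residuals.
#' @return numeric vector of non-negative conditional means.
#' @export
expected_inefficiency <- function(fit, eps = fit$residuals) {
  if (!inherits(fit, "sfa_fit")) stopf("expected an sfa_fit")
  sv2 <- fit$sigma_v2; su2 <- fit$sigma_u2
  if (su2 <= 0) return(rep(0, length(eps)))
  sv <- sqrt(sv2); su <- sqrt(su2)
  if (fit$dist == "NE") {
    mu_star <- -eps - sv2 / su
    s_star <- sv
  } else {
    s2 <- sv2 + su2
    mu_star <- (fit$mu * sv2 - eps * su2) / s2  # mu = 0 for NH
    s_star <- sv * su / sqrt(s2)
  }
  z <- mu_star / s_star
  # mean of N(mu_star, s_star^2) truncated to u >= 0
  out <- mu_star + s_star * exp(stats::dnorm(z, log = TRUE) -
                                  stats::pnorm(z, log.p = TRUE))
  pmax(out, 0)
}
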
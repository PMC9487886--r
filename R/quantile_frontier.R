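#' Design matrix for a boundary-line model
#'
#' Builds the log-scale design `(1, ln Dg)` for Reineke's model or
#' `(1, ln Dg, ln Hd)` for the variable density model, with the response
#' `ln(tph)` as attribute-free companion via [log_density()].
#'
#' @param plots plot table.
#' @param form `"RM"` or `"VDM"`.
#' @return numeric matrix with columns `intercept`, `log_d` and (VDM)
#'   `log_hd`.
#' @export
design_matrix <- function(plots, form = c("VDM", "RM")) {
  form <- match.arg(form)
  if (any(plots$qmd_cm <= 0)) stopf("qmd_cm must be positive")
  X <- cbind(intercept = 1, log_d = log(plots$qmd_cm))
  if (form == "VDM") {
    if (any(plots$dom_height_m <= 0)) stopf("dom_height_m must be positive")
    X <- cbind(X, log_hd = log(plots$dom_height_m))
  }
  X
}

#' @rdname design_matrix
#' @export
log_density <- function(plots) {
  if (any(plots$tph <= 0)) stopf("tph must be positive")
  log(plots$tph)
}

# asymmetric check loss rho_tau summed over residuals
check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Linear quantile regression by asymmetric-loss minimization
#'
#' Estimates the coefficients minimizing the check loss
#' `sum_i rho_tau(y_i - x_i' b)`, where residuals above the line are weighted
#' `tau` and residuals below it `1 - tau`. Large `tau` (0.90-0.99) places the
#' fitted line near the upper boundary of the density scatter, which is how
#' the self-thinning line is estimated.
#'
#' The solver iterates a majorize-minimize reweighting of the (convex,
#' piecewise-linear) objective to near-optimality and then polishes to an
#' exact vertex solution: an optimum interpolates at least `p` data points, so
#' the `p`-subsets of the observations with smallest absolute residuals are
#' enumerated and the best interpolating fit kept, repeating until no exchange
#' improves the objective.
#'
#' @param X design matrix (intercept column included), e.g. [design_matrix()].
#' @param y response vector (`ln` stems/ha).
#' @param tau quantile level in (0, 1).
#' @param max_iter,tol reweighting iteration cap and relative objective
#'   tolerance.
#' @return object of class `quantile_fit`: `tau`, named `coefficients`,
#'   attained `objective`, `converged`, residuals, and `n_interpolated`
#'   (zero-residual points at the solution).
#' @export
fit_quantile <- function(X, y, tau, max_iter = 500L, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("X and y sizes disagree")
  if (!(tau > 0 && tau < 1)) stopf("tau must lie strictly in (0, 1)")
  if (n < p + 1) stopf("need at least %d rows for %d coefficients", p + 1, p)
  if (qr(X)$rank < p) stopf("singular design: collinear columns")

  # --- majorize-minimize reweighting ---
  b <- qr.coef(qr(X), y)
  r <- y - drop(X %*% b)
  obj <- check_loss(r, tau)
  delta <- max(mean(abs(r)), 1e-4) / 10
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- 1 / pmax(abs(r), delta)
    A <- crossprod(X, d * X)
    rhs <- crossprod(X, d * y) + (2 * tau - 1) * colSums(X)
    b_new <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(b_new)) break
    b_new <- drop(b_new)
    r <- y - drop(X %*% b_new)
    obj_new <- check_loss(r, tau)
    if (is.finite(obj_new) && obj_new <= obj + tol * (1 + obj)) b <- b_new
    if (abs(obj - obj_new) < tol * (1 + obj) && delta <= 1e-10) {
      obj <- min(obj, obj_new); converged <- TRUE; break
    }
    obj <- min(obj, obj_new)
    delta <- max(delta * 0.7, 1e-10)
  }
  r <- y - drop(X %*% b)
  obj <- check_loss(r, tau)

  # --- vertex polish: enumerate interpolating p-subsets near the optimum ---
  polish <- polish_vertex(X, y, tau, b, obj)
  b <- polish$b; obj <- polish$obj
  r <- y - drop(X %*% b)

  if (!converged && !polish$improved_stable) {
    stopf("quantile fit did not converge at tau = %g (objective %.6g after %d iterations)",
          tau, obj, max_iter)
  }
  names(b) <- colnames(X)
  structure(list(
    tau = tau, coefficients = b, objective = obj, converged = TRUE,
    residuals = r, n_interpolated = sum(abs(r) < 1e-8 * (1 + stats::sd(y))),
    n_obs = n, ci = NULL
  ), class = "quantile_fit")
}

# Exchange-descent on vertex solutions: repeatedly enumerate p-subsets of the
# observations with smallest |residual| and keep the best exact fit.
polish_vertex <- function(X, y, tau, b, obj, rounds = 20L) {
  n <- nrow(X); p <- ncol(X)
  m <- min(n, max(2L * p + 6L, 12L))
  improved_stable <- FALSE
  for (round in seq_len(rounds)) {
    r <- y - drop(X %*% b)
    cand <- order(abs(r))[seq_len(m)]
    subsets <- utils::combn(cand, p)
    best_obj <- obj; best_b <- b
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      Xs <- X[idx, , drop = FALSE]
      bj <- tryCatch(solve(Xs, y[idx]), error = function(e) NULL)
      if (is.null(bj)) next
      oj <- check_loss(y - drop(X %*% bj), tau)
      if (oj < best_obj - 1e-12) { best_obj <- oj; best_b <- drop(bj) }
    }
    if (best_obj >= obj - 1e-12 * (1 + obj)) { improved_stable <- TRUE; break }
    b <- best_b; obj <- best_obj
  }
  list(b = b, obj = obj, improved_stable = improved_stable)
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile boundary fit, tau = %.3f (objective %.4f, %d obs)\n",
              x$tau, x$objective, x$n_obs))
  print(round(x$coefficients, 4))
  if (!is.null(x$ci)) {
    cat("95% bootstrap CI:\n"); print(round(x$ci, 4))
  }
  invisible(x)
}

#' @export
coef.quantile_fit <- function(object, ...) object$coefficients

#' Quantile-regression path over several upper quantiles
#'
#' Fits [fit_quantile()] at each level of `taus` (default the upper set
#' 0.900, 0.925, 0.950, 0.975, 0.990 used for boundary-line work). Levels
#' that fail to converge are recorded, not fatal, as long as at least one
#' level succeeds.
#'
#' @inheritParams fit_quantile
#' @param taus quantile levels.
#' @return object of class `quantile_path`: list of `quantile_fit` (or `NULL`
#'   for failed levels), with `taus` and per-level `errors`.
#' @export
fit_quantile_path <- function(X, y, taus = c(0.900, 0.925, 0.950, 0.975, 0.990)) {
  fits <- vector("list", length(taus))
  errs <- character(length(taus))
  for (i in seq_along(taus)) {
    res <- tryCatch(fit_quantile(X, y, taus[i]), error = function(e) e)
    if (inherits(res, "error")) errs[i] <- conditionMessage(res) else fits[[i]] <- res
  }
  if (all(vapply(fits, is.null, logical(1)))) {
    stopf("all quantile levels failed: %s", paste(unique(errs), collapse = "; "))
  }
  structure(list(taus = taus, fits = fits, errors = errs), class = "quantile_path")
}

#' @export
print.quantile_path <- function(x, ...) {
  cat("Quantile boundary path:\n")
  for (i in seq_along(x$taus)) {
    if (is.null(x$fits[[i]])) {
      cat(sprintf("  tau %.3f: failed (%s)\n", x$taus[i], x$errors[i]))
    } else {
      cat(sprintf("  tau %.3f: %s\n", x$taus[i],
                  paste(sprintf("%s=%.4f", names(x$fits[[i]]$coefficients),
                                x$fits[[i]]$coefficients), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Percentile bootstrap confidence intervals for quantile coefficients
#'
#' Resamples observation pairs (rows of `X` with their `y`) with replacement,
#' refits the quantile regression, and reports per-coefficient percentile
#' intervals. Reproducible under `seed`.
#'
#' @inheritParams fit_quantile
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param level interval coverage (default 0.95).
#' @return matrix with one row per coefficient and columns `lower`, `upper`;
#'   bootstrap draws attached as attribute `"boot"`.
#' @export
quantile_ci <- function(X, y, tau, n_boot = 1000L, seed = 1L, level = 0.95) {
  if (n_boot < 100) stopf("n_boot must be at least 100")
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, p)
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(fit_quantile(X[idx, , drop = FALSE], y[idx], tau),
                      error = function(e) NULL)
      if (!is.null(fit)) out[bi, ] <- fit$coefficients
    }
    out
  })
  keep <- stats::complete.cases(boot)
  if (sum(keep) < 0.5 * n_boot) stopf("too many bootstrap fits failed (%d of %d)",
                                      n_boot - sum(keep), n_boot)
  a <- (1 - level) / 2
  ci <- t(apply(boot[keep, , drop = FALSE], 2, stats::quantile, probs = c(a, 1 - a)))
  dimnames(ci) <- list(colnames(X), c("lower", "upper"))
  attr(ci, "boot") <- boot
  ci
}
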
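test_that("exactly linear data are interpolated at any quantile", {
  fp <- frontier_plots(10)
  X <- design_matrix(fp, "VDM")
  y <- log_density(fp)
  for (tau in c(0.25, 0.5, 0.9, 0.975)) {
    fit <- fit_quantile(X, y, tau)
    expect_equal(unname(fit$coefficients), c(8.424, -0.996, 0.621),
                 tolerance = 1e-7)
    expect_lt(fit$objective, 1e-8)
  }
  expect_error(fit_quantile(X, y, 1.2), "tau")
  expect_error(fit_quantile(cbind(X, X[, 2]), y, 0.5), "singular")
})

test_that("the solver attains the brute-force minimum over point-pair lines", {
  withr::with_seed(17, {
    for (rep in 1:12) {
      n <- sample(8:12, 1)
      x <- rnorm(n)
      y <- 2 + 1.5 * x + rt(n, df = 3)
      tau <- runif(1, 0.1, 0.95)
      fit <- fit_quantile(cbind(intercept = 1, x = x), y, tau)
      expect_equal(fit$objective, brute_force_qr(x, y, tau), tolerance = 1e-9)
    }
  })
})

test_that("the median fit agrees with an independent linear-programming oracle", {
  skip_if(Sys.which("python") == "", "no python interpreter for the LP oracle")
  # L1 regression as an LP solved by an external solver: variables are the
  # split coefficients and split residuals, minimize the residual sum
  withr::with_seed(23, {
    n <- 25
    x <- rnorm(n)
    y <- 1 - 2 * x + rnorm(n)
    fit <- fit_quantile(cbind(1, x), y, 0.5)
    dat <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(x = x, y = y), dat, row.names = FALSE)
    script <- withr::local_tempfile(fileext = ".py")
    writeLines(c(
      "import csv, sys",
      "import numpy as np",
      "from scipy.optimize import linprog",
      sprintf("rows = list(csv.DictReader(open('%s')))", dat),
      "x = np.array([float(r['x']) for r in rows]); y = np.array([float(r['y']) for r in rows])",
      "n = len(y); X = np.column_stack([np.ones(n), x])",
      "c = np.concatenate([np.zeros(4), 0.5*np.ones(2*n)])",
      "Aeq = np.hstack([X, -X, np.eye(n), -np.eye(n)])",
      "res = linprog(c, A_eq=Aeq, b_eq=y, method='highs')",
      "print(repr(res.fun))"
    ), script)
    out <- system2("python", script, stdout = TRUE)
    lp_obj <- as.numeric(out[length(out)])
    expect_equal(fit$objective, lp_obj, tolerance = 1e-8)
  })
})

test_that("optimal residual signs satisfy the quantile subgradient condition", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      plots <- make_plots(40, seed = rep)
      X <- design_matrix(plots, "VDM")
      y <- log_density(plots)
      tau <- sample(c(0.5, 0.9, 0.95), 1)
      fit <- fit_quantile(X, y, tau)
      n <- length(y)
      tol <- 1e-8 * (1 + sd(y))
      expect_lte(sum(fit$residuals < -tol), n * tau)
      expect_gte(sum(fit$residuals <= tol), n * tau)
    }
  })
})

test_that("coefficients scale equivariantly with the response", {
  plots <- make_plots(30, seed = 2)
  X <- design_matrix(plots, "RM")
  y <- log_density(plots)
  f1 <- fit_quantile(X, y, 0.9)
  f2 <- fit_quantile(X, 3 * y, 0.9)
  expect_equal(f2$coefficients, 3 * f1$coefficients, tolerance = 1e-7)
})

test_that("the quantile path fits all levels and records failures per level", {
  sim <- simulate_stands(synthetic_config(n_plots = 120, seed = 12))
  X <- design_matrix(sim$t0, "VDM")
  y <- log_density(sim$t0)
  path <- fit_quantile_path(X, y)
  expect_length(path$fits, 5)
  expect_true(all(!vapply(path$fits, is.null, logical(1))))
  # predicted boundary at the mean tree size is non-decreasing in tau
  xbar <- colMeans(X)
  preds <- vapply(path$fits, function(f) sum(f$coefficients * xbar), numeric(1))
  expect_true(all(diff(preds) > -1e-8))
  # single-level path equals the direct fit
  p1 <- fit_quantile_path(X, y, taus = 0.95)
  expect_equal(p1$fits[[1]]$coefficients, fit_quantile(X, y, 0.95)$coefficients)
  # an impossible level is recorded without aborting the path
  p2 <- fit_quantile_path(X, y, taus = c(0.9, NA))
  expect_false(is.null(p2$fits[[1]]))
  expect_true(is.null(p2$fits[[2]]))
  expect_match(p2$errors[2], ".+")
})

test_that("bootstrap intervals are reproducible and collapse on noiseless data", {
  fp <- frontier_plots(15)
  X <- design_matrix(fp, "VDM")
  y <- log_density(fp)
  ci <- quantile_ci(X, y, 0.9, n_boot = 120, seed = 4)
  expect_equal(ci[, "lower"], ci[, "upper"], tolerance = 1e-6)
  plots <- make_plots(40, seed = 5)
  X2 <- design_matrix(plots, "RM")
  y2 <- log_density(plots)
  ci1 <- quantile_ci(X2, y2, 0.9, n_boot = 150, seed = 7)
  ci2 <- quantile_ci(X2, y2, 0.9, n_boot = 150, seed = 7)
  expect_identical(ci1[, ], ci2[, ])
  expect_true(all(ci1[, "lower"] <= ci1[, "upper"]))
  expect_error(quantile_ci(X2, y2, 0.9, n_boot = 50), "at least 100")
})

test_that("bootstrap intervals cover a known slope at roughly nominal rate", {
  hits <- logical(120)
  for (i in seq_along(hits)) {
    dat <- withr::with_seed(9000 + i, {
      x <- runif(40, 0, 3)
      list(x = x, y = 1 + 0.8 * x + rnorm(40, 0, 0.5))
    })
    # the 0.5-quantile slope of this homoscedastic model is the true slope
    ci <- quantile_ci(cbind(1, dat$x), dat$y, 0.5, n_boot = 120, seed = i)
    hits[i] <- ci[2, "lower"] <= 0.8 && 0.8 <= ci[2, "upper"]
  }
  expect_gte(mean(hits), 0.87)
  expect_lte(mean(hits), 1.00)
})
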
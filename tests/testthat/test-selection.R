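test_that("interval selection keeps the densest plots per diameter bin", {
  plots <- make_plots(8)
  plots$qmd_cm <- c(8, 9, 8.5, 9.5, 18, 19, 18.5, 19.5)
  plots$tph <- c(900, 1200, 800, 700, 500, 650, 400, 300)
  sel <- select_interval(plots, n_bins = 2, points_per_bin = 1)
  expect_setequal(sel$selected_ids, plots$plot_id[c(2, 6)])
  sel2 <- select_interval(plots, n_bins = 2, points_per_bin = 2)
  expect_setequal(sel2$selected_ids, plots$plot_id[c(1, 2, 5, 6)])
  # idempotent: reselecting from the kept set returns the same set
  resel <- select_interval(sel2$plots, n_bins = 2, points_per_bin = 2)
  expect_setequal(resel$selected_ids, sel2$selected_ids)
  # degenerate: one distinct diameter cannot form two bins
  plots$qmd_cm <- 10
  expect_error(select_interval(plots, n_bins = 2), "bins")
})

test_that("mortality selection thresholds the period mortality", {
  sim <- simulate_stands(synthetic_config(n_plots = 50, seed = 18))
  pairs <- sim$pairs
  expect_equal(length(select_mortality(pairs, threshold = 0)$selected_ids), 50)
  expect_equal(length(select_mortality(pairs, threshold = 1.01)$selected_ids), 0)
  sel <- select_mortality(pairs, threshold = 0.20)
  expect_true(all(compute_mortality(pairs)[pairs$plot_id %in% sel$selected_ids] >= 0.20))
  # the default generator reproduces high mixed-stand mortality: a majority
  # of plots pass the classical 20% onset threshold
  expect_gt(length(sel$selected_ids), 25)
})

test_that("relative-density selection keeps plots at or beyond the provisional line", {
  plots <- make_plots(30, seed = 3)
  prov <- fit_ols_boundary(plots, "VDM")
  expect_equal(length(select_relative_density(plots, prov, standard = 0)$selected_ids), 30)
  sel <- select_relative_density(plots, prov, standard = 1)
  r <- relative_density(plots, prov)
  expect_setequal(sel$selected_ids, plots$plot_id[r >= 1])
  # plots strictly below the line: nothing at standard 1
  below <- plots
  below$tph <- exp(frontier_log_density(prov, below$qmd_cm, below$dom_height_m)) * 0.8
  expect_equal(length(select_relative_density(below, prov, 1)$selected_ids), 0)
  # the selected subset's OLS line lies above the all-data OLS line at the
  # mean diameter
  fit_sel <- fit_ols_boundary(sel, "RM")
  fit_all <- fit_ols_boundary(plots, "RM")
  dbar <- mean(plots$qmd_cm)
  expect_gt(frontier_log_density(fit_sel, dbar), frontier_log_density(fit_all, dbar))
})

test_that("upper-hull selection dominates the scatter and ignores interior points", {
  plots <- make_plots(3)
  plots$qmd_cm <- c(8, 12, 20)
  plots$tph <- c(1000, 1500, 600)
  sel <- select_upper_hull(plots)
  expect_true(all(c("T01", "T02", "T03") %in% sel$selected_ids))
  # collinear input: degenerate hull returns every distinct diameter
  lin <- make_plots(5)
  lin$qmd_cm <- seq(8, 16, 2)
  lin$tph <- exp(9 - 1.6 * log(lin$qmd_cm))
  expect_equal(length(select_upper_hull(lin)$selected_ids), 5)
  # dominance: no plot lies above a hull chord between consecutive vertices
  big <- make_plots(40, seed = 11)
  sel2 <- select_upper_hull(big)
  hp <- sel2$plots[order(log(sel2$plots$qmd_cm)), ]
  x <- log(big$qmd_cm); y <- log(big$tph)
  hx <- log(hp$qmd_cm); hy <- log(hp$tph)
  for (i in seq_len(nrow(hp) - 1)) {
    in_span <- x >= hx[i] & x <= hx[i + 1]
    chord <- hy[i] + (hy[i + 1] - hy[i]) * (x[in_span] - hx[i]) / (hx[i + 1] - hx[i])
    expect_true(all(y[in_span] <= chord + 1e-9))
  }
  # invariant to adding points strictly below the hull
  extra <- big[1:5, ]
  extra$plot_id <- paste0("X", 1:5)
  extra$tph <- extra$tph * 0.3
  sel3 <- select_upper_hull(rbind(big, extra))
  expect_setequal(sel3$selected_ids, sel2$selected_ids)
})

test_that("OLS boundary fitting is exact on clean data and matches normal equations", {
  fp <- frontier_plots(12)
  fit <- fit_ols_boundary(fp, "VDM")
  expect_equal(c(fit$k, fit$alpha, fit$beta), c(8.424, -0.996, 0.621),
               tolerance = 1e-9)
  # closed-form normal-equation oracle on a 5-point fixture
  plots <- make_plots(5, seed = 9)
  X <- cbind(1, log(plots$qmd_cm))
  y <- log(plots$tph)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  fit_rm <- fit_ols_boundary(plots, "RM")
  expect_equal(c(fit_rm$k, fit_rm$alpha), as.numeric(oracle), tolerance = 1e-10)
  expect_error(fit_ols_boundary(plots[1:2, ], "VDM"), "at least")
})

test_that("interval selection recovers a less biased thinning slope", {
  # scatter contaminated by understocked young stands: small-diameter plots
  # sit below the boundary, flattening the all-data OLS slope; bin maxima
  # track the boundary and recover the generating slope
  n_rep <- 40
  bias_all <- bias_sel <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    dat <- withr::with_seed(600 + i, {
      n <- 120
      ld <- runif(n, log(7), log(23))
      u <- (log(23) - ld) / (log(23) - log(7)) * abs(rnorm(n, 0, 1.0))
      data.frame(plot_id = sprintf("p%03d", seq_len(n)), year = 2004,
                 tph = exp(11.6 - 1.605 * ld + rnorm(n, 0, 0.1) - u),
                 qmd_cm = exp(ld), dom_height_m = 10)
    })
    fit_all <- fit_ols_boundary(dat, "RM")
    fit_sel <- fit_ols_boundary(select_interval(dat, n_bins = 10), "RM")
    bias_all[i] <- fit_all$alpha - (-1.605)
    bias_sel[i] <- fit_sel$alpha - (-1.605)
  }
  expect_lt(mean(abs(bias_sel)), mean(abs(bias_all)))
  # all-data OLS is flatter than the truth; the selected slope is steeper
  expect_gt(mean(bias_all), 0)
  expect_lt(mean(bias_sel), mean(bias_all))
})
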
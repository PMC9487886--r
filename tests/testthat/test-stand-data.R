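test_that("CSV round trip preserves records and unpacks encoded columns", {
  df <- make_plots(3)
  df$species_tally <- c("Quercus chenii:12;Pinus massoniana:8",
                        "Quercus chenii:20", "")
  df$dbh_list_cm <- c("6.1;7.5;12.0", "5.0;9.9", "")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  plots <- read_plot_table(path)
  expect_equal(nrow(plots), 3)
  expect_equal(plots$tph, df$tph, tolerance = 1e-12)
  expect_equal(plots$species_tally[[1]],
               c("Quercus chenii" = 12, "Pinus massoniana" = 8))
  expect_equal(plots$dbh_list_cm[[2]], c(5.0, 9.9))
  expect_null(plots$species_tally[[3]])
})

test_that("missing mandatory columns and bad values are rejected by name", {
  df <- make_plots(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[setdiff(names(df), "tph")], path, row.names = FALSE)
  expect_error(read_plot_table(path), "tph")
  bad <- df
  bad$qmd_cm[2] <- -1
  expect_error(plot_table(bad), "row")
  remap <- df
  names(remap)[names(remap) == "tph"] <- "stems_per_ha"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(remap, path2, row.names = FALSE)
  plots <- read_plot_table(path2, column_map = c(tph = "stems_per_ha"))
  expect_equal(plots$tph, df$tph, tolerance = 1e-12)
})

test_that("mortality is deaths over initial stems, guarded at zero", {
  pairs <- data.frame(n_dead = c(30L, 0L, 50L), n_stems0 = c(100L, 80L, 50L))
  expect_equal(compute_mortality(pairs), c(0.30, 0, 1))
  expect_error(compute_mortality(data.frame(n_dead = 0L, n_stems0 = 0L)),
               "no stems")
  expect_error(compute_mortality(data.frame(n_dead = 5L, n_stems0 = 3L)))
  # monotone in n_dead
  m <- compute_mortality(data.frame(n_dead = 0:10, n_stems0 = 10L))
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("inclusion filters apply the canopy/density/oak-share rules", {
  plots <- make_plots(4)
  plots$tph <- c(400, 800, 800, 800)
  plots$canopy_density <- c(0.7, 0.7, 0.7, 0.55)
  plots$oak_fraction <- c(0.2, 0.10, 0.2, 0.3)
  kept <- apply_inclusion_filters(plots)
  expect_equal(kept$plot_id, plots$plot_id[3])
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts["kept"]), 1)
  expect_equal(unname(counts["input"]), 4)
  # boundary conventions: oak exactly at 0.15 kept, tph exactly 500 dropped
  plots$tph <- 500; plots$canopy_density <- 0.7; plots$oak_fraction <- 0.15
  expect_equal(nrow(apply_inclusion_filters(plots)), 0)
  plots$tph <- 501
  expect_equal(nrow(apply_inclusion_filters(plots)), 4)
})

test_that("modeling/validation split gives floor(frac n) and is a seeded partition", {
  plots <- make_plots(10)
  s <- split_modeling_validation(plots, 0.7, seed = 5)
  expect_equal(nrow(s$modeling), 7)
  expect_equal(nrow(s$validation), 3)
  expect_length(intersect(s$modeling$plot_id, s$validation$plot_id), 0)
  expect_setequal(c(s$modeling$plot_id, s$validation$plot_id), plots$plot_id)
  s2 <- split_modeling_validation(plots, 0.7, seed = 5)
  expect_identical(s$modeling$plot_id, s2$modeling$plot_id)
  expect_false(identical(
    split_modeling_validation(plots, 0.7, seed = 6)$modeling$plot_id,
    s$modeling$plot_id))
  # the 265-plot inventory splits 185 / 80
  big <- do.call(rbind, replicate(27, plots, simplify = FALSE))[1:265, ]
  big$plot_id <- sprintf("B%03d", 1:265)
  s3 <- split_modeling_validation(big, 0.7, seed = 1)
  expect_equal(nrow(s3$modeling), 185)
  expect_equal(nrow(s3$validation), 80)
  expect_error(split_modeling_validation(plots[1, ]), "at least 2")
})

test_that("noise-free simulation lies exactly on the configured frontier", {
  cfg <- synthetic_config(sigma_v2 = 0, sigma_u2 = 0, mort_sd = 0,
                          n_plots = 40, seed = 9)
  sim <- simulate_stands(cfg)
  pred <- cfg$k + cfg$alpha * log(sim$t0$qmd_cm) +
    cfg$beta * log(sim$t0$dom_height_m)
  expect_equal(log(sim$t0$tph), pred, tolerance = 1e-12)
  expect_true(all(abs(sim$pairs$rel_density - 1) < 1e-12))
})

test_that("simulated stands reproduce the intended study conditions", {
  sim <- simulate_stands(synthetic_config(seed = 21))
  expect_equal(nrow(sim$t0), 185)
  expect_true(all(sim$pairs$mortality >= 0 & sim$pairs$mortality <= 1))
  expect_gt(mean(sim$pairs$mortality), 0.25)
  expect_lt(mean(sim$pairs$mortality), 0.45)
  expect_true(all(sim$t0$qmd_cm >= 5))
  expect_true(all(vapply(sim$t0$dbh_list_cm, min, numeric(1)) >= 5))
  # species tallies sum to the tallied stems
  expect_equal(vapply(sim$t0$species_tally, sum, numeric(1)),
               as.numeric(sim$pairs$n_stems0))
  expect_true(all(sim$pairs$year0 < sim$pairs$year1))
  expect_true(all(sim$pairs$n_dead <= sim$pairs$n_stems0))
  # reproducible under the config seed
  sim2 <- simulate_stands(synthetic_config(seed = 21))
  expect_identical(sim$t0$tph, sim2$t0$tph)
})

test_that("with no inefficiency the log-density residuals are symmetric", {
  sim <- simulate_stands(synthetic_config(sigma_u2 = 0, n_plots = 4000, seed = 3))
  X <- design_matrix(sim$t0, "VDM")
  res <- stats::lm.fit(X, log_density(sim$t0))$residuals
  skew <- mean(res^3) / mean(res^2)^1.5
  expect_lt(abs(skew), 0.1)
  expect_error(synthetic_config(sigma_u2 = -1), "non-negative")
})
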
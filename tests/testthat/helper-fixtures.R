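# small in-code fixtures shared across test files

# minimal valid plot table without going through the simulator
make_plots <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    qmd <- runif(n, 7, 23)
    hd <- 2.5 * qmd^0.6 * exp(rnorm(n, 0, 0.2))
    data.frame(
      plot_id = sprintf("T%02d", seq_len(n)),
      year = 2004,
      tph = exp(8.4 - 1.0 * log(qmd) + 0.6 * log(hd) + rnorm(n, 0, 0.3)),
      qmd_cm = qmd,
      dom_height_m = hd,
      canopy_density = runif(n, 0.65, 0.9),
      oak_fraction = runif(n, 0.2, 0.7),
      altitude_m = runif(n, 100, 1200),
      slope_deg = runif(n, 0, 45),
      stringsAsFactors = FALSE
    )
  })
}

# plots lying exactly on a configured frontier (no noise)
frontier_plots <- function(n = 12, k = 8.424, alpha = -0.996, beta = 0.621,
                           seed = 3) {
  withr::with_seed(seed, {
    qmd <- seq(7, 22, length.out = n)
    # jitter the allometry so (1, ln d, ln hd) has full rank
    hd <- 2.5 * qmd^0.6 * exp(rnorm(n, 0, 0.15))
    data.frame(
      plot_id = sprintf("F%02d", seq_len(n)), year = 2004,
      tph = exp(k + alpha * log(qmd) + beta * log(hd)),
      qmd_cm = qmd, dom_height_m = hd, stringsAsFactors = FALSE
    )
  })
}

table3_spec <- function() thinning_model_spec("VDM", k = 8.424, alpha = -0.996,
                                              beta = 0.621)

# brute-force check-loss minimum over all lines through data-point pairs
brute_force_qr <- function(x, y, tau) {
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (x[i] == x[j]) next
      b1 <- (y[j] - y[i]) / (x[j] - x[i])
      b0 <- y[i] - b1 * x[i]
      r <- y - b0 - b1 * x
      best <- min(best, sum(r * (tau - (r < 0))))
    }
  }
  best
}
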
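#' End-to-end self-thinning analysis
#'
#' Runs the full workflow on a plot table or a synthetic configuration:
#' inclusion filters, modeling/validation split, quantile-regression path and
#' stochastic frontier fits for Reineke's and the variable density model,
#' nested-model comparison per error law, density-index projection and
#' relative density under the best (lowest-AIC) frontier, the
#' mortality-density regression (when repeated measurements are available),
#' a holdout comparison of projected SDI, boundary-point selections with
#' their OLS lines, and the stand-structure covariate model.
#'
#' @param input one of: a plot table (first survey), a [synthetic_config()]
#'   (simulated first), or a `stand_sim` from [simulate_stands()].
#' @param pairs optional repeated-measurement pairs (taken from the
#'   simulation automatically).
#' @param filters `NULL` to skip the inclusion filters, or a list with
#'   `min_canopy`, `min_tph`, `min_oak`.
#' @param split_frac modeling fraction for the random split.
#' @param taus quantile levels (`NULL` disables quantile regression).
#' @param dists composed-error laws to fit (`NULL` disables the frontier
#'   estimator); at least one estimator must remain enabled.
#' @param ref [sdi_reference()] for projections.
#' @param selection run the traditional selection methods (logical).
#' @param covariate_form form for [fit_covariate_model()].
#' @param se_method standard-error method passed to [fit_sfa()].
#' @param seed RNG seed governing the split (and any simulation that does not
#'   carry its own seed).
#' @param out_dir optional directory; when given, all report tables are
#'   written as CSV alongside a `run_info.csv` echoing seed and settings.
#' @return object of class `selfthin_run`: list of tables and fitted objects
#'   (`sfa_table`, `qr_table`, `comparison`, `best_fit`, `sdi`,
#'   `mortality_fit`, `holdout`, `selection_table`, `covariate_fit`, ...).
#' @export
run_full_analysis <- function(input, pairs = NULL,
                              filters = NULL,
                              split_frac = 0.7,
                              taus = c(0.900, 0.925, 0.950, 0.975, 0.990),
                              dists = c("NH", "NE", "NT"),
                              ref = sdi_reference(),
                              selection = TRUE,
                              covariate_form = "linear",
                              se_method = "profile",
                              seed = 1L,
                              out_dir = NULL) {
  if (is.null(taus) && is.null(dists)) stopf("at least one estimator must be enabled")

  sim <- NULL
  if (inherits(input, "synthetic_config")) input <- simulate_stands(input)
  if (inherits(input, "stand_sim")) {
    sim <- input
    plots <- sim$t0
    if (is.null(pairs)) pairs <- sim$pairs
  } else {
    plots <- plot_table(input)
  }

  if (!is.null(filters)) {
    plots <- do.call(apply_inclusion_filters, c(list(plots), filters))
    if (!is.null(pairs)) pairs <- pairs[pairs$plot_id %in% plots$plot_id, , drop = FALSE]
  }

  split <- split_modeling_validation(plots, frac = split_frac, seed = seed)
  modeling <- split$modeling; validation <- split$validation
  y <- log_density(modeling)

  # --- quantile regression path, both model forms ---
  qr_fits <- list(); qr_table <- NULL
  if (!is.null(taus)) {
    for (form in c("RM", "VDM")) {
      X <- design_matrix(modeling, form)
      qr_fits[[form]] <- fit_quantile_path(X, y, taus)
    }
    qr_table <- do.call(rbind, lapply(names(qr_fits), function(form) {
      path <- qr_fits[[form]]
      do.call(rbind, lapply(seq_along(path$taus), function(i) {
        f <- path$fits[[i]]
        data.frame(form = form, tau = path$taus[i],
                   converged = !is.null(f),
                   intercept = if (is.null(f)) NA else f$coefficients[1],
                   slope_d = if (is.null(f)) NA else f$coefficients[2],
                   slope_hd = if (is.null(f) || form == "RM") NA else f$coefficients[3],
                   objective = if (is.null(f)) NA else f$objective,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(qr_table) <- NULL
  }

  # --- stochastic frontier fits and nested comparison ---
  sfa_fits <- list(); sfa_table <- NULL; comparison <- NULL
  if (!is.null(dists)) {
    X_rm <- design_matrix(modeling, "RM")
    X_vdm <- design_matrix(modeling, "VDM")
    rows <- list(); cmps <- list()
    for (d in dists) {
      f_rm <- fit_sfa(X_rm, y, d, seed = seed, se_method = se_method)
      f_vdm <- fit_sfa(X_vdm, y, d, seed = seed, se_method = se_method)
      cmp <- compare_models(f_rm, f_vdm, X_vdm = X_vdm, y = y)
      f_vdm <- cmp$fit_vdm
      sfa_fits[[paste0(d, "-RM")]] <- f_rm
      sfa_fits[[paste0(d, "-VDM")]] <- f_vdm
      cmps[[d]] <- cmp
      rows[[paste0(d, "-RM")]] <- data.frame(
        model = paste0(d, "-RM"), intercept = f_rm$coefficients[1],
        slope_d = f_rm$coefficients[2], slope_hd = NA_real_,
        se_intercept = f_rm$se[1], se_d = f_rm$se[2], se_hd = NA_real_,
        sigma_v2 = f_rm$sigma_v2, sigma_u2 = f_rm$sigma_u2,
        aic = f_rm$aic, lrt_p = cmp$lrt_p, stringsAsFactors = FALSE)
      rows[[paste0(d, "-VDM")]] <- data.frame(
        model = paste0(d, "-VDM"), intercept = f_vdm$coefficients[1],
        slope_d = f_vdm$coefficients[2], slope_hd = f_vdm$coefficients[3],
        se_intercept = f_vdm$se[1], se_d = f_vdm$se[2], se_hd = f_vdm$se[3],
        sigma_v2 = f_vdm$sigma_v2, sigma_u2 = f_vdm$sigma_u2,
        aic = f_vdm$aic, lrt_p = NA_real_, stringsAsFactors = FALSE)
    }
    sfa_table <- do.call(rbind, rows); rownames(sfa_table) <- NULL
    comparison <- cmps
  }

  # --- best frontier (lowest AIC) drives the density diagnostics ---
  best_fit <- NULL; best_spec <- NULL
  if (length(sfa_fits)) {
    best_fit <- sfa_fits[[which.min(vapply(sfa_fits, `[[`, numeric(1), "aic"))]]
    best_spec <- best_fit$spec
  } else {
    f <- qr_fits[["VDM"]]$fits[[which.max(!vapply(qr_fits[["VDM"]]$fits, is.null, logical(1)))]]
    best_spec <- thinning_model_spec("VDM", f$coefficients[1], f$coefficients[2],
                                     f$coefficients[3])
  }

  sdi <- data.frame(
    plot_id = plots$plot_id,
    set = ifelse(plots$plot_id %in% modeling$plot_id, "modeling", "validation"),
    sdi_max = sdi_projected(plots, best_spec, ref),
    rel_density = relative_density(plots, best_spec),
    stringsAsFactors = FALSE
  )

  mortality_fit <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 3) {
    mortality_fit <- mortality_density_regression(pairs, best_spec)
  }

  holdout <- validate_holdout(best_spec, modeling, validation, ref = ref)

  # --- traditional boundary-point selections with OLS lines ---
  selection_table <- NULL; selections <- NULL
  if (isTRUE(selection)) {
    provisional <- fit_ols_boundary(modeling, "VDM")
    selections <- list(
      interval = select_interval(modeling),
      relative_density = select_relative_density(modeling, provisional),
      upper_hull = select_upper_hull(modeling)
    )
    if (!is.null(pairs)) {
      mp <- pairs[pairs$plot_id %in% modeling$plot_id, , drop = FALSE]
      if (nrow(mp) >= 3) selections$mortality <- select_mortality(mp)
    }
    selection_table <- do.call(rbind, lapply(names(selections), function(m) {
      sel <- selections[[m]]
      fit <- tryCatch(fit_ols_boundary(sel, "RM"), error = function(e) NULL)
      data.frame(method = m, n_selected = length(sel$selected_ids),
                 intercept = if (is.null(fit)) NA else fit$k,
                 slope_d = if (is.null(fit)) NA else fit$alpha,
                 r2 = if (is.null(fit)) NA else attr(fit, "r2"),
                 stringsAsFactors = FALSE)
    }))
    rownames(selection_table) <- NULL
  }

  # --- structure covariate model on the modeling set ---
  covariate_fit <- NULL
  metrics <- structure_metrics(modeling)
  covs <- data.frame(altitude_m = modeling$altitude_m,
                     simpson = metrics$simpson,
                     hd_over_d = metrics$hd_over_d)
  if (!anyNA(covs) && nrow(covs) >= 10) {
    sdi_model <- sdi$sdi_max[sdi$set == "modeling"]
    covariate_fit <- fit_covariate_model(sdi_model, covs, form = covariate_form)
  }

  run <- structure(list(
    seed = seed, n_input = nrow(plots),
    n_modeling = nrow(modeling), n_validation = nrow(validation),
    qr_table = qr_table, qr_fits = qr_fits,
    sfa_table = sfa_table, sfa_fits = sfa_fits, comparison = comparison,
    best_fit = best_fit, best_spec = best_spec,
    sdi = sdi, mortality_fit = mortality_fit, holdout = holdout,
    selection_table = selection_table, selections = selections,
    covariate_fit = covariate_fit, metrics = metrics,
    truth = if (!is.null(sim)) sim$truth[c("k", "alpha", "beta", "sigma_v2",
                                           "sigma_u2", "mu", "dist")]
  ), class = "selfthin_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(run$sfa_table, "sfa_comparison.csv")
  wr(run$qr_table, "quantile_path.csv")
  wr(run$sdi, "sdi_projection.csv")
  wr(run$selection_table, "boundary_selection.csv")
  wr(run$metrics, "structure_metrics.csv")
  if (!is.null(run$mortality_fit)) {
    wr(data.frame(slope = run$mortality_fit$slope,
                  intercept = run$mortality_fit$intercept,
                  r2 = run$mortality_fit$r2,
                  p_value = run$mortality_fit$p_value), "mortality_regression.csv")
  }
  wr(data.frame(statistic = run$holdout$statistic, p_value = run$holdout$p_value,
                mean_modeling = run$holdout$mean_modeling,
                mean_validation = run$holdout$mean_validation), "holdout_ttest.csv")
  if (!is.null(run$covariate_fit)) {
    wr(data.frame(term = names(run$covariate_fit$coefficients),
                  estimate = unname(run$covariate_fit$coefficients)),
       "covariate_model.csv")
    wr(data.frame(relative_error_pct = run$covariate_fit$relative_error_pct,
                  r2 = run$covariate_fit$r2, form = run$covariate_fit$form),
       "covariate_model_summary.csv")
  }
  wr(data.frame(seed = run$seed, n_input = run$n_input,
                n_modeling = run$n_modeling, n_validation = run$n_validation),
     "run_info.csv")
  invisible(out_dir)
}

#' @export
print.selfthin_run <- function(x, ...) {
  cat(sprintf("Self-thinning analysis run (seed %d): %d plots -> %d modeling / %d validation\n",
              x$seed, x$n_input, x$n_modeling, x$n_validation))
  if (!is.null(x$sfa_table)) {
    cat("\nStochastic frontier comparison:\n")
    print(cbind(x$sfa_table[, c("model", "intercept", "slope_d", "slope_hd")],
                round(x$sfa_table[, c("sigma_v2", "sigma_u2", "aic", "lrt_p")], 4)),
          digits = 4)
  }
  if (!is.null(x$best_fit)) {
    cat(sprintf("\nBest frontier by AIC: %s-%s\n", x$best_fit$dist, x$best_spec$form))
  }
  if (!is.null(x$mortality_fit)) {
    cat(sprintf("Mortality ~ relative density: slope %.3f (p = %.3g, R2 %.3f)\n",
                x$mortality_fit$slope, x$mortality_fit$p_value, x$mortality_fit$r2))
  }
  cat(sprintf("Holdout SDI t-test: t = %.3f, p = %.3f\n",
              x$holdout$statistic, x$holdout$p_value))
  if (!is.null(x$covariate_fit)) {
    cat(sprintf("Covariate model relative error: %.1f%%\n",
                x$covariate_fit$relative_error_pct))
  }
  invisible(x)
}

#' Holdout comparison of projected density indices
#'
#' Welch two-sample t-test of projected SDI between the modeling and
#' validation plots under a common fitted boundary: no significant difference
#' indicates the boundary transfers to held-out stands.
#'
#' @param spec fitted [thinning_model_spec()] (or an `sfa_fit`, whose spec is
#'   used).
#' @param modeling,validation plot tables (>= 2 plots each).
#' @param ref [sdi_reference()].
#' @return list with `statistic`, `p_value`, `mean_modeling`,
#'   `mean_validation`, and the per-set SDI vectors.
#' @export
validate_holdout <- function(spec, modeling, validation, ref = sdi_reference()) {
  if (inherits(spec, "sfa_fit")) spec <- spec$spec
  if (nrow(modeling) < 2 || nrow(validation) < 2) {
    stopf("need at least 2 plots in each of the modeling and validation sets")
  }
  s_m <- sdi_projected(modeling, spec, ref)
  s_v <- sdi_projected(validation, spec, ref)
  if (stats::sd(s_m) == 0 && stats::sd(s_v) == 0 && mean(s_m) == mean(s_v)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(s_m, s_v)
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_modeling = mean(s_m), mean_validation = mean(s_v),
       sdi_modeling = s_m, sdi_validation = s_v)
}
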
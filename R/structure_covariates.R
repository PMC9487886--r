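#' Shannon diversity of a species tally
#'
#' `H' = -sum p_i ln p_i` over species with at least one stem.
#'
#' @param counts named (or unnamed) vector of stems per species.
#' @return Shannon index (>= 0; 0 for a single species).
#' @export
shannon_index <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  if (!length(counts)) stopf("empty species tally")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Simpson diversity of a species tally
#'
#' Unbiased form `DS = 1 - sum n_i (n_i - 1) / (N (N - 1))`: the probability
#' that two stems drawn without replacement belong to different species.
#'
#' @param counts stems per species.
#' @return Simpson index in \[0, 1\].
#' @export
simpson_index <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  n_tot <- sum(counts)
  if (n_tot < 2) stopf("need at least 2 stems for the Simpson index")
  1 - sum(counts * (counts - 1)) / (n_tot * (n_tot - 1))
}

#' Coefficient of variation of stem diameters
#'
#' Sample standard deviation (n - 1 denominator) over the mean DBH.
#'
#' @param dbh_list per-stem DBH values (cm), at least 2.
#' @return nondimensional CV (0 for a constant list).
#' @export
cv_dbh <- function(dbh_list) {
  dbh_list <- dbh_list[!is.na(dbh_list)]
  if (length(dbh_list) < 2) stopf("need at least 2 stems for a CV")
  m <- mean(dbh_list)
  if (m <= 0) stopf("mean DBH must be positive")
  stats::sd(dbh_list) / m
}

#' Dominant height to mean diameter ratio
#'
#' Slenderness-type structure covariate: dominant height (m) divided by mean
#' DBH expressed in meters, so a 12 m stand of 10 cm stems scores 120.
#'
#' @param dom_height_m dominant height (m).
#' @param mean_dbh_cm mean stem DBH (cm).
#' @return nondimensional ratio.
#' @export
hd_over_d <- function(dom_height_m, mean_dbh_cm) {
  if (any(dom_height_m <= 0) || any(mean_dbh_cm <= 0)) {
    stopf("heights and diameters must be positive")
  }
  dom_height_m / (mean_dbh_cm / 100)
}

#' Per-plot stand-structure metrics
#'
#' Computes Shannon and Simpson diversity from the species tallies, the DBH
#' coefficient of variation, and the height-diameter ratio for every plot.
#' When a per-stem DBH list is present its arithmetic mean is used for
#' `hd_over_d` and the CV; otherwise the quadratic mean diameter stands in
#' for the mean DBH and the CV is `NA`.
#'
#' @param plots plot table.
#' @return data.frame with `plot_id`, `shannon`, `simpson`, `cv_dbh`,
#'   `hd_over_d`.
#' @export
structure_metrics <- function(plots) {
  plots <- plot_table(plots)
  n <- nrow(plots)
  out <- data.frame(plot_id = plots$plot_id,
                    shannon = NA_real_, simpson = NA_real_,
                    cv_dbh = NA_real_, hd_over_d = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tal <- plots$species_tally[[i]]
    if (!is.null(tal) && length(tal)) {
      out$shannon[i] <- shannon_index(tal)
      if (sum(tal) >= 2) out$simpson[i] <- simpson_index(tal)
    }
    dbh <- plots$dbh_list_cm[[i]]
    mean_d <- if (!is.null(dbh) && length(dbh)) mean(dbh) else plots$qmd_cm[i]
    if (!is.null(dbh) && length(dbh) >= 2) out$cv_dbh[i] <- cv_dbh(dbh)
    out$hd_over_d[i] <- hd_over_d(plots$dom_height_m[i], mean_d)
  }
  out
}

#' Covariate model for maximum stand density index
#'
#' Least-squares regression of projected maximum density (SDI) on site and
#' structure covariates, in a linear (`SDI ~ X`) or log-linear
#' (`ln SDI ~ X`) form. The fit quality is summarized as the relative error,
#' `100 * RMSE / mean(SDI)`, on the SDI scale for either form.
#'
#' @param sdi_values per-plot projected SDI (positive).
#' @param covariates data.frame of predictors (e.g. altitude, Simpson index,
#'   height-diameter ratio); no missing values.
#' @param form `"linear"` or `"log_linear"`.
#' @return object of class `covariate_model_fit`: `coefficients`,
#'   `residual_sd`, `relative_error_pct`, `r2`, `form`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_covariate_model <- function(sdi_values, covariates, form = c("linear", "log_linear")) {
  form <- match.arg(form)
  covariates <- as.data.frame(covariates)
  if (length(sdi_values) != nrow(covariates)) stopf("sdi_values and covariates sizes disagree")
  if (nrow(covariates) < 10) stopf("need at least 10 plots")
  if (anyNA(covariates) || anyNA(sdi_values)) stopf("missing values in SDI or covariates")
  if (any(sdi_values <= 0)) stopf("SDI values must be positive")
  X <- stats::model.matrix(~ ., data = covariates)
  if (qr(X)$rank < ncol(X)) stopf("collinear covariates: singular design")
  y <- if (form == "linear") sdi_values else log(sdi_values)
  dat <- cbind(.y = y, covariates)
  fit <- stats::lm(.y ~ ., data = dat)
  pred <- if (form == "linear") stats::fitted(fit) else exp(stats::fitted(fit))
  rmse <- sqrt(mean((sdi_values - pred)^2))
  structure(list(
    coefficients = stats::coef(fit),
    residual_sd = summary(fit)$sigma,
    relative_error_pct = 100 * rmse / mean(sdi_values),
    r2 = summary(fit)$r.squared,
    form = form, n = nrow(covariates), lm_fit = fit
  ), class = "covariate_model_fit")
}

#' @export
print.covariate_model_fit <- function(x, ...) {
  cat(sprintf("SDI covariate model (%s form, n = %d)\n", x$form, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("relative error %.1f%% of mean SDI, R2 %.3f\n",
              x$relative_error_pct, x$r2))
  invisible(x)
}
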
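#' Self-thinning model specification
#'
#' Two nested boundary-line forms on the log scale. Reineke's model (`"RM"`)
#' relates log stand density to log quadratic mean diameter only,
#' `ln N = k + alpha ln Dg`; the variable density model (`"VDM"`) adds log
#' dominant height, `ln N = k + alpha ln Dg + beta ln Hd`, so that stands of
#' equal mean diameter but taller dominants can carry more stems.
#'
#' @param form `"RM"` or `"VDM"`.
#' @param k intercept on the `ln(stems/ha)` scale.
#' @param alpha log-diameter slope (self-thinning rate; negative for thinning
#'   stands).
#' @param beta log-dominant-height slope; must be 0 (and is ignored) for RM.
#' @return object of class `thinning_model_spec`.
#' @export
thinning_model_spec <- function(form = c("VDM", "RM"), k, alpha, beta = 0) {
  form <- match.arg(form)
  if (form == "RM" && !identical(beta, 0) && !isTRUE(beta == 0)) {
    stopf("Reineke's model has no height slope: beta must be 0 when form = 'RM'")
  }
  structure(list(form = form, k = as.numeric(k), alpha = as.numeric(alpha),
                 beta = if (form == "RM") 0 else as.numeric(beta)),
            class = "thinning_model_spec")
}

#' @export
print.thinning_model_spec <- function(x, ...) {
  if (x$form == "RM") {
    cat(sprintf("RM boundary: ln N = %.4f %+.4f ln Dg\n", x$k, x$alpha))
  } else {
    cat(sprintf("VDM boundary: ln N = %.4f %+.4f ln Dg %+.4f ln Hd\n",
                x$k, x$alpha, x$beta))
  }
  invisible(x)
}

check_spec_fitted <- function(spec) {
  if (!inherits(spec, "thinning_model_spec")) stopf("expected a thinning_model_spec")
  if (!all(is.finite(c(spec$k, spec$alpha, spec$beta)))) {
    stopf("model spec has non-finite coefficients (unfitted?)")
  }
  spec
}

#' Reference tree size for stand density index projection
#'
#' @param d0_cm reference quadratic mean diameter (default 16 cm).
#' @param h0_m reference dominant height (default 12 m).
#' @return object of class `sdi_reference`.
#' @export
sdi_reference <- function(d0_cm = 16, h0_m = 12) {
  if (d0_cm <= 0 || h0_m <= 0) stopf("reference sizes must be positive")
  structure(list(d0_cm = d0_cm, h0_m = h0_m), class = "sdi_reference")
}

#' Boundary-line log density at a given tree size
#'
#' Evaluates the fitted frontier `k + alpha ln d (+ beta ln hd)`.
#'
#' @param spec fitted [thinning_model_spec()].
#' @param d_cm quadratic mean diameter (cm), vectorized.
#' @param hd_m dominant height (m), vectorized; ignored for RM.
#' @return predicted `ln(stems/ha)` at the boundary.
#' @export
frontier_log_density <- function(spec, d_cm, hd_m = NULL) {
  check_spec_fitted(spec)
  if (any(d_cm <= 0)) stopf("d_cm must be positive")
  out <- spec$k + spec$alpha * log(d_cm)
  if (spec$form == "VDM") {
    if (is.null(hd_m)) stopf("hd_m is required for the variable density model")
    if (any(hd_m <= 0)) stopf("hd_m must be positive")
    out <- out + spec$beta * log(hd_m)
  }
  out
}

#' Stand density index projected to a reference size
#'
#' Projects each plot's observed density along the fitted boundary to the
#' reference tree size: `SDI = N (d0/Dg)^alpha` for Reineke's model and
#' `SDI = N (d0/Dg)^alpha (h0/Hg)^beta` for the variable density model. A plot
#' already at the reference size keeps its observed density. With
#' `orientation = "size_over_reference"` the historical convention
#' `N (Dg/d0)^alpha ...` is used instead, for comparison; only the default is
#' consistent with projection along the frontier.
#'
#' @param plots plot table (or data.frame with `tph`, `qmd_cm`, `dom_height_m`).
#' @param spec fitted [thinning_model_spec()].
#' @param ref an [sdi_reference()].
#' @param orientation `"reference_over_size"` (default, frontier-consistent)
#'   or `"size_over_reference"`.
#' @return numeric vector of projected stand density indices (stems/ha at the
#'   reference size).
#' @export
sdi_projected <- function(plots, spec, ref = sdi_reference(),
                          orientation = c("reference_over_size", "size_over_reference")) {
  orientation <- match.arg(orientation)
  check_spec_fitted(spec)
  if (any(plots$tph <= 0) || any(plots$qmd_cm <= 0)) stopf("densities and sizes must be positive")
  rd <- ref$d0_cm / plots$qmd_cm
  out <- plots$tph * rd^spec$alpha
  if (spec$form == "VDM") {
    if (any(plots$dom_height_m <= 0)) stopf("dominant heights must be positive")
    out <- out * (ref$h0_m / plots$dom_height_m)^spec$beta
  }
  if (orientation == "size_over_reference") {
    out <- plots$tph * (1 / rd)^spec$alpha
    if (spec$form == "VDM") out <- out * (plots$dom_height_m / ref$h0_m)^spec$beta
  }
  out
}

#' Relative density against the fitted boundary
#'
#' Ratio of the observed density to the frontier-predicted maximum density at
#' the plot's own mean size, `R = N / exp(k + alpha ln Dg + beta ln Hg)`.
#' A plot on the boundary has `R = 1`; crowding increases with `R`. Unlike
#' [sdi_projected()], this quantity does not depend on a reference size.
#'
#' @inheritParams sdi_projected
#' @return numeric vector of relative densities (>= 0).
#' @export
relative_density <- function(plots, spec) {
  check_spec_fitted(spec)
  plots$tph / exp(frontier_log_density(spec, plots$qmd_cm, plots$dom_height_m))
}

#' Mortality against relative density
#'
#' Ordinary least squares of period mortality on relative density, the
#' diagnostic used to judge how well a fitted boundary orders stands by
#' crowding: steeper, tighter positive relationships indicate a boundary that
#' better separates self-thinning stands.
#'
#' @param pairs repeated-measurement pairs (from [plot_pairs()] or
#'   [simulate_stands()]); first-survey density and sizes are used.
#' @param spec fitted [thinning_model_spec()].
#' @return list with `slope`, `intercept`, `r2`, `p_value` (slope t-test) and
#'   the per-plot `rel_density` used.
#' @export
mortality_density_regression <- function(pairs, spec) {
  if (nrow(pairs) < 3) stopf("need at least 3 pairs")
  mort <- compute_mortality(pairs)
  plots0 <- data.frame(tph = pairs$tph0, qmd_cm = pairs$qmd0_cm,
                       dom_height_m = pairs$hd0_m)
  r <- relative_density(plots0, spec)
  if (stats::sd(r) == 0) stopf("relative density is constant: singular design")
  fit <- stats::lm(mort ~ r)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (stats::sd(mort) == 0) r2 <- 0  # constant mortality carries no signal
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = r2,
    p_value = sm$coefficients[2, 4],
    rel_density = r
  )
}
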
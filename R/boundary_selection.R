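#' Traditional boundary-point selection
#'
#' Before quantile or frontier methods, self-thinning lines were fitted by OLS
#' to hand-picked "boundary" plots. Four objective selection rules are
#' provided: equal-width intervals over `ln Dg` keeping the densest plots per
#' bin ([select_interval()]), a period-mortality threshold
#' ([select_mortality()]), a relative-density standard against a provisional
#' line ([select_relative_density()]), and the upper convex hull of the
#' `(ln Dg, ln N)` scatter ([select_upper_hull()], an objective surrogate for
#' the subjective visual method). [fit_ols_boundary()] then fits the boundary
#' to a selected subset.
#'
#' @name boundary_selection
NULL

new_selection <- function(method, plots, keep, params) {
  structure(list(
    method = method,
    selected_ids = plots$plot_id[keep],
    params = params,
    plots = plots[keep, , drop = FALSE]
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Boundary-point selection (%s): %d plots kept\n",
              x$method, length(x$selected_ids)))
  if (length(x$params)) {
    cat("  params:", paste(sprintf("%s=%s", names(x$params), unlist(x$params)),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Equal-width interval selection
#'
#' Splits the `ln Dg` range into `n_bins` equal-width bins and keeps the
#' `points_per_bin` densest plots (highest `ln N`) in each non-empty bin.
#' Ties are broken by plot id.
#'
#' @param plots plot table.
#' @param n_bins number of equal-width bins over `ln Dg` (>= 2).
#' @param points_per_bin plots kept per non-empty bin.
#' @return `selection_result`.
#' @export
select_interval <- function(plots, n_bins = 10L, points_per_bin = 1L) {
  plots <- plot_table(plots)
  if (n_bins < 2) stopf("n_bins must be at least 2")
  ld <- log(plots$qmd_cm)
  if (diff(range(ld)) == 0) stopf("fewer than 2 non-empty diameter bins")
  breaks <- seq(min(ld), max(ld), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(ld, breaks = breaks, labels = FALSE)
  if (length(unique(bin)) < 2) stopf("fewer than 2 non-empty diameter bins")
  ord <- order(bin, -log(plots$tph), plots$plot_id)
  keep_idx <- unlist(lapply(split(ord, bin[ord]), utils::head, points_per_bin),
                     use.names = FALSE)
  keep <- sort(keep_idx)
  new_selection("interval", plots, keep,
                list(n_bins = n_bins, points_per_bin = points_per_bin))
}

#' Mortality-threshold selection
#'
#' Keeps plots whose period mortality reached `threshold`; 20% is the
#' classical onset-of-self-thinning value for plantations, but in mixed
#' stands death from suppression and shading occurs below the density
#' ceiling, so the threshold is exposed for adjustment.
#'
#' @param pairs repeated-measurement pairs (first-survey variables are
#'   carried into the selection).
#' @param threshold mortality fraction (default 0.20); selection keeps
#'   `mortality >= threshold`.
#' @return `selection_result` whose `plots` slot holds first-survey variables.
#' @export
select_mortality <- function(pairs, threshold = 0.20) {
  mort <- compute_mortality(pairs)
  plots <- data.frame(plot_id = pairs$plot_id, year = pairs$year0,
                      tph = pairs$tph0, qmd_cm = pairs$qmd0_cm,
                      dom_height_m = pairs$hd0_m, stringsAsFactors = FALSE)
  plots <- plot_table(plots)
  keep <- which(mort >= threshold)
  out <- new_selection("mortality", plots, keep, list(threshold = threshold))
  out$mortality <- mort[keep]
  out
}

#' Relative-density selection
#'
#' Keeps plots at or above a relative-density `standard` computed against a
#' provisional fitted line (typically a mean OLS line through all plots);
#' `standard = 1` keeps plots at or beyond that line.
#'
#' @param plots plot table.
#' @param spec provisional fitted [thinning_model_spec()].
#' @param standard relative-density cutoff (default 1.0).
#' @return `selection_result`.
#' @export
select_relative_density <- function(plots, spec, standard = 1.0) {
  plots <- plot_table(plots)
  r <- relative_density(plots, spec)
  keep <- which(r >= standard)
  out <- new_selection("relative_density", plots, keep,
                       list(standard = standard))
  out$rel_density <- r[keep]
  out
}

#' Upper-hull selection
#'
#' Keeps the vertices of the upper convex hull of the `(ln Dg, ln N)` scatter
#' (Andrew's monotone chain): no plot lies above any chord between
#' consecutive selected plots. With collinear input the hull is degenerate
#' and the densest plot at each distinct diameter is returned.
#'
#' @param plots plot table (>= 3 plots).
#' @param drop_endpoints drop the two extreme-diameter hull endpoints, which
#'   have no neighbor on one side (default FALSE).
#' @return `selection_result`.
#' @export
select_upper_hull <- function(plots, drop_endpoints = FALSE) {
  plots <- plot_table(plots)
  if (nrow(plots) < 3) stopf("need at least 3 plots for a hull")
  x <- log(plots$qmd_cm); y <- log(plots$tph)
  # one point per distinct x: the densest (others can never be upper-hull vertices)
  ord <- order(x, -y, plots$plot_id)
  dup <- duplicated(x[ord])
  cand <- ord[!dup]
  if (length(cand) < 2) stopf("all plots share one diameter: no hull")
  # Andrew's monotone chain, upper chain only; points exactly on a chord are
  # kept, so collinear (degenerate) input returns every distinct diameter
  eps <- 1e-12 * max(diff(range(x)), diff(range(y)), 1)
  hull <- integer(0)
  for (i in cand) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross > eps) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  keep <- sort(hull)
  if (drop_endpoints && length(keep) > 2) {
    ends <- c(which.min(x[keep]), which.max(x[keep]))
    keep <- keep[-ends]
  }
  new_selection("upper_hull", plots, keep,
                list(drop_endpoints = drop_endpoints))
}

#' OLS boundary fit on selected plots
#'
#' Ordinary least squares of `ln N` on `ln Dg` (RM) or on `ln Dg` and
#' `ln Hd` (VDM) over the plots retained by a selection rule.
#'
#' @param selection a `selection_result` (or a plot table).
#' @param form `"RM"` or `"VDM"`.
#' @return fitted [thinning_model_spec()] with attributes `"r2"` and `"n"`.
#' @export
fit_ols_boundary <- function(selection, form = c("RM", "VDM")) {
  form <- match.arg(form)
  plots <- if (inherits(selection, "selection_result")) selection$plots else plot_table(selection)
  p <- if (form == "RM") 2L else 3L
  if (nrow(plots) < p + 1) stopf("need at least %d selected plots for %s", p + 1, form)
  X <- design_matrix(plots, form)
  if (qr(X)$rank < p) stopf("singular design on the selected plots")
  y <- log_density(plots)
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  spec <- if (form == "RM") {
    thinning_model_spec("RM", k = b[1], alpha = b[2])
  } else {
    thinning_model_spec("VDM", k = b[1], alpha = b[2], beta = b[3])
  }
  tss <- sum((y - mean(y))^2)
  attr(spec, "r2") <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  attr(spec, "n") <- nrow(plots)
  spec
}
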
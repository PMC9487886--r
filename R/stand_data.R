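#' Plot-level stand tables
#'
#' A plot table is a plain `data.frame` with one row per plot x survey year.
#' `plot_table()` validates (and lightly coerces) such a table. Mandatory
#' columns are `plot_id`, `year`, `tph` (stems per hectare), `qmd_cm`
#' (quadratic mean diameter, cm) and `dom_height_m` (dominant height, m, the
#' arithmetic mean height of the dominant trees). Optional columns:
#' `basal_area_m2ha`, `canopy_density` (fraction in \[0, 1\]),
#' `oak_fraction` (fraction in \[0, 1\]), `altitude_m`, `slope_deg`,
#' `species_tally` (list column of named stem counts) and `dbh_list_cm`
#' (list column of per-stem DBH values, minimum recording limit 5 cm).
#'
#' @param df data.frame to validate.
#' @return the validated data.frame, with missing optional columns added
#'   as `NA` (or empty list columns).
#' @export
plot_table <- function(df) {
  if (!is.data.frame(df)) stopf("plot table must be a data.frame")
  mandatory <- c("plot_id", "year", "tph", "qmd_cm", "dom_height_m")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stopf("plot table is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df$plot_id <- as.character(df$plot_id)
  for (col in c("year", "tph", "qmd_cm", "dom_height_m")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.finite(df$tph) | df$tph <= 0 |
               !is.finite(df$qmd_cm) | df$qmd_cm <= 0 |
               !is.finite(df$dom_height_m) | df$dom_height_m <= 0)
  if (length(bad)) {
    stopf("non-positive or missing tph/qmd_cm/dom_height_m in row(s): %s (plot id %s)",
          paste(bad, collapse = ", "),
          paste(df$plot_id[bad], collapse = ", "))
  }
  optional_num <- c("basal_area_m2ha", "canopy_density", "oak_fraction",
                    "altitude_m", "slope_deg")
  for (col in optional_num) {
    if (!col %in% names(df)) df[[col]] <- NA_real_ else df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("canopy_density", "oak_fraction")) {
    out <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(out)) stopf("%s outside [0, 1] in row(s): %s", col,
                           paste(out, collapse = ", "))
  }
  if (!"species_tally" %in% names(df)) df$species_tally <- replicate(nrow(df), NULL)
  if (!"dbh_list_cm" %in% names(df)) df$dbh_list_cm <- replicate(nrow(df), NULL)
  df
}

#' Read a plot table from CSV
#'
#' Reads one row per plot x year. Column names can be remapped with
#' `column_map` (a named character vector, `canonical = "file column"`).
#' Two encoded columns are unpacked if present: `species_tally` as
#' `"species:count;species:count"`, and `dbh_list_cm` as semicolon-separated
#' per-stem DBH values in cm.
#'
#' @param path CSV file path (with header).
#' @param column_map optional named character vector renaming file columns to
#'   the canonical names of [plot_table()].
#' @return validated plot table (data.frame).
#' @export
read_plot_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stopf("column_map names absent column '%s'", src)
      names(df)[names(df) == src] <- canon
    }
  }
  if ("species_tally" %in% names(df) && is.character(df$species_tally)) {
    df$species_tally <- lapply(df$species_tally, parse_species_tally)
  }
  if ("dbh_list_cm" %in% names(df) && is.character(df$dbh_list_cm)) {
    df$dbh_list_cm <- lapply(df$dbh_list_cm, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  plot_table(df)
}

parse_species_tally <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(counts) <- vapply(kv, `[`, character(1), 1)
  counts
}

#' Inclusion filters for mixed-oak plots
#'
#' Keeps plots with canopy density above `min_canopy`, stem density above
#' `min_tph`, and an oak share of at least `min_oak`. Canopy and density use
#' strict `>` ("higher than 0.60", "exceeded 500"); the oak share uses `>=`.
#' Rows with a missing filter variable are dropped. Counts of excluded plots
#' per rule are attached as attribute `"filter_counts"`.
#'
#' @param plots plot table.
#' @param min_canopy canopy-density threshold (default 0.60).
#' @param min_tph stems-per-hectare threshold (default 500).
#' @param min_oak minimum oak stem fraction (default 0.15).
#' @return filtered plot table.
#' @export
apply_inclusion_filters <- function(plots, min_canopy = 0.60, min_tph = 500,
                                    min_oak = 0.15) {
  plots <- plot_table(plots)
  ok_canopy <- !is.na(plots$canopy_density) & plots$canopy_density > min_canopy
  ok_tph <- plots$tph > min_tph
  ok_oak <- !is.na(plots$oak_fraction) & plots$oak_fraction >= min_oak
  keep <- ok_canopy & ok_tph & ok_oak
  out <- plots[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    input = nrow(plots),
    fail_canopy = sum(!ok_canopy),
    fail_tph = sum(!ok_tph),
    fail_oak = sum(!ok_oak),
    kept = sum(keep)
  )
  out
}

#' Build repeated-measurement pairs from two survey years
#'
#' Matches plots by `plot_id` across the two tables and attaches per-plot stem
#' counts and deaths. The stem count at the first survey is `n_stems0`
#' (stems actually tallied in the plot); `n_dead` is the number of those stems
#' that died between the surveys.
#'
#' @param t0,t1 plot tables for the first and second survey.
#' @param n_stems0 integer stems tallied at the first survey, one per matched
#'   plot (in `t0` order of the matched ids).
#' @param n_dead integer deaths between surveys, same length.
#' @return data.frame with one row per matched plot: identifiers, both years'
#'   density and size variables, `n_stems0`, `n_dead`.
#' @export
plot_pairs <- function(t0, t1, n_stems0, n_dead) {
  t0 <- plot_table(t0); t1 <- plot_table(t1)
  ids <- intersect(t0$plot_id, t1$plot_id)
  if (!length(ids)) stopf("no plot ids shared between the two surveys")
  i0 <- match(ids, t0$plot_id); i1 <- match(ids, t1$plot_id)
  if (length(n_stems0) != length(ids) || length(n_dead) != length(ids)) {
    stopf("n_stems0 and n_dead must have one value per matched plot (%d)", length(ids))
  }
  if (any(t0$year[i0] >= t1$year[i1])) stopf("first survey year must precede the second")
  if (any(n_dead < 0) || any(n_dead > n_stems0)) {
    stopf("n_dead must lie in [0, n_stems0] for every plot")
  }
  data.frame(
    plot_id = ids,
    year0 = t0$year[i0], year1 = t1$year[i1],
    tph0 = t0$tph[i0], tph1 = t1$tph[i1],
    qmd0_cm = t0$qmd_cm[i0], qmd1_cm = t1$qmd_cm[i1],
    hd0_m = t0$dom_height_m[i0], hd1_m = t1$dom_height_m[i1],
    n_stems0 = as.integer(n_stems0),
    n_dead = as.integer(n_dead),
    stringsAsFactors = FALSE
  )
}

#' Period mortality of a plot pair
#'
#' Mortality is the number of stems that died between the two surveys divided
#' by the stems present at the first survey.
#'
#' @param pairs data.frame from [plot_pairs()] (columns `n_dead`, `n_stems0`).
#' @return numeric vector of mortality fractions in \[0, 1\].
#' @export
compute_mortality <- function(pairs) {
  if (!all(c("n_dead", "n_stems0") %in% names(pairs))) {
    stopf("pairs must carry n_dead and n_stems0 columns")
  }
  if (any(pairs$n_stems0 <= 0)) stopf("mortality undefined for plots with no stems at t0")
  if (any(pairs$n_dead < 0 | pairs$n_dead > pairs$n_stems0)) {
    stopf("n_dead outside [0, n_stems0]")
  }
  pairs$n_dead / pairs$n_stems0
}

#' Split a plot table into modeling and validation sets
#'
#' Draws a random partition with `floor(frac * n)` plots for modeling and the
#' remainder for validation (265 plots at `frac = 0.7` give 185 / 80). The
#' split is deterministic for a given seed.
#'
#' @param plots plot table.
#' @param frac modeling fraction in (0, 1); default 0.7.
#' @param seed integer RNG seed.
#' @return list with elements `modeling` and `validation`.
#' @export
split_modeling_validation <- function(plots, frac = 0.7, seed = 1L) {
  plots <- plot_table(plots)
  n <- nrow(plots)
  if (n < 2) stopf("need at least 2 plots to split")
  if (!(frac > 0 && frac < 1)) stopf("frac must lie strictly between 0 and 1")
  n_model <- floor(frac * n + 1e-9)
  n_model <- max(1L, min(n - 1L, as.integer(n_model)))
  idx <- with_seed(seed, sample.int(n, n_model))
  modeling <- plots[sort(idx), , drop = FALSE]
  validation <- plots[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(modeling) <- rownames(validation) <- NULL
  list(modeling = modeling, validation = validation)
}
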
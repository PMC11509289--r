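#' Exceedance percentage of navigation errors
#'
#' Percentage of cases whose absolute error strictly exceeds a threshold
#' ("errors over 5 degrees" reads as strict inequality).
#'
#' @param errors numeric vector of signed errors.
#' @param threshold positive threshold (same units as `errors`).
#' @return Percentage in `[0, 100]`.
#' @export
exceedance <- function(errors, threshold) {
  if (!length(errors)) stop("no errors supplied", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  100 * sum(abs(errors) > threshold) / length(errors)
}

metric_columns <- c(
  anteversion_deg = "d_anteversion",
  inclination_deg = "d_inclination",
  depth_mm = "d_depth"
)

#' Summarise navigation errors into study statistics
#'
#' Per metric (anteversion and inclination in degrees, depth in mm): sample
#' mean, sample SD (n-1 denominator), min, max, and mean/SD of the absolute
#' errors, plus exceedance percentages at the given thresholds. This is the
#' "mean +/- SD of the navigation errors" machinery of a precision study
#' table.
#'
#' @param errors a `data.frame` of navigation errors with columns
#'   `d_anteversion`, `d_inclination`, `d_depth` (e.g. rows from
#'   [navigation_error()]).
#' @param thresholds numeric thresholds for exceedance percentages
#'   (degrees for the angle metrics, mm for depth).
#' @return An object of class `study_summary`: list with `n_cases`,
#'   `metrics` (per-metric named stats) and `exceedance` (per metric, named
#'   by threshold).
#' @export
summarize_errors <- function(errors, thresholds = c(5, 10)) {
  errors <- as.data.frame(errors)
  need <- unname(metric_columns)
  if (!all(need %in% names(errors))) {
    stop(
      "errors must contain columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(errors)
  if (n < 2L) {
    stop("at least 2 error rows are required (SD is undefined for n < 2)",
      call. = FALSE
    )
  }
  metrics <- lapply(metric_columns, function(col) {
    x <- errors[[col]]
    stopifnot_finite(x, col)
    c(
      mean = mean(x), sd = sd(x), min = min(x), max = max(x),
      abs_mean = mean(abs(x)), abs_sd = sd(abs(x))
    )
  })
  exc <- lapply(metric_columns, function(col) {
    out <- vapply(thresholds, function(th) exceedance(errors[[col]], th), 0)
    names(out) <- as.character(thresholds)
    out
  })
  structure(
    list(n_cases = n, metrics = metrics, exceedance = exc),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> N = %d\n", x$n_cases))
  print(format_summary(x), row.names = FALSE)
  invisible(x)
}

#' Render a study summary as a publication-style table
#'
#' One row per metric with Mean and SD columns, in the layout of a precision
#' study's navigation-error table.
#'
#' @param summary a `study_summary`.
#' @param digits decimals for the printed values.
#' @return A `data.frame` with columns `Metrics`, `Mean`, `SD`.
#' @export
format_summary <- function(summary, digits = 2) {
  stopifnot(inherits(summary, "study_summary"))
  lab <- c(
    anteversion_deg = "Anteversion (°)",
    inclination_deg = "Inclination (°)",
    depth_mm = "Depth (mm)"
  )
  data.frame(
    Metrics = unname(lab[names(summary$metrics)]),
    Mean = vapply(summary$metrics, function(m) {
      formatC(round(m[["mean"]], digits), format = "f", digits = digits)
    }, ""),
    SD = vapply(summary$metrics, function(m) {
      formatC(round(m[["sd"]], digits), format = "f", digits = digits)
    }, ""),
    row.names = NULL
  )
}

#' Study configuration
#'
#' @param mode `"interrater"` (each case contributes one error row per
#'   rater, emulating repeated alignments on the same side) or `"patient"`
#'   (one rater, one row per case).
#' @param n_cases number of simulated surgeries.
#' @param seed master study seed.
#' @param scene a template `scene_config`; each case derives its own seed
#'   from the study seed and the case index.
#' @param thresholds exceedance thresholds (degrees / mm).
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("patient", "interrater"), n_cases = 18L,
                         seed = 1L, scene = scene_config(),
                         thresholds = c(5, 10)) {
  mode <- match.arg(mode)
  stopifnot(n_cases >= 1L, inherits(scene, "scene_config"))
  if (mode == "patient") {
    scene$n_raters <- 1L
  }
  structure(
    list(
      mode = mode, n_cases = as.integer(n_cases), seed = as.integer(seed),
      scene = scene, thresholds = thresholds
    ),
    class = "study_config"
  )
}

#' Run a full simulated precision study
#'
#' Simulates `n_cases` surgeries, runs the whole pipeline on each (patient
#' alignment per rater, guide readout, post-op registration, navigation
#' errors), aggregates the study summary and, when `out_dir` is given,
#' writes `cases.csv` (one row per measurement), `summary.json`,
#' `boxplot.csv` (median, quartiles, whiskers per metric) and `scatter.csv`
#' (per-case error pairs). Fully deterministic for a given configuration.
#'
#' @param config a `study_config`.
#' @param out_dir optional output directory.
#' @param offset_deg deliberate guide-side anteversion offset (degrees),
#'   for linearity probes.
#' @return List with `errors` (data.frame), `summary` (`study_summary`),
#'   `failures` (per-case error messages, if any) and `files`.
#' @export
run_study <- function(config, out_dir = NULL, offset_deg = 0) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  failures <- character(0)
  for (i in seq_len(config$n_cases)) {
    scene <- config$scene
    scene$seed <- child_seed(config$seed, "study-case", i)
    res <- tryCatch(
      assess_case(simulate_case(scene), case_id = i, offset_deg = offset_deg),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("case %d: %s", i, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$errors
    }
  }
  if (!length(rows)) {
    stop("all cases failed:\n", paste(failures, collapse = "\n"), call. = FALSE)
  }
  errors <- do.call(rbind, rows)
  summary <- summarize_errors(errors, config$thresholds)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_cases <- file.path(out_dir, "cases.csv")
    write.csv(format_numeric_df(errors), f_cases, row.names = FALSE, quote = FALSE)
    f_summary <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      summary_to_list(summary, config),
      f_summary,
      digits = 10, auto_unbox = TRUE
    )
    f_box <- file.path(out_dir, "boxplot.csv")
    write.csv(format_numeric_df(boxplot_data(errors)), f_box,
      row.names = FALSE, quote = FALSE
    )
    f_scatter <- file.path(out_dir, "scatter.csv")
    scatter <- errors[, c(
      "case_id", "rater_id", "d_anteversion", "d_inclination", "d_depth"
    )]
    write.csv(format_numeric_df(scatter), f_scatter, row.names = FALSE, quote = FALSE)
    files <- c(cases = f_cases, summary = f_summary, boxplot = f_box, scatter = f_scatter)
  }
  list(errors = errors, summary = summary, failures = failures, files = files)
}

# round-trip-stable numeric formatting so identical runs give identical bytes
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.10g", df[[nm]])
    }
  }
  df
}

summary_to_list <- function(summary, config = NULL) {
  out <- list(
    n_cases = summary$n_cases,
    metrics = lapply(summary$metrics, as.list),
    exceedance = lapply(summary$exceedance, as.list)
  )
  if (!is.null(config)) {
    out$config <- list(
      mode = config$mode, n_cases = config$n_cases, seed = config$seed,
      scene_seed = config$scene$seed,
      point_noise_sigma_mm = config$scene$point_noise_sigma_mm,
      n_points = config$scene$n_points, n_raters = config$scene$n_raters,
      thresholds = config$thresholds
    )
  }
  out
}

#' Boxplot-ready quantile export of navigation errors
#'
#' Median, quartiles and Tukey whiskers (last observations within 1.5 IQR of
#' the quartiles) per metric — the data behind a navigation-error boxplot.
#'
#' @param errors navigation-error `data.frame`.
#' @return A `data.frame`, one row per metric.
#' @export
boxplot_data <- function(errors) {
  errors <- as.data.frame(errors)
  rows <- lapply(names(metric_columns), function(metric) {
    x <- errors[[metric_columns[[metric]]]]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lw <- min(x[x >= q[1] - 1.5 * iqr])
    uw <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(
      metric = metric, lower_whisker = lw, q1 = q[1], median = q[2],
      q3 = q[3], upper_whisker = uw, n = length(x)
    )
  })
  do.call(rbind, rows)
}

#' Build a study configuration from a plain list (e.g. parsed YAML)
#'
#' @param lst named list with optional `mode`, `n_cases`, `seed`,
#'   `thresholds` and a nested `scene` list of `scene_config` fields.
#' @return A `study_config`.
#' @export
study_config_from_list <- function(lst) {
  scene <- if (is.null(lst$scene)) scene_config() else scene_config_from_list(lst$scene)
  study_config(
    mode = lst$mode %||% "patient",
    n_cases = lst$n_cases %||% 18L,
    seed = lst$seed %||% 1L,
    scene = scene,
    thresholds = unlist(lst$thresholds %||% c(5, 10))
  )
}
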
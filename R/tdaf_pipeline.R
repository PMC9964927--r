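#' Run the time-dispersion feature analysis
#'
#' End-to-end orchestration: every voltage series is cut into overlapping
#' sub-minute windows, the per-window features are extracted, and for each
#' class code and feature the values are pooled by time bin into
#' dispersion summaries (min, quartiles, median, max).  A window failing
#' one extractor (e.g. a constant window under DFA) contributes a missing
#' value to its bin only; the number of missing values per report is
#' recorded, and bins where fewer than half the pooled values are valid
#' are flagged.
#'
#' @param x Either a manifest data frame (columns `file`, `class`,
#'   `treatment`, `tissue`, `phase`, optionally `kind`; rows with
#'   `kind == "turgor"` are ignored) or a list of [voltage_series()]
#'   objects.
#' @param config A [tdaf_config()].
#' @param data_dir Directory that manifest file paths are relative to.
#' @return A named list of `tdaf_report` objects, one per class x feature,
#'   named `"<class>.<feature>"`.  Each report carries `class_code`,
#'   `feature_name`, `summaries` (see [summarize_bins()], plus a `flagged`
#'   column), `window_seconds`, `delay_fraction`, `step_seconds`,
#'   `n_series` and `n_missing`.  The pooled per-window feature table is
#'   attached as attribute `"features"`.
#' @export
run_tdaf <- function(x, config = tdaf_config(), data_dir = ".") {
  series_list <- if (is.data.frame(x)) {
    v <- x
    if ("kind" %in% names(v)) v <- v[v$kind != "turgor", , drop = FALSE]
    if (nrow(v) == 0L) stop("manifest contains no voltage series")
    lapply(seq_len(nrow(v)), function(i) {
      read_series(file.path(data_dir, v$file[i]),
                  treatment = v$treatment[i], tissue = v$tissue[i],
                  phase = v$phase[i])
    })
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "voltage_series"))) {
    x
  } else {
    stop("'x' must be a manifest data frame or a list of voltage_series")
  }
  if (length(series_list) == 0L) stop("no input series")

  labels <- vapply(series_list, `[[`, character(1), "label")
  feat_rows <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    srs <- series_list[[i]]
    slices <- slice_windows(srs, config$window_seconds,
                            config$delay_fraction)
    sigma_series <- stats::sd(srs$samples)
    rows <- lapply(slices, extract_features, config = config,
                   series_sigma = sigma_series)
    tab <- do.call(rbind, rows)
    tab$series_id <- i
    tab$class <- srs$label
    feat_rows[[i]] <- tab
  }
  features <- do.call(rbind, feat_rows)

  feature_cols <- setdiff(names(features),
                          c("bin_index", "start_time", "series_id", "class"))
  reports <- list()
  for (cls in unique(labels)) {
    in_cls <- which(labels == cls)
    fs_vals <- unique(vapply(series_list[in_cls], `[[`, numeric(1), "fs"))
    if (length(fs_vals) != 1L) {
      stop("heterogeneous sampling rates within class ", cls)
    }
    lens <- unique(vapply(series_list[in_cls],
                          function(s) length(s$samples), integer(1)))
    if (length(lens) != 1L) {
      stop("heterogeneous series lengths within class ", cls)
    }
    w <- floor(config$window_seconds * fs_vals)
    step_seconds <- floor((1 - config$delay_fraction) * w) / fs_vals
    cls_tab <- features[features$class == cls, , drop = FALSE]
    for (fname in feature_cols) {
      summ <- summarize_bins(cls_tab, fname)
      n_expected <- length(in_cls)
      summ$flagged <- summ$n_values < 0.5 * n_expected
      n_missing <- sum(is.na(cls_tab[[fname]]))
      rep_obj <- structure(
        list(class_code = cls, feature_name = fname, summaries = summ,
             window_seconds = config$window_seconds,
             delay_fraction = config$delay_fraction,
             step_seconds = step_seconds,
             n_series = n_expected, n_missing = n_missing),
        class = "tdaf_report")
      reports[[paste(cls, fname, sep = ".")]] <- rep_obj
    }
  }
  attr(reports, "features") <- features
  reports
}

#' @export
print.tdaf_report <- function(x, ...) {
  cat(sprintf(
    "<tdaf_report> %s / %s: %d bins x %d series (%d missing values)\n",
    x$class_code, x$feature_name, nrow(x$summaries), x$n_series,
    x$n_missing))
  invisible(x)
}

#' Compare dispersion reports before versus after a stimulus
#'
#' Produces the per-bin table of median feature values before and after
#' and their difference, plus the mean median-difference over the early
#' effect window (bins starting within the first `effect_window_s`
#' seconds, 10 minutes by default).
#'
#' @param report_before,report_after `tdaf_report` objects for the same
#'   feature with identical bin structure.
#' @param effect_window_s Length of the early effect window in seconds.
#' @return A list of class `phase_comparison` with elements `table`
#'   (`bin_index`, `start_time`, `median_before`, `median_after`, `diff`),
#'   `feature_name`, `effect_window_s`, `effect_bins` and
#'   `effect_mean_diff`.
#' @export
compare_phases <- function(report_before, report_after,
                           effect_window_s = 600) {
  stopifnot(inherits(report_before, "tdaf_report"),
            inherits(report_after, "tdaf_report"))
  if (report_before$feature_name != report_after$feature_name) {
    stop("reports describe different features")
  }
  sb <- report_before$summaries
  sa <- report_after$summaries
  if (nrow(sb) != nrow(sa) || !all(sb$bin_index == sa$bin_index)) {
    stop("mismatched bin structure between phases")
  }
  start_time <- sb$bin_index * report_before$step_seconds
  tab <- data.frame(
    bin_index = sb$bin_index,
    start_time = start_time,
    median_before = sb$median,
    median_after = sa$median,
    diff = sa$median - sb$median
  )
  eff <- tab$start_time < effect_window_s
  structure(
    list(table = tab, feature_name = report_before$feature_name,
         effect_window_s = effect_window_s,
         effect_bins = sum(eff),
         effect_mean_diff = mean(tab$diff[eff], na.rm = TRUE)),
    class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf(
    "<phase_comparison> %s: mean median-difference over first %g min = %.4g (%d bins)\n",
    x$feature_name, x$effect_window_s / 60, x$effect_mean_diff,
    x$effect_bins))
  invisible(x)
}

#' Plot a dispersion report
#'
#' Median line with an inter-quartile ribbon and a lighter min-max ribbon
#' per time bin, the standard presentation of time-binned feature
#' dispersion.
#'
#' @param report A `tdaf_report`.
#' @param path Optional output file; written with [ggplot2::ggsave()].
#' @return The ggplot object, invisibly if written to file.
#' @export
plot_tdaf <- function(report, path = NULL) {
  stopifnot(inherits(report, "tdaf_report"))
  s <- report$summaries
  if (nrow(s) == 0L) stop("empty report")
  s$minutes <- s$bin_index * report$step_seconds / 60
  p <- ggplot2::ggplot(s, ggplot2::aes(x = minutes)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = minimum, ymax = maximum),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q1, ymax = q3),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = median), linewidth = 0.5) +
    ggplot2::labs(x = "time (min)", y = report$feature_name,
                  title = sprintf("%s / %s", report$class_code,
                                  report$feature_name)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
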
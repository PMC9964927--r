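#' Derive the class code of a series from its design labels
#'
#' Electrome recordings are labeled by whether the plant was stimulated
#' (treated vs control), which tissue carried the electrodes (local =
#' stimulated leaf, systemic = distant leaf) and the recording phase
#' (before vs after the stimulus).  The eight resulting codes are
#' `tlb, tla, tsb, tsa, clb, cla, csb, csa`.
#'
#' @param treatment One of `"W"`, `"HS"`, `"W_HS"`, `"CONTROL"`.
#' @param tissue One of `"LOCAL"`, `"SYSTEMIC"`.
#' @param phase One of `"BEFORE"`, `"AFTER"`.
#' @return A three-letter class code.
#' @examples
#' class_label("W", "LOCAL", "BEFORE")    # "tlb"
#' class_label("CONTROL", "SYSTEMIC", "AFTER")  # "csa"
#' @export
class_label <- function(treatment, tissue, phase) {
  treatment <- match.arg(treatment, TREATMENTS)
  tissue <- match.arg(tissue, TISSUES)
  phase <- match.arg(phase, PHASES)
  paste0(
    if (treatment == "CONTROL") "c" else "t",
    if (tissue == "LOCAL") "l" else "s",
    if (phase == "BEFORE") "b" else "a"
  )
}

#' Construct a voltage time series
#'
#' A `voltage_series` is one channel of microvolt samples at a fixed
#' sampling rate together with its experimental-design metadata.
#'
#' @param samples Numeric vector of voltage samples in microvolts.
#' @param fs Sampling frequency in Hz (default 62.5).
#' @param treatment,tissue,phase Design labels, see [class_label()].
#' @return An object of class `voltage_series`: a list with elements
#'   `samples`, `fs`, `treatment`, `tissue`, `phase` and the derived `label`.
#' @export
voltage_series <- function(samples, fs = 62.5,
                           treatment = "CONTROL", tissue = "LOCAL",
                           phase = "BEFORE") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (anyNA(samples)) stop("'samples' must not contain NA")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  structure(
    list(
      samples = samples, fs = fs,
      treatment = match.arg(treatment, TREATMENTS),
      tissue = match.arg(tissue, TISSUES),
      phase = match.arg(phase, PHASES),
      label = class_label(treatment, tissue, phase)
    ),
    class = "voltage_series"
  )
}

#' @export
print.voltage_series <- function(x, ...) {
  cat(sprintf(
    "<voltage_series> %s: %d samples @ %g Hz (%.1f s), sd %.3g uV\n",
    x$label, length(x$samples), x$fs, length(x$samples) / x$fs,
    stats::sd(x$samples)
  ))
  invisible(x)
}

#' Read a voltage series from a delimited text file
#'
#' Accepts either a two-column file (`time_s`, `voltage_uV`) or a
#' single-column file (`voltage_uV`); a header line is expected.  The
#' delimiter is inferred from the extension (`.tsv`/`.txt` use tab,
#' everything else comma).  Samples are kept in file order; no resampling.
#'
#' @param path Path to the file.
#' @param fs Sampling frequency in Hz, used as-is for single-column files
#'   and attached to the result either way.
#' @inheritParams voltage_series
#' @return A [voltage_series()].
#' @export
read_series <- function(path, fs = 62.5, treatment = "CONTROL",
                        tissue = "LOCAL", phase = "BEFORE") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty input file: ", path)
  vcol <- if ("voltage_uV" %in% names(raw)) "voltage_uV" else names(raw)[ncol(raw)]
  v <- suppressWarnings(as.numeric(raw[[vcol]]))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("non-numeric voltage value at data line %d of %s", bad, path))
  }
  voltage_series(v, fs = fs, treatment = treatment, tissue = tissue,
                 phase = phase)
}

#' Write a voltage series to a delimited text file
#'
#' Writes `time_s,voltage_uV` rows with fixed 6-decimal formatting so that
#' [read_series()] inverts the write exactly on the voltage column.
#'
#' @param series A [voltage_series()].
#' @param path Output path; the extension selects the delimiter as in
#'   [read_series()].
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "voltage_series"))
  if (length(series$samples) == 0L) stop("refusing to write an empty series")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  n <- length(series$samples)
  t_s <- (seq_len(n) - 1L) / series$fs
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("time_s", "voltage_uV", sep = sep), con)
  writeLines(sprintf("%.6f%s%.6f", t_s, sep, series$samples), con)
  invisible(path)
}

#' Cut a series into overlapping sub-minute windows
#'
#' The dispersion analysis works on windows shorter than one minute taken
#' with a 20 % overlap ("delay") between consecutive windows, which
#' suppresses trends introduced by the cut points.  Window length is
#' `floor(window_seconds * fs)` samples and the hop is
#' `floor((1 - delay_fraction) * w)` samples; a trailing partial window is
#' discarded.
#'
#' @param series A [voltage_series()].
#' @param window_seconds Window length in seconds, must be `< 60`
#'   (default 48).
#' @param delay_fraction Overlap fraction in `(0, 1)` (default 0.2).
#' @return A list of `window_slice` objects, each a list with `bin_index`
#'   (0-based), `start_time` (seconds), `samples` and `fs`.
#' @examples
#' s <- voltage_series(sin(seq_len(6250)), fs = 62.5)
#' length(slice_windows(s))  # windows of 3000 samples, hop 2400
#' @export
slice_windows <- function(series, window_seconds = 48, delay_fraction = 0.2) {
  stopifnot(inherits(series, "voltage_series"))
  if (window_seconds >= 60) {
    stop("'window_seconds' must be below 60 (sub-minute windows)")
  }
  if (window_seconds <= 0) stop("'window_seconds' must be positive")
  if (delay_fraction <= 0 || delay_fraction >= 1) {
    stop("'delay_fraction' must lie in (0, 1)")
  }
  w <- floor(window_seconds * series$fs)
  s <- floor((1 - delay_fraction) * w)
  n <- length(series$samples)
  if (n < w) {
    stop(sprintf("series too short: %d samples, one window needs %d", n, w))
  }
  n_win <- (n - w) %/% s + 1L
  lapply(seq_len(n_win) - 1L, function(k) {
    off <- k * s
    structure(
      list(
        bin_index = k,
        start_time = off / series$fs,
        samples = series$samples[(off + 1L):(off + w)],
        fs = series$fs
      ),
      class = "window_slice"
    )
  })
}

#' Pool a per-window feature across series into per-bin dispersion summaries
#'
#' All windows sharing a `bin_index` (i.e. the same position in time across
#' the recordings of one class) are pooled and summarized by their minimum,
#' quartiles, median and maximum.  Quartiles use linear interpolation
#' between order statistics (type 7).
#'
#' @param features A data frame with at least `bin_index` and the named
#'   feature column, typically from [extract_features()] rows bound together.
#' @param feature_name Name of the feature column to summarize.
#' @return A data frame ordered by `bin_index` with columns `bin_index`,
#'   `n_values`, `minimum`, `q1`, `median`, `q3`, `maximum`.
#' @export
summarize_bins <- function(features, feature_name) {
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stop("'features' must be a non-empty data frame")
  }
  if (!feature_name %in% names(features)) {
    stop("unknown feature: ", feature_name)
  }
  if (!"bin_index" %in% names(features)) stop("'features' lacks 'bin_index'")
  vals <- split(features[[feature_name]], features$bin_index)
  out <- lapply(names(vals), function(b) {
    v <- vals[[b]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(data.frame(bin_index = as.integer(b), n_values = 0L,
                        minimum = NA_real_, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_, maximum = NA_real_))
    }
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
    data.frame(bin_index = as.integer(b), n_values = length(v),
               minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
               maximum = q[5])
  })
  out <- do.call(rbind, out)
  out[order(out$bin_index), , drop = FALSE]
}
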
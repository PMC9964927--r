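#' Construct a turgor (patch-pressure) series
#'
#' @param samples Pressure values in relative probe units.
#' @param sample_interval_s Sampling interval in seconds (default 10).
#' @param stimulus_time_s Stimulus time in seconds from the series start;
#'   must lie within the series span.
#' @param treatment Optional treatment label.
#' @return An object of class `turgor_series`.
#' @export
turgor_series <- function(samples, sample_interval_s = 10,
                          stimulus_time_s, treatment = "CONTROL") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  span <- (length(samples) - 1L) * sample_interval_s
  if (stimulus_time_s < 0 || stimulus_time_s > span) {
    stop("'stimulus_time_s' must lie within the series span")
  }
  structure(
    list(samples = samples, sample_interval_s = sample_interval_s,
         stimulus_time_s = stimulus_time_s,
         treatment = match.arg(treatment, TREATMENTS)),
    class = "turgor_series"
  )
}

#' @export
print.turgor_series <- function(x, ...) {
  cat(sprintf(
    "<turgor_series> %s: %d samples every %g s, stimulus at %g s\n",
    x$treatment, length(x$samples), x$sample_interval_s, x$stimulus_time_s))
  invisible(x)
}

#' Read / write turgor series as delimited text
#'
#' Files carry a `time_s,pressure` header.
#'
#' @param path File path.
#' @param stimulus_time_s,treatment Metadata attached on read.
#' @return `read_turgor` returns a [turgor_series()]; `write_turgor`
#'   invisibly returns `path`.
#' @export
read_turgor <- function(path, stimulus_time_s = NULL, treatment = "CONTROL") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) < 2L) stop("turgor file needs at least 2 samples")
  dt <- raw$time_s[2L] - raw$time_s[1L]
  if (is.null(stimulus_time_s)) {
    stimulus_time_s <- (nrow(raw) - 1L) * dt / 2
  }
  turgor_series(raw$pressure, sample_interval_s = dt,
                stimulus_time_s = stimulus_time_s, treatment = treatment)
}

#' @rdname read_turgor
#' @param series A [turgor_series()].
#' @export
write_turgor <- function(series, path) {
  stopifnot(inherits(series, "turgor_series"))
  n <- length(series$samples)
  t_s <- (seq_len(n) - 1L) * series$sample_interval_s
  utils::write.csv(data.frame(time_s = t_s, pressure = series$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Normalize a turgor series to percent of its initial pressure
#'
#' Each value becomes `100 * value / first value`, so the series starts
#' at exactly 100 %.  Normalizing twice is a no-op.
#'
#' @param series A [turgor_series()].
#' @return The series with normalized samples.
#' @examples
#' s <- turgor_series(c(10, 12, 8), stimulus_time_s = 10)
#' normalize_percent(s)$samples  # 100 120 80
#' @export
normalize_percent <- function(series) {
  stopifnot(inherits(series, "turgor_series"))
  p0 <- series$samples[1L]
  if (p0 == 0) stop("degenerate input: first sample is zero")
  series$samples <- 100 * series$samples / p0
  series
}

#' Percent coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.  The
#' statistic is invariant to positive rescaling but not to mean shifts,
#' and inherits the sign of the mean.
#'
#' @param values Numeric vector of at least 2 values with non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(100, 120, 80))  # 20
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  100 * stats::sd(values) / m
}

#' Coefficient of variation before versus after the stimulus
#'
#' The series is percent-normalized, split at `stimulus_time_s` (the
#' boundary sample counts as "after": stimulus effects begin at
#' application), and each side's percent CV is returned.
#'
#' @param series A [turgor_series()].
#' @return Named numeric vector `c(cv_before_pct, cv_after_pct)`.
#' @export
before_after_cv <- function(series) {
  stopifnot(inherits(series, "turgor_series"))
  norm <- normalize_percent(series)
  t <- (seq_along(norm$samples) - 1L) * norm$sample_interval_s
  before <- norm$samples[t < norm$stimulus_time_s]
  after <- norm$samples[t >= norm$stimulus_time_s]
  if (length(before) < 2L || length(after) < 2L) {
    stop("need at least 2 samples on each side of the stimulus")
  }
  c(cv_before_pct = coefficient_of_variation(before),
    cv_after_pct = coefficient_of_variation(after))
}
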
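#' Approximate entropy parameters
#'
#' Defaults follow the common electrophysiology choice for short windows:
#' embedding dimension `m = 2`, lag `tau = 1` and tolerance
#' `r = r_coef * sigma` with `r_coef = 0.02`, where `sigma` is the standard
#' deviation of the analyzed window.  `r_coef = 0.02` is unusually strict
#' compared with the 0.1-0.25 range typical in the entropy literature, so it
#' is exposed as a first-class knob; `sigma_scope` selects whether `sigma`
#' is taken per analyzed window (default) or fixed per parent series.
#'
#' @param m Embedding dimension, integer `>= 1`.
#' @param tau Embedding lag in samples, integer `>= 1`.
#' @param r_coef Tolerance as a multiple of the standard deviation.
#' @param sigma_scope `"window"` or `"series"`.
#' @return A list of class `apen_params`.
#' @export
apen_params <- function(m = 2L, tau = 1L, r_coef = 0.02,
                        sigma_scope = c("window", "series")) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L) stop("'m' must be >= 1")
  if (tau < 1L) stop("'tau' must be >= 1")
  if (!is.numeric(r_coef) || r_coef <= 0) stop("'r_coef' must be positive")
  structure(list(m = m, tau = tau, r_coef = r_coef,
                 sigma_scope = match.arg(sigma_scope)),
            class = "apen_params")
}

#' Approximate entropy of a sequence
#'
#' Regularity statistic `Phi_m(r) - Phi_{m+1}(r)` where `Phi_m(r)` is the
#' mean over the `M = N - (m - 1) * tau` embedding vectors of the natural
#' log of the fraction of vectors within Chebyshev distance `r` (the
#' self-match is included, so counts are never zero).  Low values indicate
#' regular, nearly deterministic dynamics; high values irregular ones.
#'
#' @param x Numeric sequence.
#' @param m Embedding dimension (default 2).
#' @param tau Embedding lag in samples (default 1).
#' @param r Absolute tolerance.  If `NULL` (default), `r = r_coef * sd(x)`.
#' @param r_coef Tolerance coefficient used when `r` is `NULL`.
#' @return A single non-negative number (clamped at 0 against floating
#'   point round-off).  Constant input returns 0 directly.
#' @examples
#' approximate_entropy(rep(1, 500))            # 0, fully regular
#' set.seed(1); approximate_entropy(rnorm(300))
#' @export
approximate_entropy <- function(x, m = 2L, tau = 1L, r = NULL,
                                r_coef = 0.02) {
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L) stop("'m' must be >= 1")
  if (tau < 1L) stop("'tau' must be >= 1")
  N <- length(x)
  if (N < m * tau + 2L) {
    stop(sprintf("sequence too short for ApEn: N = %d, need > %d",
                 N, m * tau + 1L))
  }
  sigma <- stats::sd(x)
  if (sigma == 0) return(0)
  if (is.null(r)) r <- r_coef * sigma
  if (!is.numeric(r) || r <= 0) stop("'r' must be positive")
  max(0, .apen_impl(x, m, tau, r))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Mean-centers and cumulatively sums the input (the profile), partitions
#' the profile into non-overlapping boxes of each size, removes a
#' least-squares linear trend per box, and records the RMS residual
#' fluctuation `F(s)` per box size `s`.  The scaling exponent `alpha` is
#' the slope of the least-squares fit of `log2 F(s)` against `log2 s`.
#'
#' Interpretation of `alpha`: about 0.5 for uncorrelated noise, between
#' 0.5 and 1 for persistent (positively correlated) stationary signals,
#' below 0.5 for anti-persistent ones, and above 1 for non-stationary
#' signals of fractional-Brownian type (Hurst exponent `H = alpha - 1`).
#'
#' @param x Numeric sequence of length `>= 64`.
#' @param box_sizes Optional integer vector of box sizes.  Default:
#'   16 log-spaced sizes from 4 to `length(x) / 4`.
#' @return A list of class `dfa_result` with `alpha`, `box_sizes` and
#'   `fluctuations`.
#' @examples
#' set.seed(1)
#' dfa_alpha(rnorm(4096))$alpha          # close to 0.5
#' dfa_alpha(cumsum(rnorm(4096)))$alpha  # close to 1.5
#' @export
dfa_alpha <- function(x, box_sizes = NULL) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 64L) stop("DFA needs at least 64 samples, got ", N)
  if (stats::sd(x) == 0) stop("degenerate input: zero variance")
  if (is.null(box_sizes)) {
    box_sizes <- unique(round(2^seq(2, log2(N / 4), length.out = 16L)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes >= 4L & box_sizes <= N %/% 2L]
  prof <- cumsum(x - mean(x))
  fluct <- vapply(box_sizes, function(s) {
    nb <- N %/% s
    m <- matrix(prof[seq_len(nb * s)], nrow = s)
    tc <- seq_len(s) - (s + 1) / 2          # centered time within a box
    slope <- colSums(m * tc) / sum(tc^2)
    res <- m - rep(colMeans(m), each = s) - outer(tc, slope)
    sqrt(mean(res^2))
  }, numeric(1))
  keep <- is.finite(fluct) & fluct > 0
  if (sum(keep) < 4L) stop("fewer than 4 usable box sizes")
  box_sizes <- box_sizes[keep]; fluct <- fluct[keep]
  fit <- stats::lm(log2(fluct) ~ log2(box_sizes))
  structure(
    list(alpha = unname(stats::coef(fit)[2L]),
         box_sizes = box_sizes, fluctuations = fluct),
    class = "dfa_result"
  )
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: 512-sample Hann-windowed segments with
#' 50 % overlap, per-segment mean removal, density scaling.  The one-sided
#' grid runs from 0 to the Nyquist frequency in steps of `fs / nperseg`
#' (about 0.122 Hz at 62.5 Hz sampling), which resolves a 0-0.5 Hz band
#' with at least 4 grid points.
#'
#' @param x Numeric sequence, at least `nperseg` samples.
#' @param fs Sampling frequency in Hz.
#' @param nperseg Segment length in samples (default 512).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A list with `frequencies` (Hz) and `psd` (power density,
#'   signal-units squared per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 512L, overlap = 0.5) {
  x <- as.numeric(x)
  nperseg <- as.integer(nperseg)
  N <- length(x)
  if (N < nperseg) {
    stop(sprintf("input shorter than one segment (%d < %d)", N, nperseg))
  }
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / nperseg)
  starts <- seq(1L, N - nperseg + 1L, by = step)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / length(starts) / (fs * sum(win^2))
  # one-sided: double everything except DC and (for even nperseg) Nyquist
  dbl <- seq(2L, nf - if (nperseg %% 2L == 0L) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(frequencies = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Default spectral band table
#'
#' EEG-style bands used for electrome band power: low (0-0.5 Hz),
#' delta (0.5-4), theta (4-8), alpha (8-12) and beta (12-30 Hz).
#' The 30-100 Hz gamma band is omitted: it lies above the 31.25 Hz
#' Nyquist frequency of a 62.5 Hz recording.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("low", "delta", "theta", "alpha", "beta"),
    f_lo = c(0, 0.5, 4, 8, 12),
    f_hi = c(0.5, 4, 8, 12, 30),
    stringsAsFactors = FALSE
  )
}

# Composite Simpson integral over a uniformly spaced grid; an even number
# of points uses Simpson on the first n-1 plus a trapezoid on the last
# interval.  Two points fall back to the trapezoid rule.
simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(0)
  if (n == 2L) return(h * (y[1] + y[2]) / 2)
  if (n %% 2L == 0L) {
    return(simpson_uniform(y[-n], h) + h * (y[n - 1L] + y[n]) / 2)
  }
  i <- seq(2L, n - 1L)
  h / 3 * (y[1] + y[n] + sum(y[i] * ifelse(i %% 2L == 0L, 4, 2)))
}

#' Band-integrated spectral power
#'
#' Integrates the PSD over the grid points whose frequency falls inside
#' `[f_lo, f_hi]` (the upper edge is clipped to the Nyquist frequency)
#' using the composite Simpson rule; with fewer than 3 in-band points the
#' trapezoid rule is used and a warning is emitted.
#'
#' @param frequencies Frequency grid in Hz (uniform spacing).
#' @param psd Power density on that grid.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi`.
#' @return Band power (signal-units squared), non-negative.
#' @export
average_band_power <- function(frequencies, psd, f_lo, f_hi) {
  stopifnot(length(frequencies) == length(psd))
  if (f_lo < 0 || f_hi <= f_lo) stop("need 0 <= f_lo < f_hi")
  nyq <- max(frequencies)
  if (f_lo >= nyq) {
    stop(sprintf("band [%g, %g] Hz lies above Nyquist (%g Hz)",
                 f_lo, f_hi, nyq))
  }
  f_hi <- min(f_hi, nyq)
  inb <- which(frequencies >= f_lo & frequencies <= f_hi)
  if (length(inb) < 2L) stop("fewer than 2 PSD points in band")
  h <- frequencies[2L] - frequencies[1L]
  if (length(inb) < 3L) {
    warning("fewer than 3 PSD points in band; using trapezoid rule")
    return(h * (psd[inb[1]] + psd[inb[2]]) / 2)
  }
  simpson_uniform(psd[inb], h)
}

#' Feature-extraction configuration
#'
#' Bundles the windowing and per-window feature settings used by the
#' pipeline.
#'
#' @param window_seconds,delay_fraction Windowing, see [slice_windows()].
#' @param apen Approximate-entropy settings, see [apen_params()].
#' @param bands Band table as from [default_bands()].
#' @param features Character subset of `c("apen", "dfa", "abp")` to compute.
#' @param nperseg Welch segment length; capped at the window length.
#' @return A list of class `tdaf_config`.
#' @export
tdaf_config <- function(window_seconds = 48, delay_fraction = 0.2,
                        apen = apen_params(), bands = default_bands(),
                        features = c("apen", "dfa", "abp"),
                        nperseg = 512L) {
  features <- match.arg(features, c("apen", "dfa", "abp"),
                        several.ok = TRUE)
  structure(list(window_seconds = window_seconds,
                 delay_fraction = delay_fraction, apen = apen,
                 bands = bands, features = features,
                 nperseg = as.integer(nperseg)),
            class = "tdaf_config")
}

#' Extract the per-window feature vector
#'
#' Computes approximate entropy, the DFA scaling exponent and the band
#' powers of one window and returns them as a single data-frame row.  A
#' degenerate window (e.g. constant input for DFA) yields `NA` for the
#' affected feature rather than an error.
#'
#' @param slice A `window_slice` from [slice_windows()], or any list with
#'   `samples`, `fs`, `bin_index`, `start_time`.
#' @param config A [tdaf_config()].
#' @param series_sigma Standard deviation of the parent series; used for
#'   the ApEn tolerance when `config$apen$sigma_scope == "series"`.
#' @return A one-row data frame: `bin_index`, `start_time`, `apen`,
#'   `dfa_alpha`, and one `abp_<band>` column per configured band.
#' @export
extract_features <- function(slice, config = tdaf_config(),
                             series_sigma = NULL) {
  x <- slice$samples
  out <- data.frame(bin_index = slice$bin_index,
                    start_time = slice$start_time)
  ap <- config$apen
  if ("apen" %in% config$features) {
    r <- if (ap$sigma_scope == "series" && !is.null(series_sigma)) {
      ap$r_coef * series_sigma
    } else NULL  # per-window sigma handled inside approximate_entropy
    out$apen <- if (stats::sd(x) == 0) 0 else {
      approximate_entropy(x, m = ap$m, tau = ap$tau, r = r,
                          r_coef = ap$r_coef)
    }
  }
  if ("dfa" %in% config$features) {
    out$dfa_alpha <- tryCatch(dfa_alpha(x)$alpha, error = function(e) NA_real_)
  }
  if ("abp" %in% config$features) {
    nseg <- min(config$nperseg, length(x))
    pw <- welch_psd(x, fs = slice$fs, nperseg = nseg)
    for (i in seq_len(nrow(config$bands))) {
      b <- config$bands[i, ]
      out[[paste0("abp_", b$name)]] <-
        average_band_power(pw$frequencies, pw$psd, b$f_lo, b$f_hi)
    }
  }
  out
}
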
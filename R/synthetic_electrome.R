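#' Stimulus-response scenario
#'
#' Describes how a stimulated plant's electrome departs from baseline after
#' the stimulus.  Defaults encode the stimulus-specific effect sizes used
#' throughout the package: in the stimulated (local) leaf all three
#' stimuli depress approximate entropy by about 0.3; in the distant
#' (systemic) leaf the wound alone gives a 0.1 drop, heat shock 0.3 and
#' the combined stimulus 0.2 with a biphasic time course (two effect lobes
#' separated by a trough near +10 min).  Systemic spikes are smaller than
#' local ones.
#'
#' @param treatment One of `"W"` (wound), `"HS"` (heat shock), `"W_HS"`
#'   (combined), `"CONTROL"`.
#' @param tissue `"LOCAL"` or `"SYSTEMIC"`.
#' @param response_onset_s Seconds after the stimulus at which the effect
#'   starts (default 0).
#' @param response_duration_s Length of one effect lobe in seconds
#'   (default 600).
#' @param biphasic Two effect lobes instead of one; default `TRUE` only
#'   for `"W_HS"`.
#' @param apen_drop_target Target drop in windowed approximate entropy
#'   during the effect; `NULL` picks the treatment/tissue default above.
#' @param systemic_amplitude_scale Spike-amplitude scale in `(0, 1]`
#'   applied to systemic tissue (default 0.5).
#' @param slow_wave_gain Amplitude of the post-stimulus slow-wave regime
#'   relative to the baseline standard deviation (default 1.5).
#' @param spike_gain Spike-amplitude multiplier inside the effect window
#'   (default 1.5).
#' @return A list of class `stimulus_scenario`.
#' @export
stimulus_scenario <- function(treatment, tissue = c("LOCAL", "SYSTEMIC"),
                              response_onset_s = 0,
                              response_duration_s = 600,
                              biphasic = NULL,
                              apen_drop_target = NULL,
                              systemic_amplitude_scale = 0.5,
                              slow_wave_gain = 1.5,
                              spike_gain = 1.5) {
  treatment <- match.arg(treatment, TREATMENTS)
  tissue <- match.arg(tissue)
  if (response_duration_s <= 0) stop("'response_duration_s' must be positive")
  if (systemic_amplitude_scale <= 0 || systemic_amplitude_scale > 1) {
    stop("'systemic_amplitude_scale' must lie in (0, 1]")
  }
  if (is.null(biphasic)) biphasic <- treatment == "W_HS"
  if (is.null(apen_drop_target)) {
    apen_drop_target <- if (treatment == "CONTROL") {
      0
    } else if (tissue == "LOCAL") {
      0.3
    } else {
      switch(treatment, W = 0.1, HS = 0.3, W_HS = 0.2)
    }
  }
  if (apen_drop_target < 0) stop("'apen_drop_target' must be >= 0")
  structure(
    list(treatment = treatment, tissue = tissue,
         response_onset_s = response_onset_s,
         response_duration_s = response_duration_s,
         biphasic = biphasic, apen_drop_target = apen_drop_target,
         systemic_amplitude_scale = systemic_amplitude_scale,
         slow_wave_gain = slow_wave_gain, spike_gain = spike_gain),
    class = "stimulus_scenario"
  )
}

#' Electrome generator parameters
#'
#' @param fs Sampling frequency in Hz (default 62.5).
#' @param duration_s Series duration in seconds (default 3600, i.e. one
#'   hour: 225,000 samples at 62.5 Hz).  `duration_s * fs` must be an
#'   integer sample count.
#' @param baseline_sigma Standard deviation of the baseline colored noise
#'   in microvolts (default 25).
#' @param spectral_exponent Exponent `beta` of the `1/f^beta` baseline
#'   noise (default 1).
#' @param spike_rate Mean spike events per minute (default 6).
#' @param spike_amp_range Two-element range of spike peak amplitudes in
#'   microvolts; the lower edge must be at least 50 (default 50-300).
#' @param seed Integer seed; identical parameters and seed give an
#'   identical series.
#' @return A list of class `electrome_gen_params`.
#' @export
electrome_gen_params <- function(fs = 62.5, duration_s = 3600,
                                 baseline_sigma = 25,
                                 spectral_exponent = 1,
                                 spike_rate = 6,
                                 spike_amp_range = c(50, 300),
                                 seed = 1L) {
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-8) {
    stop("'duration_s * fs' must be an integer sample count")
  }
  if (baseline_sigma <= 0) stop("'baseline_sigma' must be positive")
  if (spike_rate < 0) stop("'spike_rate' must be >= 0")
  if (length(spike_amp_range) != 2L || spike_amp_range[1] > spike_amp_range[2]) {
    stop("'spike_amp_range' must be an increasing length-2 range")
  }
  if (spike_amp_range[1] < 50) {
    stop("spike amplitudes are above 50 uV by construction; raise the lower edge")
  }
  structure(
    list(fs = fs, duration_s = duration_s, baseline_sigma = baseline_sigma,
         spectral_exponent = spectral_exponent, spike_rate = spike_rate,
         spike_amp_range = spike_amp_range, seed = as.integer(seed)),
    class = "electrome_gen_params"
  )
}

# Unit-variance 1/f^beta noise by spectral synthesis (FFT filtering of
# white Gaussian noise); beta = 0 reduces to white noise.
colored_noise_unit <- function(n, beta) {
  w <- stats::rnorm(n)
  if (beta == 0) return((w - mean(w)) / stats::sd(w))
  X <- stats::fft(w)
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) / n
  s <- ifelse(fk > 0, fk^(-beta / 2), 0)
  x <- Re(stats::fft(X * s, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Zero-phase Gaussian low-pass via FFT; 'width' is the kernel standard
# deviation in samples (transfer function exp(-2 (pi f width)^2)).
gaussian_lowpass <- function(x, width) {
  n <- length(x)
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) / n
  H <- exp(-2 * (pi * fk * width)^2)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# Calibration of the post-stimulus slow-wave regime: Gaussian low-pass
# width (samples at 62.5 Hz) versus the drop it produces in the pooled
# per-bin median of windowed ApEn over the first 10 min, measured from
# 10-replicate generator runs at the default generator and analysis
# settings (48 s windows, m = 2, tau = 1, r = 0.02 * window sd, default
# spike train).  Built once from generator runs; interpolated linearly.
.slow_wave_cal <- list(
  # full-amplitude (local) spike train
  LOCAL = data.frame(
    width = c(1.5, 1.6, 1.7, 1.9, 2, 2.2, 2.5, 3, 4),
    drop  = c(0.068, 0.111, 0.150, 0.220, 0.251, 0.305, 0.362, 0.416, 0.464)
  ),
  # half-amplitude (systemic) spike train sits in a different neighbor-count
  # regime and needs much wider low-pass kernels for the same drop
  SYSTEMIC = data.frame(
    width = c(5, 10, 20, 40, 80, 150),
    drop  = c(0.067, 0.127, 0.248, 0.399, 0.486, 0.526)
  )
)

slow_wave_width_for_drop <- function(drop, tissue = "LOCAL") {
  cal <- .slow_wave_cal[[tissue]]
  if (drop <= 0) return(0)
  if (drop >= max(cal$drop)) return(max(cal$width))
  if (drop <= min(cal$drop)) {
    return(cal$width[1] * drop / cal$drop[1])
  }
  stats::approx(cal$drop, cal$width, xout = drop, ties = "ordered")$y
}

# Biexponential spike kernel (0.2 s rise, 1 s decay), peak normalized to 1.
spike_kernel <- function(fs, t_rise = 0.2, t_decay = 1, span_s = 6) {
  t <- seq(0, span_s, by = 1 / fs)
  k <- exp(-t / t_decay) - exp(-t / t_rise)
  k / max(k)
}

# Effect lobes as (start, end) second pairs relative to series start.
effect_lobes <- function(scenario) {
  on <- scenario$response_onset_s
  dur <- scenario$response_duration_s
  if (!scenario$biphasic) {
    matrix(c(on, on + dur), ncol = 2)
  } else {
    # two lobes with a trough around onset + dur (near +10 min at defaults)
    rbind(c(on, on + 0.9 * dur),
          c(on + 1.1 * dur, on + 2 * dur))
  }
}

# Plateau envelope over [a, b] seconds with short cosine ramps.
lobe_envelope <- function(t, a, b, ramp_s = 2) {
  e <- numeric(length(t))
  inside <- t >= a & t <= b
  e[inside] <- 1
  up <- t >= a & t < a + ramp_s
  e[up] <- 0.5 - 0.5 * cos(pi * (t[up] - a) / ramp_s)
  dn <- t > b - ramp_s & t <= b
  e[dn] <- 0.5 - 0.5 * cos(pi * (b - t[dn]) / ramp_s)
  e
}

#' Generate a synthetic electrome series
#'
#' The baseline electrome is unit-variance `1/f^beta` colored noise scaled
#' to `baseline_sigma`, with a Poisson train of biexponential voltage
#' spikes (peak amplitudes uniform in `spike_amp_range`, at least 50 uV,
#' scaled down for systemic tissue) superposed.  In the `"AFTER"` phase of
#' a stimulated scenario the signal inside the effect lobe(s) cross-fades
#' into a slow-wave regime: the same underlying noise passed through a
#' Gaussian low-pass whose width is calibrated to yield the scenario's
#' target drop in windowed approximate entropy, rescaled to
#' `slow_wave_gain` times the baseline standard deviation.  This
#' simultaneously depresses approximate entropy, raises the DFA scaling
#' exponent and concentrates spectral energy below 0.5 Hz; spikes inside
#' the lobes are amplified by `spike_gain`.  The `"AFTER"` phase of a
#' control scenario is statistically identical to `"BEFORE"`.
#'
#' @param params An [electrome_gen_params()].
#' @param scenario A [stimulus_scenario()].
#' @param phase `"BEFORE"` or `"AFTER"`.
#' @return A [voltage_series()] labeled from the scenario and phase.
#' @examples
#' p <- electrome_gen_params(duration_s = 120, seed = 7)
#' s <- generate_electrome(p, stimulus_scenario("W"), "BEFORE")
#' length(s$samples)  # 7500
#' @export
generate_electrome <- function(params, scenario, phase = c("BEFORE", "AFTER")) {
  stopifnot(inherits(params, "electrome_gen_params"),
            inherits(scenario, "stimulus_scenario"))
  phase <- match.arg(phase)
  n <- as.integer(round(params$duration_s * params$fs))
  set.seed(params$seed)
  u <- colored_noise_unit(n, params$spectral_exponent)
  base <- params$baseline_sigma * u
  t <- (seq_len(n) - 1L) / params$fs

  stimulated <- phase == "AFTER" && scenario$treatment != "CONTROL" &&
    scenario$apen_drop_target > 0
  lobes <- if (stimulated) effect_lobes(scenario) else NULL

  x <- base
  if (stimulated) {
    width <- slow_wave_width_for_drop(scenario$apen_drop_target,
                                      scenario$tissue)
    if (width > 0) {
      sw <- gaussian_lowpass(u, width)
      sw <- sw / stats::sd(sw) *
        scenario$slow_wave_gain * params$baseline_sigma
      env <- numeric(n)
      for (i in seq_len(nrow(lobes))) {
        env <- pmax(env, lobe_envelope(t, lobes[i, 1],
                                       min(lobes[i, 2], params$duration_s)))
      }
      x <- (1 - env) * base + env * sw
    }
  }

  # spike train
  n_spikes <- stats::rpois(1, params$spike_rate * params$duration_s / 60)
  if (n_spikes > 0) {
    kern <- spike_kernel(params$fs)
    pos <- sort(sample.int(n, n_spikes, replace = TRUE))
    amp <- stats::runif(n_spikes, params$spike_amp_range[1],
                        params$spike_amp_range[2])
    sgn <- sample(c(-1, 1), n_spikes, replace = TRUE)
    if (scenario$tissue == "SYSTEMIC") {
      amp <- amp * scenario$systemic_amplitude_scale
    }
    if (stimulated) {
      t_sp <- (pos - 1L) / params$fs
      in_lobe <- vapply(t_sp, function(ts) {
        any(ts >= lobes[, 1] & ts <= lobes[, 2])
      }, logical(1))
      amp[in_lobe] <- amp[in_lobe] * scenario$spike_gain
    }
    for (i in seq_len(n_spikes)) {
      idx <- pos[i]:min(n, pos[i] + length(kern) - 1L)
      x[idx] <- x[idx] + sgn[i] * amp[i] * kern[seq_along(idx)]
    }
  }

  voltage_series(x, fs = params$fs, treatment = scenario$treatment,
                 tissue = scenario$tissue, phase = phase)
}

#' Turgor generator parameters
#'
#' @param sample_interval_s Sampling interval in seconds (default 10).
#' @param duration_s Total duration in seconds (default 7200: one hour
#'   before and one hour after the stimulus).
#' @param baseline_pressure Baseline patch pressure in probe units
#'   (default 100).
#' @param oscillation_period_s Period of the turgor oscillation in seconds
#'   (default 600).
#' @param cv_before_pct,cv_after_pct Target percent coefficients of
#'   variation of the two halves; `NULL` picks treatment defaults
#'   (HS 18.84 to 27.06, W+HS 9.89 to 28.27, control 21.5 to 14,
#'   W 15 to 10).
#' @param noise_fraction Fraction of each half's fluctuation variance
#'   carried by white noise rather than the oscillation (default 0.3;
#'   0 gives a pure deterministic series).
#' @param stimulus_time_s Stimulus time in seconds; must split the series
#'   into two equal halves (default `duration_s / 2`).
#' @param seed Integer seed.
#' @return A list of class `turgor_gen_params`.
#' @export
turgor_gen_params <- function(sample_interval_s = 10, duration_s = 7200,
                              baseline_pressure = 100,
                              oscillation_period_s = 600,
                              cv_before_pct = NULL, cv_after_pct = NULL,
                              noise_fraction = 0.3,
                              stimulus_time_s = duration_s / 2,
                              seed = 1L) {
  if (duration_s %% sample_interval_s != 0) {
    stop("'duration_s' must be a multiple of 'sample_interval_s'")
  }
  if (abs(stimulus_time_s - duration_s / 2) > 1e-9) {
    stop("'stimulus_time_s' must split the series into equal halves")
  }
  if (!is.null(cv_before_pct) && cv_before_pct <= 0) {
    stop("CV targets must be positive")
  }
  if (!is.null(cv_after_pct) && cv_after_pct <= 0) {
    stop("CV targets must be positive")
  }
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("'noise_fraction' must lie in [0, 1]")
  }
  structure(
    list(sample_interval_s = sample_interval_s, duration_s = duration_s,
         baseline_pressure = baseline_pressure,
         oscillation_period_s = oscillation_period_s,
         cv_before_pct = cv_before_pct, cv_after_pct = cv_after_pct,
         noise_fraction = noise_fraction,
         stimulus_time_s = stimulus_time_s, seed = as.integer(seed)),
    class = "turgor_gen_params"
  )
}

turgor_cv_defaults <- function(treatment) {
  switch(treatment,
         HS = c(18.84, 27.06),
         W_HS = c(9.89, 28.27),
         W = c(15, 10),
         CONTROL = c(21.5, 14))
}

#' Generate a synthetic leaf turgor (patch-pressure) series
#'
#' Baseline pressure plus a slow oscillation and white noise, with the
#' oscillation/noise amplitudes of each half calibrated analytically (from
#' the half's deterministic shape, mean and the sd/mean identity) so the
#' realized percent coefficient of variation matches the half's target
#' within about 2 percentage points.  Treatment-specific deterministic
#' shapes: heat shock sharpens the oscillation (halved period) after the
#' stimulus; wounding damps the oscillation exponentially starting 900 s
#' after the stimulus; the combined stimulus adds a ramped pressure step
#' beginning 240 s after the stimulus; controls change nothing
#' deterministically.
#'
#' @param params A [turgor_gen_params()].
#' @param scenario A [stimulus_scenario()]; only its `treatment` is used.
#' @return A [turgor_series()].
#' @export
generate_turgor <- function(params, scenario) {
  stopifnot(inherits(params, "turgor_gen_params"),
            inherits(scenario, "stimulus_scenario"))
  set.seed(params$seed)
  dt <- params$sample_interval_s
  n <- as.integer(params$duration_s / dt)
  t <- (seq_len(n) - 1L) * dt
  stim <- params$stimulus_time_s
  before <- t < stim
  cv_t <- c(
    if (is.null(params$cv_before_pct))
      turgor_cv_defaults(scenario$treatment)[1] else params$cv_before_pct,
    if (is.null(params$cv_after_pct))
      turgor_cv_defaults(scenario$treatment)[2] else params$cv_after_pct
  )

  period <- params$oscillation_period_s
  # deterministic relative shape (about 1) per treatment
  shape <- numeric(n)
  osc_damp <- rep(1, n)
  period_vec <- rep(period, n)
  if (scenario$treatment == "W_HS") {
    ramp_start <- stim + 240
    shape[t >= ramp_start] <-
      0.3 * pmin(1, (t[t >= ramp_start] - ramp_start) / 120)
  } else if (scenario$treatment == "W") {
    damp_start <- stim + 900
    osc_damp[t >= damp_start] <- exp(-(t[t >= damp_start] - damp_start) / 600)
  } else if (scenario$treatment == "HS") {
    period_vec[!before] <- period / 2
  }

  phase_arg <- ifelse(before, 2 * pi * t / period_vec,
                      2 * pi * (t - stim) / period_vec)
  osc_unit <- sin(phase_arg) * osc_damp

  rel <- numeric(n)
  for (half in list(before, !before)) {
    target_cv <- if (identical(half, before)) cv_t[1] else cv_t[2]
    sh <- shape[half]
    mu <- 1 + mean(sh)
    sd_need <- target_cv / 100 * mu
    v_shape <- mean((sh - mean(sh))^2)
    rem <- sd_need^2 - v_shape
    if (rem < 0) {
      # shape alone exceeds the target variance: shrink it to 80 % of budget
      sc <- sqrt(0.8 * sd_need^2 / v_shape)
      sh <- sh * sc
      shape[half] <- sh
      mu <- 1 + mean(sh)
      sd_need <- target_cv / 100 * mu
      rem <- sd_need^2 - mean((sh - mean(sh))^2)
    }
    ou <- osc_unit[half]
    v_osc_unit <- mean(ou^2)
    amp <- if (v_osc_unit > 0) {
      sqrt((1 - params$noise_fraction) * rem / v_osc_unit)
    } else 0
    noise_sd <- sqrt(params$noise_fraction * rem +
                       (if (v_osc_unit > 0) 0 else
                          (1 - params$noise_fraction) * rem))
    rel[half] <- sh + amp * ou +
      (if (noise_sd > 0) stats::rnorm(sum(half), 0, noise_sd) else 0)
  }

  samples <- params$baseline_pressure * (1 + rel)
  turgor_series(samples, sample_interval_s = dt, stimulus_time_s = stim,
                treatment = scenario$treatment)
}

#' Generate a full synthetic experiment on disk
#'
#' Emits paired before/after electrome series for every treatment x tissue
#' combination and one turgor series per treatment (systemic leaf), each
#' with a distinct seed derived from the master seed by a fixed counter
#' scheme (`seed + 1000 * entry_counter`), and writes a `manifest.csv`
#' describing every file.
#'
#' @param n_replicates Number of replicate plants per combination.
#' @param out_dir Output directory (created if needed).
#' @param params Electrome generator settings; its `seed` is the master
#'   seed.
#' @param turgor_params Turgor generator settings.
#' @param treatments,tissues Subsets of the full design, by default all.
#' @param with_turgor Also generate turgor series (default `TRUE`).
#' @return Invisibly, the manifest data frame with columns `file`, `kind`,
#'   `class`, `treatment`, `tissue`, `phase`, `seed`.
#' @export
generate_experiment <- function(n_replicates, out_dir,
                                params = electrome_gen_params(),
                                turgor_params = turgor_gen_params(),
                                treatments = TREATMENTS,
                                tissues = TISSUES,
                                with_turgor = TRUE) {
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  counter <- 0L
  seen <- character()
  for (rep_i in seq_len(n_replicates)) {
    for (tr in treatments) {
      for (ti in tissues) {
        scen <- stimulus_scenario(tr, ti)
        for (ph in PHASES) {
          counter <- counter + 1L
          seed_i <- params$seed + 1000L * counter
          p_i <- params
          p_i$seed <- seed_i
          srs <- generate_electrome(p_i, scen, ph)
          fname <- sprintf("%s_%s_%s_r%02d.csv", tolower(tr), tolower(ti),
                           tolower(ph), rep_i)
          if (fname %in% seen) stop("output path collision: ", fname)
          seen <- c(seen, fname)
          write_series(srs, file.path(out_dir, fname))
          rows[[length(rows) + 1L]] <- data.frame(
            file = fname, kind = "voltage", class = srs$label,
            treatment = tr, tissue = ti, phase = ph, seed = seed_i,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (with_turgor) {
      for (tr in treatments) {
        counter <- counter + 1L
        seed_i <- params$seed + 1000L * counter
        tp <- turgor_params
        tp$seed <- seed_i
        ts <- generate_turgor(tp, stimulus_scenario(tr, "SYSTEMIC"))
        fname <- sprintf("turgor_%s_r%02d.csv", tolower(tr), rep_i)
        if (fname %in% seen) stop("output path collision: ", fname)
        seen <- c(seen, fname)
        write_turgor(ts, file.path(out_dir, fname))
        rows[[length(rows) + 1L]] <- data.frame(
          file = fname, kind = "turgor", class = NA_character_,
          treatment = tr, tissue = "SYSTEMIC", phase = NA_character_,
          seed = seed_i, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
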
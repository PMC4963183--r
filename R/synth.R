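#' Parameters for the synthetic six-condition recording generator
#'
#' Builds the parameter set for simulated extracellular recordings of
#' trigeminal brainstem responses to whisker-array sweeps. Each trial is a
#' broadband voltage trace containing a condition-dependent evoked LFP
#' deflection with trial-to-trial onset jitter, Gaussian background noise,
#' and stereotyped spike waveforms embedded at ground-truth spike times drawn
#' from a condition-dependent rate profile.
#'
#' Defaults encode the study conditions: 29 trials per condition, six
#' conditions (three speeds x two directions), evoked responses whose
#' duration is inversely proportional to sweep speed (the post spends less
#' time in the array at higher speeds), slightly stronger responses for
#' caudal-rostral sweeps, and a low spontaneous rate.
#'
#' @param n_trials_per_condition Trials per condition (default 29).
#' @param fs Sampling rate in Hz (default 4000; any rate up to 40000).
#' @param trial_duration Trial length in s. Must leave room for a 750 ms
#'   analysis window plus the +/- 100 ms shift-search span on both sides of
#'   the alignment point; the default 1.2 s does so for all conditions and
#'   jitters within 4 standard deviations.
#' @param onset Evoked-response onset time in s (default 0.5).
#' @param evoked_amplitude Peak absolute amplitude of the evoked LFP
#'   deflection per condition (length 6, condition order of
#'   \code{\link{conditions}}), arbitrary voltage units.
#' @param evoked_duration Named map speed -> evoked duration in s; default
#'   inversely proportional to speed (0.15, 0.075, 0.0375 s). Together with
#'   the default contact rates these keep the evoked rate well above three
#'   times the whole-window mean rate, the regime in which PSTH-threshold
#'   contact-window estimation operates.
#' @param contact_rate Firing rate during contact per condition (length 6),
#'   spikes/s; defaults are higher for caudal-rostral sweeps and for slower
#'   speeds.
#' @param spontaneous_rate Baseline firing rate, spikes/s (default 2).
#' @param lfp_noise_sd Standard deviation of the additive Gaussian voltage
#'   noise (default 0.1). With the default amplitudes the evoked deflection
#'   is 20-30 noise SDs (evoked LFPs dwarf single spikes in vivo) and the
#'   embedded spikes sit near 10, comfortably above the customary
#'   signal-to-noise bound of 3 for an isolatable unit.
#' @param start_jitter_sd Standard deviation of the per-trial onset jitter in
#'   s (default 0.01). The same jitter shifts the LFP and the rate profile.
#' @param spike_amplitude Peak absolute amplitude of the embedded biphasic
#'   spike waveform (default 1).
#' @param spike_duration Spike waveform length in s (default 0.0015).
#' @param seed Integer RNG seed.
#' @return An object of class \code{synth_params}.
#' @export
synth_params <- function(n_trials_per_condition = 29,
                         fs = 4000,
                         trial_duration = 1.2,
                         onset = 0.5,
                         evoked_amplitude = c(2.5, 3.0, 2.2, 2.8, 2.0, 2.6),
                         evoked_duration = c(`90` = 0.15, `180` = 0.075, `360` = 0.0375),
                         contact_rate = c(80, 100, 70, 90, 60, 75),
                         spontaneous_rate = 2,
                         lfp_noise_sd = 0.1,
                         start_jitter_sd = 0.01,
                         spike_amplitude = 1,
                         spike_duration = 0.0015,
                         seed = 1L) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(trial_duration, "trial_duration", positive = TRUE)
  assert_scalar_num(onset, "onset", positive = TRUE)
  assert_scalar_num(spontaneous_rate, "spontaneous_rate")
  assert_scalar_num(start_jitter_sd, "start_jitter_sd")
  if (n_trials_per_condition < 1) stop("need at least one trial per condition")
  if (length(evoked_amplitude) != 6) stop("evoked_amplitude must have length 6")
  if (length(contact_rate) != 6) stop("contact_rate must have length 6")
  if (any(contact_rate < 0) || spontaneous_rate < 0)
    stop("firing rates must be non-negative")
  speeds <- c("90", "180", "360")
  if (!all(speeds %in% names(evoked_duration)))
    stop("evoked_duration must be named with speeds 90, 180, 360")
  dur <- as.numeric(evoked_duration[speeds])
  if (any(diff(dur) > 0))
    stop("evoked_duration must be non-increasing in speed")
  if (any(dur <= 0)) stop("evoked durations must be positive")
  if (onset + max(dur) >= trial_duration)
    stop("evoked response does not fit in the trial")
  p <- list(
    n_trials_per_condition = as.integer(n_trials_per_condition),
    fs = fs, trial_duration = trial_duration, onset = onset,
    evoked_amplitude = evoked_amplitude,
    evoked_duration = evoked_duration[speeds],
    contact_rate = contact_rate,
    spontaneous_rate = spontaneous_rate,
    lfp_noise_sd = lfp_noise_sd,
    start_jitter_sd = start_jitter_sd,
    spike_amplitude = spike_amplitude,
    spike_duration = spike_duration,
    seed = as.integer(seed)
  )
  class(p) <- "synth_params"
  p
}

n_samples <- function(params) round(params$fs * params$trial_duration)

#' Stereotyped biphasic spike waveform
#'
#' @param fs Sampling rate, Hz.
#' @param amplitude Peak absolute amplitude, voltage units.
#' @param duration Waveform length, s (default 1.5 ms).
#' @return Numeric vector of voltage samples.
#' @export
make_spike_waveform <- function(fs, amplitude = 1, duration = 0.0015) {
  n <- max(3L, round(fs * duration))
  u <- seq(0, 1, length.out = n)
  w <- exp(-((u - 0.35) / 0.12)^2) - 0.85 * exp(-((u - 0.65) / 0.18)^2)
  w / max(abs(w)) * amplitude
}

#' Noise-free evoked LFP profile for one condition
#'
#' A smooth deflection with compact support: the support width equals the
#' speed's evoked duration and the peak absolute voltage equals the
#' condition's amplitude. The main lobe is negative-going (extracellular
#' evoked deflections) with a smaller rebound, and its peak sits earlier in
#' the contact window for RC sweeps than for CR sweeps, so all six profiles
#' are mutually distinct.
#'
#' @param condition A condition from \code{\link{condition}} (or a list with
#'   \code{speed} and \code{direction}).
#' @param params A \code{\link{synth_params}} object.
#' @return Voltage vector of length \code{round(fs * trial_duration)}.
#' @export
make_lfp_profile <- function(condition, params) {
  cond <- condition(condition$speed, condition$direction)
  n <- n_samples(params)
  dur <- as.numeric(params$evoked_duration[as.character(cond$speed)])
  amp <- params$evoked_amplitude[cond$j]
  t <- (seq_len(n) - 1) / params$fs
  u <- (t - params$onset) / dur
  inside <- u >= 0 & u < 1
  prof <- numeric(n)
  if (amp != 0 && any(inside)) {
    up <- if (cond$direction == "RC") 0.4 else 0.6
    g <- exp(-((u[inside] - up) / 0.15)^2 / 2) -
      0.55 * exp(-((u[inside] - up) / 0.30)^2 / 2)
    g <- g * sin(pi * u[inside])^2   # taper to zero at the support edges
    prof[inside] <- -g / max(abs(g)) * amp
  }
  prof
}

#' Firing-rate profile for one condition
#'
#' Piecewise-constant rate: the spontaneous rate outside the contact window
#' and the condition's contact rate inside it. The contact window starts at
#' the evoked onset and lasts the speed's evoked duration, mirroring shorter
#' contact times at faster sweeps.
#'
#' @inheritParams make_lfp_profile
#' @return Rate vector (spikes/s per sample) with attribute
#'   \code{contact_window = c(start, end)} in s.
#' @export
make_rate_profile <- function(condition, params) {
  cond <- condition(condition$speed, condition$direction)
  n <- n_samples(params)
  dur <- as.numeric(params$evoked_duration[as.character(cond$speed)])
  t <- (seq_len(n) - 1) / params$fs
  r <- rep(params$spontaneous_rate, n)
  win <- c(params$onset, params$onset + dur)
  r[t >= win[1] & t < win[2]] <- params$contact_rate[cond$j]
  attr(r, "contact_window") <- win
  r
}

shift_samples <- function(x, k) {
  # integer-sample shift with zero fill
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) {
    if (k < n) out[(k + 1):n] <- x[1:(n - k)]
  } else {
    if (-k < n) out[1:(n + k)] <- x[(1 - k):n]
  }
  out
}

#' Simulate one trial
#'
#' Voltage = jittered evoked LFP profile + Gaussian noise + a spike waveform
#' at each ground-truth spike time. Spikes are drawn by per-sample Bernoulli
#' thinning with probability rate/fs (valid for rates well below fs; rates
#' above 0.1 * fs are rejected) from the rate profile shifted by the same
#' per-trial onset jitter as the LFP.
#'
#' @inheritParams make_lfp_profile
#' @param jitter Optional fixed onset jitter in s; by default drawn from
#'   N(0, start_jitter_sd^2) using the current RNG state.
#' @return A \code{raw_trial}: list with \code{voltage}, \code{fs},
#'   \code{condition}, \code{true_spike_times}, \code{true_contact_window},
#'   \code{jitter}, \code{trial_duration}.
#' @export
simulate_trial <- function(condition, params, jitter = NULL) {
  cond <- condition(condition$speed, condition$direction)
  if (max(params$contact_rate, params$spontaneous_rate) > 0.1 * params$fs)
    stop("firing rates must not exceed 0.1 * fs for Bernoulli thinning")
  n <- n_samples(params)
  jit <- jitter %||% stats::rnorm(1, 0, params$start_jitter_sd)
  k <- round(jit * params$fs)

  prof <- shift_samples(make_lfp_profile(cond, params), k)
  rate <- make_rate_profile(cond, params)
  win <- attr(rate, "contact_window") + k / params$fs
  rate <- shift_samples(as.numeric(rate), k)
  if (k > 0) rate[seq_len(min(k, n))] <- params$spontaneous_rate
  if (k < 0) rate[(max(n + k, 0) + 1):n] <- params$spontaneous_rate

  spike_idx <- which(stats::runif(n) < rate / params$fs)
  spike_times <- (spike_idx - 1) / params$fs

  v <- prof
  if (params$lfp_noise_sd > 0)
    v <- v + stats::rnorm(n, 0, params$lfp_noise_sd)
  if (length(spike_idx)) {
    w <- make_spike_waveform(params$fs, params$spike_amplitude,
                             params$spike_duration)
    for (i in spike_idx) {
      stop_i <- min(n, i + length(w) - 1L)
      v[i:stop_i] <- v[i:stop_i] + w[seq_len(stop_i - i + 1L)]
    }
  }
  structure(list(voltage = v, fs = params$fs, condition = cond,
                 true_spike_times = spike_times,
                 true_contact_window = win,
                 jitter = jit,
                 trial_duration = params$trial_duration),
            class = "raw_trial")
}

#' Simulate a full six-condition dataset
#'
#' @param params A \code{\link{synth_params}} object; \code{params$seed}
#'   makes the dataset fully reproducible.
#' @return A list of \code{raw_trial} objects (length
#'   \code{6 * n_trials_per_condition}), each with a \code{trial_id} field.
#' @export
simulate_dataset <- function(params) {
  set.seed(params$seed)
  tab <- conditions()
  trials <- vector("list", 6L * params$n_trials_per_condition)
  id <- 0L
  for (j in tab$j) {
    cond <- condition(tab$speed[j], tab$direction[j])
    for (r in seq_len(params$n_trials_per_condition)) {
      id <- id + 1L
      tr <- simulate_trial(cond, params)
      tr$trial_id <- id
      trials[[id]] <- tr
    }
  }
  trials
}
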
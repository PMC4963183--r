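#' Alignment threshold from a set of trials
#'
#' The activity threshold for one recording site and condition: 60% (by
#' default) of the mean over trials of the per-trial peak absolute LFP value.
#'
#' @param trials List of \code{raw_trial} objects for one site and condition.
#' @param frac Fraction of the mean peak (default 0.6).
#' @return Threshold voltage.
#' @export
alignment_threshold <- function(trials, frac = 0.6) {
  if (!length(trials)) stop("alignment_threshold: empty trial list")
  peaks <- vapply(trials, function(tr) max(abs(tr$voltage)), numeric(1))
  frac * mean(peaks)
}

#' Align one trial on the start of the physiological response
#'
#' The crossing is the first sample where the rectified LFP exceeds the
#' threshold; a 750 ms window centred on the crossing is extracted, together
#' with an extended window padded by \code{pad_s} on both sides so that
#' shift-invariant decoding always has full support. Spike times are
#' re-referenced to the window start. Trials with no crossing, or whose
#' padded window does not fit inside the trace, are rejected (return
#' \code{NULL}) rather than raising an error.
#'
#' @param trial A \code{raw_trial}.
#' @param threshold Voltage threshold (see \code{\link{alignment_threshold}}).
#' @param window_s Analysis window length in s (default 0.75).
#' @param pad_s Extra support on each side for the shift search (default 0.1).
#' @return An \code{aligned_trial} (list with \code{lfp}, \code{lfp_ext},
#'   \code{spike_times}, \code{spike_times_ext}, \code{fs}, \code{condition},
#'   \code{crossing_time}, \code{window_s}, \code{pad_s}, and when ground
#'   truth is available \code{true_window} relative to the window start), or
#'   \code{NULL} if the trial is rejected.
#' @export
align_trial <- function(trial, threshold, window_s = 0.75, pad_s = 0.1) {
  idx <- which(abs(trial$voltage) > threshold)
  if (!length(idx)) return(NULL)
  extract_window(trial, idx[1], window_s, pad_s)
}

extract_window <- function(trial, cross, window_s, pad_s) {
  v <- trial$voltage
  fs <- trial$fs
  N <- round(window_s * fs)
  pad_n <- round(pad_s * fs)
  start <- cross - floor(N / 2)
  ext_start <- start - pad_n
  ext_end <- start + N - 1L + pad_n
  if (ext_start < 1L || ext_end > length(v)) return(NULL)

  t0 <- (start - 1) / fs
  st <- (trial$true_spike_times %||% numeric(0)) - t0
  out <- list(
    lfp = v[start:(start + N - 1L)],
    lfp_ext = v[ext_start:ext_end],
    spike_times = st[st >= 0 & st < window_s],
    spike_times_ext = st[st >= -pad_s & st < window_s + pad_s],
    fs = fs, condition = trial$condition,
    crossing_time = (cross - 1) / fs,
    window_s = window_s, pad_s = pad_s,
    trial_id = trial$trial_id %||% NA_integer_
  )
  if (!is.null(trial$true_contact_window) &&
      all(is.finite(trial$true_contact_window)))
    out$true_window <- trial$true_contact_window - t0
  structure(out, class = "aligned_trial")
}

#' Extract an analysis window at a known time
#'
#' Window extraction without threshold alignment, for analyses where the
#' stimulus time is taken as known or where there is no evoked response to
#' align on (e.g. chance-level controls on pure-noise data). The window is
#' centred on \code{center_s}.
#'
#' @param trial A \code{raw_trial}.
#' @param center_s Window centre in the raw-trial clock, s (default: trace
#'   midpoint).
#' @inheritParams align_trial
#' @return An \code{aligned_trial}, or \code{NULL} if the padded window does
#'   not fit.
#' @export
window_trial <- function(trial, center_s = trial$trial_duration / 2,
                         window_s = 0.75, pad_s = 0.1) {
  extract_window(trial, round(center_s * trial$fs) + 1L, window_s, pad_s)
}

#' Align a whole dataset with per-condition thresholds
#'
#' Computes the alignment threshold separately for each condition (as done
#' per recording location and condition in the source analysis) and aligns
#' every trial, dropping rejected ones.
#'
#' @param trials List of \code{raw_trial} objects.
#' @param threshold_frac Fraction of the mean peak (default 0.6).
#' @inheritParams align_trial
#' @return List with \code{aligned} (list of \code{aligned_trial}) and
#'   \code{rejected} (trial ids that had no usable crossing).
#' @export
align_dataset <- function(trials, threshold_frac = 0.6,
                          window_s = 0.75, pad_s = 0.1) {
  js <- vapply(trials, function(tr) tr$condition$j, integer(1))
  aligned <- vector("list", length(trials))
  rejected <- integer(0)
  for (j in sort(unique(js))) {
    sel <- which(js == j)
    thr <- alignment_threshold(trials[sel], frac = threshold_frac)
    for (i in sel) {
      a <- align_trial(trials[[i]], thr, window_s = window_s, pad_s = pad_s)
      if (is.null(a)) rejected <- c(rejected, trials[[i]]$trial_id %||% i)
      aligned[[i]] <- a
    }
  }
  list(aligned = Filter(Negate(is.null), aligned), rejected = rejected)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (\code{signal::filtfilt}), so the output has no phase delay and
#' spike/LFP latency relations are preserved.
#'
#' @param x Signal vector.
#' @param band Numeric length-2 vector \code{c(lo, hi)} in Hz, with
#'   \code{0 < lo < hi < fs/2}.
#' @param fs Sampling rate, Hz.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as \code{x}.
#' @export
bandpass <- function(x, band, fs, order = 4) {
  if (length(band) != 2 || !(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("band must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

analytic_signal <- function(x) {
  # analytic signal via the frequency-domain Hilbert construction
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous-amplitude envelope of a frequency band
#'
#' Band-passes the signal and returns the magnitude of its analytic signal
#' (Hilbert envelope): a non-negative instantaneous amplitude, same length
#' as the input.
#'
#' @inheritParams bandpass
#' @return Non-negative envelope vector.
#' @export
band_envelope <- function(x, band, fs) {
  Mod(analytic_signal(bandpass(x, band, fs)))
}
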
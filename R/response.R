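#' Peri-stimulus time histogram
#'
#' Bins are half-open \code{[b*dt, (b+1)*dt)}, 0-based in time from the
#' window start; counts are summed over trials and normalised to spikes/s by
#' dividing by \code{n_trials * bin_width}.
#'
#' @param spike_trains List of numeric vectors, one per trial, spike times in
#'   s relative to the analysis-window start.
#' @param bin_width Bin width, s (default 0.015).
#' @param window Window length, s (default 0.75).
#' @return A \code{psth}: list with \code{rate} (spikes/s per bin),
#'   \code{bin_width}, \code{window}, \code{n_trials}, \code{edges}.
#' @export
compute_psth <- function(spike_trains, bin_width = 0.015, window = 0.75) {
  if (bin_width <= 0) stop("bin_width must be positive")
  n_bins <- ceiling(window / bin_width)
  counts <- numeric(n_bins)
  for (st in spike_trains) {
    st <- st[st >= 0 & st < window]
    if (length(st)) {
      b <- floor(st / bin_width) + 1L
      tb <- tabulate(b, nbins = n_bins)
      counts <- counts + tb
    }
  }
  n_trials <- length(spike_trains)
  structure(list(rate = counts / (max(1L, n_trials) * bin_width),
                 bin_width = bin_width, window = window,
                 n_trials = n_trials,
                 edges = (0:n_bins) * bin_width),
            class = "psth")
}

#' Estimate the contact window from a PSTH
#'
#' The start of contact is the left edge of the first bin whose rate exceeds
#' three times the mean rate; the end is the left edge of the first
#' subsequent bin whose rate falls below twice the mean rate (or the window
#' end if the response lasts to the end). Returns \code{NULL} (no response)
#' if no bin exceeds the start threshold.
#'
#' @param psth A \code{psth} from \code{\link{compute_psth}}.
#' @param mean_rate Mean firing rate, spikes/s; defaults to the mean of the
#'   PSTH over the full window.
#' @return A \code{contact_window}: list with \code{start} and \code{end}
#'   (s), or \code{NULL} if there is no response.
#' @export
find_contact_window <- function(psth, mean_rate = mean(psth$rate)) {
  if (!inherits(psth, "psth")) stop("psth must come from compute_psth()")
  if (!is.finite(mean_rate) || mean_rate <= 0) return(NULL)
  r <- psth$rate
  start_bin <- which(r > 3 * mean_rate)[1]
  if (is.na(start_bin)) return(NULL)
  end <- psth$window
  if (start_bin < length(r)) {
    after <- which(r[(start_bin + 1):length(r)] < 2 * mean_rate)
    if (length(after)) end <- psth$edges[start_bin + after[1]]
  }
  structure(list(start = psth$edges[start_bin], end = end),
            class = "contact_window")
}

#' Per-trial response statistics for a contact window
#'
#' @param spike_train Spike times, s, relative to the analysis-window start.
#' @param window A \code{contact_window}.
#' @param total_window Analysis window length, s (default 0.75).
#' @return List with \code{rate} (in-window spikes/s), \code{duration} (s)
#'   and \code{background_rate} (out-of-window spikes/s; \code{NA} if the
#'   window covers the whole trace).
#' @export
response_stats <- function(spike_train, window, total_window = 0.75) {
  if (is.null(window) || window$end <= window$start)
    stop("response_stats: invalid or zero-length contact window")
  dur <- window$end - window$start
  inside <- sum(spike_train >= window$start & spike_train < window$end)
  outside <- sum(spike_train >= 0 & spike_train < total_window) - inside
  out_time <- total_window - dur
  list(rate = inside / dur,
       duration = dur,
       background_rate = if (out_time > 0) outside / out_time else NA_real_)
}
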
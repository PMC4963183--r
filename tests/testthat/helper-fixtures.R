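# Shared fixtures and independent oracles for the test suite.

# small, fast generator settings used where the check is structural
quick_params <- function(...) {
  args <- list(n_trials_per_condition = 5, fs = 1000, seed = 101)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(synth_params, args)
}

fake_raw_trial <- function(voltage, fs = 1000, speed = 90, direction = "RC",
                           spikes = numeric(0), id = 1L) {
  structure(list(voltage = voltage, fs = fs,
                 condition = condition(speed, direction),
                 true_spike_times = spikes,
                 true_contact_window = NULL,
                 jitter = 0,
                 trial_duration = length(voltage) / fs,
                 trial_id = id),
            class = "raw_trial")
}

# aligned_trial built directly from an extended LFP trace and/or spikes,
# bypassing threshold alignment (for decoder unit tests)
fake_aligned <- function(lfp_ext = NULL, spikes_ext = numeric(0), j = 1L,
                         fs = 1000, window_s = 0.75, pad_s = 0.1, id = 1L) {
  N <- round(window_s * fs); pad_n <- round(pad_s * fs)
  if (is.null(lfp_ext)) lfp_ext <- numeric(N + 2 * pad_n)
  stopifnot(length(lfp_ext) == N + 2 * pad_n)
  tab <- conditions()
  structure(list(
    lfp = lfp_ext[(pad_n + 1):(pad_n + N)],
    lfp_ext = lfp_ext,
    spike_times = spikes_ext[spikes_ext >= 0 & spikes_ext < window_s],
    spike_times_ext = spikes_ext,
    fs = fs, condition = condition(tab$speed[j], tab$direction[j]),
    crossing_time = NA_real_, window_s = window_s, pad_s = pad_s,
    trial_id = id), class = "aligned_trial")
}

# --- independent oracles -----------------------------------------------------

# direct evaluation of the Gaussian LFP likelihood density (log), with the
# condition-independent -N/2 log(2*pi) constant removed
oracle_lfp_loglik <- function(v, mu, sigma) {
  sum(dnorm(v, mean = mu, sd = sigma, log = TRUE)) +
    length(v) / 2 * log(2 * pi)
}

# direct evaluation of the binned Bernoulli joint probability: loop over all
# bins, occupancy by definition of the indicator phi
oracle_spike_loglik <- function(spike_times, p, T) {
  N <- length(p)
  ll <- 0
  for (i in seq_len(N)) {
    occupied <- any(spike_times >= (i - 1) * T / N & spike_times < i * T / N)
    ll <- ll + if (occupied) log(p[i]) else log(1 - p[i])
  }
  ll
}

# exhaustive scan over conditions and shifts using the scalar log-likelihoods
oracle_classify_lfp <- function(v_ext, model, grid) {
  pad_n <- (length(v_ext) - model$N) / 2
  best <- c(-Inf, NA, NA)
  ord <- order(abs(grid), grid)
  for (j in 1:6) {
    if (is.null(model$mu[[j]])) next
    for (tau in grid[ord]) {
      k <- round(tau * model$fs)
      w <- v_ext[(pad_n + k + 1):(pad_n + k + model$N)]
      ll <- lfp_loglik(w, model$mu[[j]], model$sigma[j])
      if (ll > best[1]) best <- c(ll, j, tau)
    }
  }
  list(j = best[2], tau = best[3], ll = best[1])
}

oracle_classify_spikes <- function(st_ext, models, grid) {
  best <- c(-Inf, NA, NA)
  ord <- order(abs(grid), grid)
  for (j in 1:6) {
    m <- models[[j]]
    if (is.null(m)) next
    for (tau in grid[ord]) {
      t2 <- st_ext - tau
      t2 <- t2[t2 >= 0 & t2 < m$T]
      ll <- oracle_spike_loglik(t2, m$p, m$T)
      if (ll > best[1]) best <- c(ll, j, tau)
    }
  }
  list(j = best[2], tau = best[3], ll = best[1])
}

# smooth random template supported on an N-sample window
random_template <- function(N, seed_shift = 0) {
  x <- cumsum(rnorm(N))
  x <- x - mean(x)
  stats::filter(x, rep(1 / 25, 25), circular = TRUE) |> as.numeric()
}
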
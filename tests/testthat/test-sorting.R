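# two clearly different waveform shapes used across sorting tests
wave_a <- function(fs) make_spike_waveform(fs, amplitude = 1)
wave_b <- function(fs) {
  w <- rev(make_spike_waveform(fs, amplitude = 0.8))
  w - mean(w)
}

# build a trace with waveforms inserted at given sample indices over noise
embed_events <- function(n, at, w, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, 0, noise_sd)
  for (i in at) x[i:(i + length(w) - 1)] <- x[i:(i + length(w) - 1)] + w
  x
}

test_that("event detection finds embedded spikes and honours the lockout", {
  fs <- 20000
  w <- wave_a(fs)
  at <- seq(2000, 20000, by = 2000)  # 10 spikes, 100 ms apart
  x <- embed_events(30000, at, w, noise_sd = 0.01)
  ev <- detect_events(x, fs, k_mad = 5)
  expect_equal(length(ev), 10)
  peak_off <- which.max(abs(w)) - 1
  for (k in seq_along(ev))
    expect_lt(abs(ev[[k]]$time - (at[k] - 1 + peak_off) / fs), 2.5 / fs)

  # zero signal: no events
  expect_equal(length(detect_events(numeric(5000), fs)), 0)

  # two spikes 0.5 ms apart collapse into one event
  x2 <- embed_events(10000, c(5000, 5000 + round(0.0005 * fs)), w,
                     noise_sd = 0.01)
  expect_equal(length(detect_events(x2, fs, k_mad = 5)), 1)

  expect_error(detect_events(numeric(3), fs), "shorter")
})

test_that("waveform features scale and separate classes", {
  fs <- 20000
  w <- wave_a(fs)
  at <- seq(2000, 40000, by = 1500)
  x <- embed_events(45000, at, w, noise_sd = 0.001)
  ev <- detect_events(x, fs)
  f <- featurize(ev)
  expect_equal(colnames(f),
               c("peak_height", "peak_width", "trough_depth", "trough_width",
                 "pc1", "pc2", "pc3"))
  expect_true(all(f[, "peak_width"] > 0) && all(f[, "trough_width"] > 0))

  # identical snippets: identical rows, centred PCs vanish
  ev_id <- rep(list(list(time = 0, snippet = w, fs = fs)), 6)
  f_id <- featurize(ev_id)
  expect_true(all(apply(f_id, 2, function(col) diff(range(col)) == 0)))
  expect_true(all(abs(f_id[, c("pc1", "pc2", "pc3")]) < 1e-9))

  # scaling doubles amplitudes, leaves widths unchanged
  ev2 <- list(list(time = 0, snippet = w, fs = fs),
              list(time = 0, snippet = 2 * w, fs = fs),
              list(time = 0, snippet = w, fs = fs),
              list(time = 0, snippet = 2 * w, fs = fs))
  f2 <- featurize(ev2)
  expect_equal(f2[2, "peak_height"], 2 * f2[1, "peak_height"])
  expect_equal(f2[2, "trough_depth"], 2 * f2[1, "trough_depth"])
  expect_equal(f2[2, "peak_width"], f2[1, "peak_width"])

  # two waveform classes separate along pc1
  wb <- wave_b(fs)
  mk <- function(w, n, seed) lapply(seq_len(n), function(i) {
    set.seed(seed + i); list(time = 0, snippet = w + rnorm(length(w), 0, 0.01),
                             fs = fs)
  })
  evs <- c(mk(w, 20, 1), mk(wb, 20, 100))
  fm <- featurize(evs)
  pc1 <- fm[, "pc1"]
  expect_true(max(pc1[1:20]) < min(pc1[21:40]) ||
              min(pc1[1:20]) > max(pc1[21:40]))
})

test_that("mixture clustering recovers the number of classes", {
  fs <- 20000
  w <- wave_a(fs); wb <- wave_b(fs)
  mk <- function(w, n, seed) lapply(seq_len(n), function(i) {
    set.seed(seed + i); list(time = i, snippet = w + rnorm(length(w), 0, 0.02),
                             fs = fs)
  })
  evs <- c(mk(w, 40, 1), mk(wb, 40, 500))
  f <- featurize(evs)
  cl <- cluster_events(f, k_max = 5, seed = 1)
  expect_equal(cl$k, 2)
  truth <- rep(1:2, each = 40)
  acc <- max(mean(cl$labels == truth), mean((3 - cl$labels) == truth))
  expect_gt(acc, 0.95)

  cl_again <- cluster_events(f, k_max = 5, seed = 1)
  expect_identical(cl$labels, cl_again$labels)

  # a single class is recognised as one component
  f1 <- featurize(mk(w, 50, 9))
  expect_equal(cluster_events(f1, k_max = 4, seed = 1)$k, 1)

  expect_error(cluster_events(f[1:4, ], k_max = 5), "k_max")
})

test_that("best-cluster selection uses the isolation score with a floor of 3", {
  fs <- 20000
  w <- wave_a(fs)
  mk <- function(base, sd, n, seed) lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    list(time = i, snippet = base + rnorm(length(base), 0, sd), fs = fs)
  })
  good <- mk(w, 0.02, 20, 1)                  # tight, high-amplitude
  noise <- mk(numeric(length(w)), 0.3, 20, 50) # amorphous noise cluster
  evs <- c(good, noise)
  labels <- rep(1:2, each = 20)
  sel <- select_best_cluster(evs, labels)
  expect_equal(sel$cluster, 1)
  expect_gt(sel$score, 3)

  # permutation invariance of the chosen unit
  sel_perm <- select_best_cluster(evs, 3 - labels)
  expect_equal(sel_perm$cluster, 2)
  expect_equal(sel_perm$score, sel$score)

  # nothing isolates: no-unit signal
  all_noise <- mk(numeric(length(w)), 0.3, 24, 7)
  expect_null(select_best_cluster(all_noise, rep(1:2, each = 12)))

  # one strong cluster alone is selected
  expect_equal(select_best_cluster(good, rep(1, 20))$cluster, 1)
})

test_that("template matching accepts unit spikes and rejects artifacts", {
  fs <- 20000
  w <- wave_a(fs)
  mk <- function(base, sd, n, seed) lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    list(time = i * 0.01, snippet = base + rnorm(length(base), 0, sd), fs = fs)
  })
  evs <- mk(w, 0.02, 30, 1)
  tmpl <- build_template(evs, rep(1L, 30), 1L, fs)
  expect_gt(tmpl$accept_threshold, 0)

  # an event identical to the template has error 0 and is accepted
  exact <- list(list(time = 99, snippet = tmpl$waveform, fs = fs))
  expect_equal(template_match(exact, tmpl), 99)

  # a large artifact on top of the template is rejected
  art <- tmpl$waveform
  art[tmpl$match_idx] <- art[tmpl$match_idx] + 5
  expect_equal(length(template_match(list(list(time = 1, snippet = art,
                                               fs = fs)), tmpl)), 0)

  # two-unit mixture: matching against unit A recovers A with high precision
  wb <- wave_b(fs)
  evs_b <- mk(wb, 0.02, 30, 400)
  all_ev <- c(evs, evs_b)
  got <- template_match(all_ev, tmpl)
  times_a <- vapply(evs, `[[`, numeric(1), "time")
  tp <- sum(got %in% times_a)
  expect_gt(tp / length(got), 0.9)        # precision
  expect_gt(tp / length(times_a), 0.9)    # recall
})

test_that("end-to-end sorting recovers ground-truth spikes on synthetic data", {
  p <- synth_params(n_trials_per_condition = 4, fs = 8000, seed = 17)
  d <- simulate_dataset(p)
  al <- align_dataset(d)
  srt <- sort_spikes(al$aligned, seed = 1)
  expect_false(is.null(srt))
  expect_gt(srt$isolation, 3)
  tp <- 0; fn <- 0; npos <- nrow(srt$spikes)
  for (i in seq_along(al$aligned)) {
    gt <- al$aligned[[i]]$spike_times
    det <- srt$spikes$spike_time_s[srt$spikes$trial_index == i]
    for (s in gt) if (any(abs(det - s) <= 0.001)) tp <- tp + 1 else fn <- fn + 1
  }
  prec <- tp / npos; rec <- tp / (tp + fn)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gt(f1, 0.9)
})
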
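#' Detect putative spike events by amplitude thresholding
#'
#' Events are samples where the rectified signal exceeds
#' \code{k_mad} times a robust noise estimate (median absolute deviation
#' scaled to the Gaussian standard deviation, i.e. MAD / 0.6745). Within each
#' supra-threshold excursion the local extremum is taken as the event time,
#' and a 1 ms refractory lockout suppresses secondary crossings. A snippet
#' (default 2 ms) centred on each event is extracted; events too close to the
#' trace edges for a full snippet are dropped.
#'
#' @param x Signal vector, already band-pass filtered into the spike band.
#' @param fs Sampling rate, Hz.
#' @param k_mad Detection threshold in robust standard deviations (default 4).
#' @param snippet_s Snippet length, s (default 0.002).
#' @param lockout_s Refractory lockout, s (default 0.001).
#' @return List of events, each a list with \code{time} (s) and
#'   \code{snippet} (voltage vector).
#' @export
detect_events <- function(x, fs, k_mad = 4, snippet_s = 0.002,
                          lockout_s = 0.001) {
  half <- max(1L, round(snippet_s / 2 * fs))
  if (length(x) < 2L * half + 1L) stop("signal shorter than the snippet window")
  if (max(abs(x)) == 0) return(list())
  sigma <- stats::mad(x)
  thr <- k_mad * sigma   # on a spike-free trace mad() is the noise SD / 0.6745 scaling
  lock <- max(1L, round(lockout_s * fs))
  above <- abs(x) > thr
  events <- integer(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (above[i]) {
      hi <- min(n, i + lock)
      p <- i - 1L + which.max(abs(x[i:hi]))
      events <- c(events, p)
      i <- p + lock + 1L
      while (i <= n && above[i]) i <- i + 1L  # ride out the rest of the excursion
    } else i <- i + 1L
  }
  events <- events[events - half >= 1L & events + half <= n]
  lapply(events, function(p) list(time = (p - 1) / fs,
                                  snippet = x[(p - half):(p + half)],
                                  fs = fs))
}

width_at_half <- function(snip, peak_idx, fs) {
  # full width at half extremum around peak_idx, in seconds; the half-height
  # crossings are located by linear interpolation between samples so widths
  # vary continuously with noise rather than being quantised to the grid
  hv <- snip[peak_idx] / 2
  sgn <- sign(snip[peak_idx])
  ok <- sgn * snip >= sgn * hv
  l <- peak_idx
  while (l > 1L && ok[l - 1L]) l <- l - 1L
  r <- peak_idx
  while (r < length(snip) && ok[r + 1L]) r <- r + 1L
  lpos <- l
  if (l > 1L) {
    d <- snip[l] - snip[l - 1L]
    if (d != 0) lpos <- l - (snip[l] - hv) / d
  }
  rpos <- r
  if (r < length(snip)) {
    d <- snip[r] - snip[r + 1L]
    if (d != 0) rpos <- r + (snip[r] - hv) / d
  }
  (rpos - lpos + 1) / fs
}

#' Waveform features for clustering
#'
#' Peak height, peak width, trough depth and trough width (widths are full
#' width at half extremum, in s), plus the projections onto the first three
#' principal components of the mean-centred snippets. With fewer events than
#' snippet dimensions the missing principal components are zero.
#'
#' @param events Event list from \code{\link{detect_events}}.
#' @return Numeric matrix, one row per event, columns \code{peak_height},
#'   \code{peak_width}, \code{trough_depth}, \code{trough_width},
#'   \code{pc1..pc3}.
#' @export
featurize <- function(events) {
  if (!length(events)) stop("no events to featurize")
  fs <- events[[1]]$fs
  snips <- do.call(rbind, lapply(events, `[[`, "snippet"))
  base <- t(vapply(events, function(e) {
    s <- e$snippet
    pk <- which.max(s); tr <- which.min(s)
    c(peak_height = s[pk],
      peak_width = width_at_half(s, pk, fs),
      trough_depth = s[tr],
      trough_width = width_at_half(s, tr, fs))
  }, numeric(4)))
  pcs <- matrix(0, nrow(snips), 3,
                dimnames = list(NULL, c("pc1", "pc2", "pc3")))
  ctr <- sweep(snips, 2, colMeans(snips))
  if (nrow(snips) > 1 && any(abs(ctr) > 0)) {
    pr <- stats::prcomp(snips, center = TRUE, scale. = FALSE)
    k <- min(3L, ncol(pr$x))
    pcs[, seq_len(k)] <- pr$x[, seq_len(k), drop = FALSE]
  }
  cbind(base, pcs)
}

#' Cluster spike events with a mixture of Gaussians
#'
#' Fits Gaussian mixtures for k = 1..k_max and keeps the model selected by
#' the Bayesian information criterion.
#'
#' @param features Feature matrix from \code{\link{featurize}}.
#' @param k_max Maximum number of mixture components (default 5).
#' @param seed RNG seed for the EM initialisation (default 1).
#' @return List with \code{labels} (integer cluster per event) and
#'   \code{k} (chosen number of components).
#' @export
cluster_events <- function(features, k_max = 5, seed = 1L) {
  if (nrow(features) < k_max + 1)
    stop("need at least k_max + 1 events to cluster")
  keep <- apply(features, 2, function(col) stats::sd(col) > 0)
  x <- features[, keep, drop = FALSE]
  if (ncol(x) == 0)
    return(list(labels = rep(1L, nrow(features)), k = 1L))
  set.seed(seed)
  fit <- tryCatch(
    Mclust(x, G = 1:k_max, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(labels = rep(1L, nrow(features)), k = 1L))
  list(labels = as.integer(fit$classification), k = fit$G)
}

cluster_template <- function(events, labels, cl) {
  snips <- do.call(rbind, lapply(events[labels == cl], `[[`, "snippet"))
  colMeans(snips)
}

match_error <- function(snippet, template, match_idx, max_shift = 1L) {
  # least-squares error over the matching window, tolerant to +/- 1 sample of
  # detection jitter (at low sampling rates the detection peak can land on
  # either neighbour of the true extremum)
  shifts <- -max_shift:max_shift
  m <- length(snippet)
  errs <- vapply(shifts, function(k) {
    idx <- match_idx + k
    if (min(idx) < 1L || max(idx) > m) return(Inf)
    sum((snippet[idx] - template[match_idx])^2)
  }, numeric(1))
  min(errs)
}

#' Select the best-isolated cluster
#'
#' An automated surrogate for visual cluster selection: each cluster is
#' scored by the peak-to-peak amplitude of its mean waveform divided by the
#' median RMS residual of its members around that mean (an SNR-like isolation
#' score). The best cluster must score at least \code{min_isolation}
#' (default 3, the isolation customarily demanded of a single unit);
#' otherwise no unit is accepted and \code{NULL} is returned.
#'
#' @param events Event list.
#' @param labels Cluster labels from \code{\link{cluster_events}}.
#' @param min_isolation Minimum isolation score (default 3).
#' @return List with \code{cluster} (id) and \code{score}, plus
#'   \code{scores} for all clusters; or \code{NULL} if no cluster qualifies.
#' @export
select_best_cluster <- function(events, labels, min_isolation = 3) {
  cls <- sort(unique(labels))
  if (!length(cls)) stop("no clusters")
  scores <- vapply(cls, function(cl) {
    snips <- do.call(rbind, lapply(events[labels == cl], `[[`, "snippet"))
    tmpl <- colMeans(snips)
    res <- sqrt(rowMeans(sweep(snips, 2, tmpl)^2))
    p2p <- diff(range(tmpl))
    denom <- stats::median(res)
    if (denom <= 0) denom <- .Machine$double.eps
    p2p / denom
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] < min_isolation) return(NULL)
  list(cluster = cls[best], score = scores[best],
       scores = stats::setNames(scores, cls))
}

#' Build a unit template from a cluster
#'
#' The template waveform is the mean snippet of the selected cluster. The
#' least-squares acceptance threshold defaults to \code{accept_mult} times
#' the median matched-event error: the median squared error of all detected
#' events against the template over a central matching window (default
#' 1 ms). The median is robust to the minority of noise events, and using
#' all events rather than only the cluster's members keeps the threshold
#' wide enough when the mixture model splits one unit into sub-clusters
#' (e.g. by sub-sample alignment phase at low sampling rates).
#'
#' @param events Event list.
#' @param labels Cluster labels.
#' @param cluster Cluster id to build the template from.
#' @param fs Sampling rate, Hz.
#' @param match_s Central matching window, s (default 0.001).
#' @param accept_mult Threshold multiplier (default 3).
#' @return A \code{unit_template}: list with \code{waveform},
#'   \code{accept_threshold}, \code{match_idx}.
#' @export
build_template <- function(events, labels, cluster, fs,
                           match_s = 0.001, accept_mult = 3) {
  tmpl <- cluster_template(events, labels, cluster)
  m <- length(tmpl)
  ctr <- (m + 1L) %/% 2L
  halfm <- max(1L, round(match_s / 2 * fs))
  match_idx <- max(1L, ctr - halfm):min(m, ctr + halfm)
  errs <- vapply(events, function(e)
    match_error(e$snippet, tmpl, match_idx), numeric(1))
  thr <- accept_mult * stats::median(errs)
  if (thr <= 0) thr <- 1e-12 * sum(tmpl[match_idx]^2) + .Machine$double.eps
  structure(list(waveform = tmpl, accept_threshold = thr,
                 match_idx = match_idx),
            class = "unit_template")
}

#' Accept spikes by least-squares template match
#'
#' Every detected event is compared to the unit template over the central
#' matching window; events whose summed squared error falls below the
#' template's acceptance threshold are returned as spikes of the unit.
#'
#' @param events Event list (all events, any cluster).
#' @param template A \code{unit_template} from \code{\link{build_template}}.
#' @return Sorted vector of accepted spike times, s.
#' @export
template_match <- function(events, template) {
  if (!length(events)) return(numeric(0))
  errs <- vapply(events, function(e)
    match_error(e$snippet, template$waveform, template$match_idx), numeric(1))
  sort(vapply(events[errs < template$accept_threshold], `[[`,
              numeric(1), "time"))
}

#' End-to-end spike sorting over a set of aligned trials
#'
#' Band-passes each trial into the spike band, detects events, pools them
#' across trials, clusters, selects the best-isolated cluster, builds its
#' template and template-matches all events. The spike band defaults to
#' 300-3000 Hz, capped at 0.9 of the Nyquist frequency for low sampling
#' rates.
#'
#' @param aligned List of \code{aligned_trial} objects (one recording site).
#' @param k_mad Detection threshold (default 4).
#' @param k_max Maximum clusters (default 5).
#' @param seed Clustering seed (default 1).
#' @param band Spike band, Hz (default \code{c(300, 3000)}, Nyquist-capped).
#' @param min_isolation Minimum isolation score (default 3).
#' @return List with \code{spikes} (data frame \code{trial_id},
#'   \code{spike_time_s}), \code{template}, \code{isolation}, \code{k}; or
#'   \code{NULL} if no unit passes the isolation criterion.
#' @export
sort_spikes <- function(aligned, k_mad = 4, k_max = 5, seed = 1L,
                        band = c(300, 3000), min_isolation = 3) {
  if (!length(aligned)) stop("no trials to sort")
  fs <- aligned[[1]]$fs
  band[2] <- min(band[2], 0.9 * fs / 2)
  if (band[1] >= band[2]) stop("spike band collapsed below Nyquist; raise fs")
  events <- list()
  owner <- integer(0)
  for (i in seq_along(aligned)) {
    filt <- bandpass(aligned[[i]]$lfp, band, fs)
    ev <- detect_events(filt, fs, k_mad = k_mad)
    events <- c(events, ev)
    owner <- c(owner, rep(i, length(ev)))
  }
  if (length(events) < k_max + 1) return(NULL)
  feats <- featurize(events)
  cl <- cluster_events(feats, k_max = k_max, seed = seed)
  sel <- select_best_cluster(events, cl$labels, min_isolation = min_isolation)
  if (is.null(sel)) return(NULL)
  tmpl <- build_template(events, cl$labels, sel$cluster, fs)
  errs_ok <- vapply(events, function(e)
    match_error(e$snippet, tmpl$waveform, tmpl$match_idx) <
      tmpl$accept_threshold, logical(1))
  spikes <- data.frame(
    trial_id = vapply(which(errs_ok), function(k)
      aligned[[owner[k]]]$trial_id, numeric(1)),
    trial_index = owner[errs_ok],
    spike_time_s = vapply(events[errs_ok], `[[`, numeric(1), "time"))
  spikes <- spikes[order(spikes$trial_index, spikes$spike_time_s), ]
  rownames(spikes) <- NULL
  list(spikes = spikes, template = tmpl, isolation = sel$score, k = cl$k)
}
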
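#' Shift grid for asynchronous classification
#'
#' Time shifts over which each template/model is compared to a test trial to
#' compensate for unknown absolute response start times.
#'
#' @param span Half-range in s (default 0.1, i.e. -100 ms to +100 ms).
#' @param step Resolution in s (default 0.0025).
#' @return Numeric vector of shifts, symmetric about and containing 0.
#' @export
shift_grid <- function(span = 0.1, step = 0.0025) {
  if (span < 0 || step <= 0) stop("invalid shift grid")
  g <- seq(-span, span, by = step)
  if (!any(g == 0)) stop("shift grid must contain 0")
  g
}

# order in which shifts are scanned so that which.max() implements the
# deterministic tie-break: smallest |tau| first, negative before positive
shift_scan_order <- function(grid) order(abs(grid), grid)

#' Fit per-condition Gaussian LFP template models
#'
#' For each condition the template mu_j is the pointwise mean voltage over
#' training trials, and the scalar noise sigma_j is the mean over time of
#' the across-trial standard deviation (isotropic diagonal covariance).
#' sigma is floored at 1e-9 so degenerate noiseless inputs stay usable.
#'
#' @param aligned List of \code{aligned_trial} objects (training set).
#' @return An \code{lfp_template_model}: list with \code{mu} (list of
#'   N-vectors by condition j), \code{sigma} (numeric by j), \code{N},
#'   \code{fs}.
#' @export
fit_lfp_templates <- function(aligned) {
  js <- vapply(aligned, function(tr) tr$condition$j, integer(1))
  mu <- vector("list", 6)
  sigma <- rep(NA_real_, 6)
  N <- length(aligned[[1]]$lfp)
  for (j in sort(unique(js))) {
    V <- do.call(rbind, lapply(aligned[js == j], `[[`, "lfp"))
    if (nrow(V) < 2)
      stop("fit_lfp_templates: need >= 2 trials per condition (sigma undefined)")
    mu[[j]] <- colMeans(V)
    sigma[j] <- max(mean(apply(V, 2, stats::sd)), 1e-9)
  }
  structure(list(mu = mu, sigma = sigma, N = N, fs = aligned[[1]]$fs),
            class = "lfp_template_model")
}

#' Gaussian LFP log-likelihood (up to the constant in j)
#'
#' Log-likelihood of an N-sample voltage window under condition j's template
#' model with isotropic noise:
#' \code{-0.5 * ||v - mu||^2 / sigma^2 - 0.5 * N * log(sigma^2)}. The
#' additive constant \code{-N/2 log(2 pi)}, identical across conditions, is
#' omitted.
#'
#' @param v Voltage vector of length N.
#' @param mu Template mean, length N.
#' @param sigma Scalar noise standard deviation.
#' @return Log-likelihood value.
#' @export
lfp_loglik <- function(v, mu, sigma) {
  if (length(v) != length(mu)) stop("lfp_loglik: length mismatch")
  -0.5 * sum((v - mu)^2) / sigma^2 - 0.5 * length(v) * log(sigma^2)
}

# matrix of shifted N-windows of v_ext, one row per shift (scan order)
shift_window_matrix <- function(v_ext, N, fs, grid_scan) {
  pad_n <- (length(v_ext) - N) / 2
  if (pad_n < 0 || pad_n != round(pad_n))
    stop("extended trace length incompatible with window length")
  k <- round(grid_scan * fs)
  if (any(pad_n + k < 0) || any(pad_n + k + N > length(v_ext)))
    stop("extended trace too short for the requested shifts")
  idx <- outer(pad_n + k, seq_len(N), `+`)
  matrix(v_ext[idx], nrow = length(k), ncol = N)
}

#' Shift-invariant maximum-likelihood LFP classification
#'
#' For every condition the template log-likelihood is maximised over the
#' shift grid; the predicted condition is the one with the largest maximum.
#' Ties are broken deterministically: lowest condition index, then smallest
#' absolute shift, then negative shift first.
#'
#' @param v_ext Extended voltage trace (the 750 ms window plus symmetric
#'   padding covering the shift span).
#' @param model An \code{lfp_template_model}.
#' @param grid Shift grid from \code{\link{shift_grid}}.
#' @return List with \code{j} (predicted condition), \code{tau} (best
#'   shift, s) and \code{loglik} (6 x n_shifts matrix in grid order).
#' @export
classify_lfp <- function(v_ext, model, grid = shift_grid()) {
  ord <- shift_scan_order(grid)
  W <- shift_window_matrix(v_ext, model$N, model$fs, grid[ord])
  vv <- rowSums(W * W)
  ll <- matrix(-Inf, 6, length(grid))
  best_ll <- rep(-Inf, 6)
  best_tau <- rep(NA_real_, 6)
  for (j in 1:6) {
    if (is.null(model$mu[[j]])) next
    s2 <- model$sigma[j]^2
    lj <- -0.5 * (vv - 2 * drop(W %*% model$mu[[j]]) + sum(model$mu[[j]]^2)) / s2 -
      0.5 * model$N * log(s2)
    i <- which.max(lj)
    best_ll[j] <- lj[i]
    best_tau[j] <- grid[ord][i]
    ll[j, ord] <- lj
  }
  jstar <- which.max(best_ll)
  list(j = jstar, tau = best_tau[jstar], loglik = ll)
}

#' Fit per-condition Bernoulli spike-probability models
#'
#' The analysis window is divided into bins of \code{bin_width}; for each bin
#' p_i is the fraction of training trials with at least one spike in that
#' bin (so a bin occupied in every trial attains 1), clipped to the interval
#' \code{[p_min, 1 - 1e-6]} where \code{p_min = spontaneous_rate * bin_width}
#' is the floor set by the average spontaneous rate.
#'
#' @param spike_trains List of spike-time vectors (s in \code{[0, T)}), the
#'   training trials of one condition.
#' @param bin_width Bin width, s (default 0.003).
#' @param spontaneous_rate Average spontaneous rate, spikes/s.
#' @param T Window length, s (default 0.75).
#' @return A \code{spike_prob_model}: list with \code{p} (length N),
#'   \code{bin_width}, \code{T}, \code{N}, \code{p_min}.
#' @export
fit_spike_model <- function(spike_trains, bin_width = 0.003,
                            spontaneous_rate = 0, T = 0.75) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!length(spike_trains)) stop("need at least one training trial")
  N <- round(T / bin_width)
  occ <- vapply(spike_trains, function(st) {
    st <- st[st >= 0 & st < T]
    o <- logical(N)
    if (length(st)) o[unique(floor(st / bin_width) + 1L)] <- TRUE
    o
  }, logical(N))
  p <- rowMeans(matrix(occ, nrow = N))
  p_min <- min(spontaneous_rate * bin_width, 1 - 1e-6)
  p <- pmin(pmax(p, p_min), 1 - 1e-6)
  structure(list(p = p, bin_width = bin_width, T = T, N = N, p_min = p_min),
            class = "spike_prob_model")
}

#' Bernoulli spike-train log-likelihood
#'
#' Joint log-probability of a spike train under a binned Bernoulli model:
#' occupied bins (at least one spike; multiple spikes count once) contribute
#' \code{log(p_i)}, empty bins \code{log(1 - p_i)}.
#'
#' @param spike_times Spike times, s; all must lie in \code{[0, T)}.
#' @param model A \code{spike_prob_model}.
#' @return Log-likelihood value.
#' @export
spike_loglik <- function(spike_times, model) {
  if (length(spike_times) && (any(spike_times < 0) || any(spike_times >= model$T)))
    stop("spike_loglik: spike time outside [0, T)")
  occ <- unique(floor(spike_times / model$bin_width) + 1L)
  base <- sum(log1p(-model$p))
  if (!length(occ)) return(base)
  base + sum(log(model$p[occ]) - log1p(-model$p[occ]))
}

#' Shift-invariant maximum-likelihood spike-train classification
#'
#' For each shift tau on the grid the spike train is shifted by -tau, spikes
#' falling outside \code{[0, T)} are dropped, and the Bernoulli
#' log-likelihood is evaluated; each condition's likelihood is the maximum
#' over shifts and the predicted condition is the argmax, with the same
#' deterministic tie-breaking as \code{\link{classify_lfp}}.
#'
#' @param spike_times_ext Spike times in s relative to the analysis-window
#'   start, including spikes in the padded margins (may be negative).
#' @param models List of \code{spike_prob_model} indexed by condition j.
#' @param grid Shift grid from \code{\link{shift_grid}}.
#' @return List with \code{j}, \code{tau} and \code{loglik} (6 x n_shifts).
#' @export
classify_spikes <- function(spike_times_ext, models, grid = shift_grid()) {
  ord <- shift_scan_order(grid)
  gs <- grid[ord]
  have <- !vapply(models, is.null, logical(1))
  base <- vapply(models, function(m) if (is.null(m)) -Inf else sum(log1p(-m$p)),
                 numeric(1))
  logit <- lapply(models, function(m)
    if (is.null(m)) NULL else log(m$p) - log1p(-m$p))
  ll <- matrix(-Inf, 6, length(grid))
  for (s in seq_along(gs)) {
    for (j in which(have)) {
      m <- models[[j]]
      t2 <- spike_times_ext - gs[s]
      t2 <- t2[t2 >= 0 & t2 < m$T]
      occ <- unique(floor(t2 / m$bin_width) + 1L)
      ll[j, ord[s]] <- base[j] + sum(logit[[j]][occ])
    }
  }
  best_i <- apply(ll[, ord, drop = FALSE], 1, which.max)
  best_ll <- ll[cbind(1:6, ord[best_i])]
  jstar <- which.max(best_ll)
  list(j = jstar, tau = gs[best_i[jstar]], loglik = ll)
}

estimate_spontaneous_rate <- function(trains, baseline_s = 0.15,
                                      exclude = 0L) {
  # pooled rate in the first baseline_s of the aligned window (pre-contact)
  keep <- setdiff(seq_along(trains), exclude)
  n_sp <- sum(vapply(trains[keep], function(st)
    sum(st >= 0 & st < baseline_s), numeric(1)))
  n_sp / (length(keep) * baseline_s)
}

#' Leave-one-out cross-validated decoding
#'
#' For every trial, the per-condition models (LFP templates or Bernoulli
#' spike models) are refit on all remaining trials and the held-out trial is
#' classified with the shift-invariant rule. Results are aggregated into a
#' row-stochastic confusion matrix (rows = true condition) and an overall
#' accuracy.
#'
#' @param aligned List of \code{aligned_trial} objects (>= 2 per condition).
#' @param classifier \code{"lfp"} or \code{"spikes"}.
#' @param grid Shift grid (default \code{\link{shift_grid}()}).
#' @param bin_width Spike-model bin width, s (default 0.003).
#' @param spontaneous_rate Spontaneous rate for the spike-probability floor;
#'   \code{NULL} (default) estimates it per fold from the pre-contact
#'   baseline of the training trials.
#' @param spike_trains Optional list of spike-time vectors parallel to
#'   \code{aligned} overriding each trial's \code{spike_times} (e.g. sorted
#'   spikes); used only by the spike classifier.
#' @param balance_training Balance per-fold training-set sizes (default
#'   \code{TRUE}): besides holding out the test trial, one matched-index
#'   trial of every other condition is dropped, so all conditions train on
#'   the same number of trials. Unbalanced folds (n-1 vs n training trials)
#'   measurably bias classification on uninformative data — against the true
#'   condition for the Gaussian template likelihood and towards it for the
#'   Bernoulli spike model; balancing restores exchangeability so chance-level
#'   data decode at exactly 1/6 in expectation, and has negligible effect on
#'   informative data. \code{FALSE} trains on all remaining trials.
#' @return A \code{decode_result}: list with \code{trials} (data frame
#'   \code{trial_id}, \code{true}, \code{predicted}, \code{tau}),
#'   \code{confusion} (6 x 6, rows normalised), \code{accuracy}.
#' @export
loocv <- function(aligned, classifier = c("lfp", "spikes"),
                  grid = shift_grid(), bin_width = 0.003,
                  spontaneous_rate = NULL, spike_trains = NULL,
                  balance_training = TRUE) {
  classifier <- match.arg(classifier)
  js <- vapply(aligned, function(tr) tr$condition$j, integer(1))
  cnt <- tabulate(js, 6)
  if (any(cnt[unique(js)] < 2)) stop("loocv: need >= 2 trials per condition")
  n <- length(aligned)
  pred <- integer(n); tau <- numeric(n)
  row_in_cond <- integer(n)
  for (j in which(cnt > 0)) row_in_cond[js == j] <- seq_len(cnt[j])
  # index of the matched trial to drop from condition j in trial i's fold
  drop_of <- function(i, j) {
    if (js[i] == j) row_in_cond[i]
    else if (balance_training) (row_in_cond[i] - 1L) %% cnt[j] + 1L
    else 0L
  }

  if (classifier == "lfp") {
    N <- length(aligned[[1]]$lfp)
    fs <- aligned[[1]]$fs
    V <- lapply(1:6, function(j)
      if (cnt[j]) do.call(rbind, lapply(aligned[js == j], `[[`, "lfp")) else NULL)
    S1 <- lapply(V, function(M) if (is.null(M)) NULL else colSums(M))
    S2 <- lapply(V, function(M) if (is.null(M)) NULL else colSums(M^2))
    full <- lapply(1:6, function(j) {
      if (is.null(V[[j]])) return(NULL)
      nj <- cnt[j]
      sd_t <- sqrt(pmax((S2[[j]] - S1[[j]]^2 / nj) / (nj - 1), 0))
      list(mu = S1[[j]] / nj, sigma = max(mean(sd_t), 1e-9))
    })
    loo_model <- function(j, drop) {
      v_d <- V[[j]][drop, ]
      nj <- cnt[j] - 1L
      s1 <- S1[[j]] - v_d
      s2 <- S2[[j]] - v_d^2
      sd_t <- if (nj > 1) sqrt(pmax((s2 - s1^2 / nj) / (nj - 1), 0)) else 0
      list(mu = s1 / nj, sigma = max(mean(sd_t), 1e-9))
    }
    for (i in seq_len(n)) {
      mods <- lapply(1:6, function(j) {
        if (is.null(V[[j]])) return(NULL)
        d <- drop_of(i, j)
        if (d > 0L) loo_model(j, d) else full[[j]]
      })
      model <- structure(list(mu = lapply(mods, function(m) m$mu),
                              sigma = vapply(mods, function(m)
                                if (is.null(m)) NA_real_ else m$sigma, numeric(1)),
                              N = N, fs = fs),
                         class = "lfp_template_model")
      res <- classify_lfp(aligned[[i]]$lfp_ext, model, grid)
      pred[i] <- res$j; tau[i] <- res$tau
    }
  } else {
    trains <- lapply(seq_len(n), function(i) {
      st <- if (is.null(spike_trains)) aligned[[i]]$spike_times_ext
            else spike_trains[[i]]
      st %||% numeric(0)
    })
    Tw <- aligned[[1]]$window_s
    idx_of <- lapply(1:6, function(j) which(js == j))
    for (i in seq_len(n)) {
      sr <- spontaneous_rate %||%
        estimate_spontaneous_rate(trains, exclude = i)
      mods <- lapply(1:6, function(j) {
        sel <- idx_of[[j]]
        if (!length(sel)) return(NULL)
        d <- drop_of(i, j)
        if (d > 0L && length(sel) > 1L) sel <- sel[-d]
        fit_spike_model(trains[sel], bin_width = bin_width,
                        spontaneous_rate = sr, T = Tw)
      })
      res <- classify_spikes(trains[[i]], mods, grid)
      pred[i] <- res$j; tau[i] <- res$tau
    }
  }

  conf <- matrix(0, 6, 6, dimnames = list(conditions()$label, conditions()$label))
  for (i in seq_len(n)) conf[js[i], pred[i]] <- conf[js[i], pred[i]] + 1
  occ <- rowSums(conf) > 0
  conf[occ, ] <- conf[occ, , drop = FALSE] / rowSums(conf)[occ]
  structure(list(
    trials = data.frame(
      trial_id = vapply(aligned, function(tr) as.numeric(tr$trial_id), numeric(1)),
      true = js, predicted = pred, tau = tau),
    confusion = conf,
    accuracy = mean(pred == js)),
    class = "decode_result")
}

#' Compare per-site decoding accuracies
#'
#' Two-sided Wilcoxon rank-sum test on per-recording-site classification
#' accuracies of two decoders.
#'
#' @param acc_a,acc_b Numeric vectors of per-site accuracies (same length,
#'   at least 3 sites each).
#' @return Two-sided p-value (1 if all values are identical).
#' @export
compare_accuracies <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 3)
    stop("compare_accuracies: need equal-length lists with >= 3 sites")
  if (length(unique(c(acc_a, acc_b))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(acc_a, acc_b)$p.value)
}
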
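#' Build a trial-by-phase tuning table
#'
#' Splits each aligned trial into pre-contact, contact and post-contact
#' phases using the condition's contact window and computes one response
#' value per phase: the spike rate (spikes/s) or the RMS of a band envelope.
#' Trials whose condition has no contact window are skipped with a message.
#'
#' @param aligned List of \code{aligned_trial} objects.
#' @param windows List of \code{contact_window} objects indexed by condition
#'   j (1..6), e.g. from \code{\link{find_contact_window}} per condition.
#' @param measure Either \code{"spike_rate"} or a numeric length-2 band
#'   \code{c(lo, hi)} in Hz (envelope RMS).
#' @param spike_trains Optional list of spike-time vectors parallel to
#'   \code{aligned} (defaults to each trial's own \code{spike_times}).
#' @return Data frame with columns \code{trial_id}, \code{phase}
#'   (\code{pre}/\code{contact}/\code{post}), \code{speed},
#'   \code{direction}, \code{response}; three rows per trial.
#' @export
build_tuning_table <- function(aligned, windows, measure = "spike_rate",
                               spike_trains = NULL) {
  is_band <- is.numeric(measure) && length(measure) == 2
  rows <- vector("list", length(aligned))
  for (i in seq_along(aligned)) {
    tr <- aligned[[i]]
    win <- windows[[tr$condition$j]]
    if (is.null(win)) {
      message("skipping trial ", tr$trial_id, ": no contact window for its condition")
      next
    }
    W <- tr$window_s
    bounds <- rbind(pre = c(0, win$start),
                    contact = c(win$start, win$end),
                    post = c(win$end, W))
    if (is_band) env <- band_envelope(tr$lfp, measure, tr$fs)
    st <- if (is.null(spike_trains)) tr$spike_times else spike_trains[[i]]
    resp <- vapply(rownames(bounds), function(ph) {
      a <- bounds[ph, 1]; b <- bounds[ph, 2]
      if (b <= a) return(NA_real_)
      if (is_band) {
        s0 <- floor(a * tr$fs) + 1L
        s1 <- min(length(env), ceiling(b * tr$fs))
        sqrt(mean(env[s0:s1]^2))
      } else {
        sum(st >= a & st < b) / (b - a)
      }
    }, numeric(1))
    rows[[i]] <- data.frame(trial_id = tr$trial_id,
                            phase = rownames(bounds),
                            speed = tr$condition$speed,
                            direction = tr$condition$direction,
                            response = as.numeric(resp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-factor ANOVA on a tuning table
#'
#' Fixed-effects ANOVA with main effects of contact phase, sweep speed and
#' sweep direction (no interactions), Type-II sums of squares. A constant
#' response (undefined F) yields p = 1 for every factor.
#'
#' @param table Tuning table from \code{\link{build_tuning_table}}.
#' @param alpha Significance level (default 0.05).
#' @return List with \code{p_phase}, \code{p_speed}, \code{p_direction},
#'   \code{tuned_speed}, \code{tuned_direction}, \code{alpha}.
#' @export
anova_main_effects <- function(table, alpha = 0.05) {
  tab <- table[stats::complete.cases(table[c("phase", "speed", "direction",
                                             "response")]), ]
  for (f in c("phase", "speed", "direction"))
    if (length(unique(tab[[f]])) < 2)
      stop("anova_main_effects: factor '", f, "' has fewer than 2 levels")
  ps <- c(phase = 1, speed = 1, direction = 1)
  if (stats::var(tab$response) > 0) {
    dat <- data.frame(response = tab$response,
                      phase = factor(tab$phase),
                      speed = factor(tab$speed),
                      direction = factor(tab$direction))
    fit <- stats::lm(response ~ phase + speed + direction, data = dat)
    an <- car::Anova(fit, type = 2)
    pv <- an[["Pr(>F)"]]
    names(pv) <- rownames(an)
    for (f in names(ps)) {
      p <- pv[[f]]
      ps[[f]] <- if (is.null(p) || !is.finite(p)) 1 else p
    }
  }
  list(p_phase = ps[["phase"]], p_speed = ps[["speed"]],
       p_direction = ps[["direction"]],
       tuned_speed = ps[["speed"]] < alpha,
       tuned_direction = ps[["direction"]] < alpha,
       alpha = alpha)
}

#' Fraction of units tuned to speed, direction, or both
#'
#' @param results List of results from \code{\link{anova_main_effects}}, one
#'   per unit (optionally each carrying a \code{band} label).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per band (or a single \code{"spike_rate"}
#'   row) and columns \code{pct_speed}, \code{pct_direction},
#'   \code{pct_both} in percent, plus \code{n_units}.
#' @export
tuned_fractions <- function(results, alpha = 0.05) {
  if (!length(results)) stop("tuned_fractions: no results")
  bands <- vapply(results, function(r) r$band %||% "spike_rate", character(1))
  out <- lapply(unique(bands), function(b) {
    rs <- results[bands == b]
    sp <- vapply(rs, function(r) r$p_speed < alpha, logical(1))
    di <- vapply(rs, function(r) r$p_direction < alpha, logical(1))
    data.frame(band = b,
               pct_speed = 100 * mean(sp),
               pct_direction = 100 * mean(di),
               pct_both = 100 * mean(sp & di),
               n_units = length(rs))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default LFP filterbank bands
#'
#' The band list spans the slow LFP through multi-unit frequencies,
#' including the multi-unit bands known to carry strong speed and direction
#' information. Bands above Nyquist for a given sampling rate should be
#' dropped by the caller.
#'
#' @return List of numeric length-2 vectors, Hz.
#' @export
default_bands <- function() {
  list(c(1, 100), c(100, 300), c(100, 3000), c(300, 1000),
       c(300, 3000), c(1000, 3000), c(1000, 5000), c(1500, 4200))
}
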
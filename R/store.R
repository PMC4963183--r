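#' Write a trial set to a plain-text trial store
#'
#' Persists a dataset as a directory holding \code{meta.csv} (one row per
#' trial: id, condition, fs, duration, jitter, ground-truth contact window),
#' \code{voltage.csv} (one row of voltage samples per trial) and
#' \code{spikes.csv} (columns \code{trial_id}, \code{condition},
#' \code{spike_time_s}, mirroring the spreadsheet layout used for published
#' per-trial spike times).
#'
#' @param trials List of \code{raw_trial} objects.
#' @param dir Directory to create/write into.
#' @return \code{dir}, invisibly.
#' @export
write_trial_store <- function(trials, dir) {
  if (!length(trials)) stop("no trials to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id %||% NA_integer_,
               speed = tr$condition$speed,
               direction = tr$condition$direction,
               fs = tr$fs,
               trial_duration = tr$trial_duration,
               jitter = tr$jitter %||% NA_real_,
               win_start = tr$true_contact_window[1] %||% NA_real_,
               win_end = tr$true_contact_window[2] %||% NA_real_,
               n_spikes = length(tr$true_spike_times))
  }))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  vmat <- do.call(rbind, lapply(trials, `[[`, "voltage"))
  utils::write.table(vmat, file.path(dir, "voltage.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(spike_times_table(trials), file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a trial set back from a trial store
#'
#' @param dir Directory written by \code{\link{write_trial_store}}.
#' @return List of \code{raw_trial} objects.
#' @export
read_trial_store <- function(dir) {
  meta_path <- file.path(dir, "meta.csv")
  if (!file.exists(meta_path)) stop("not a trial store: missing meta.csv")
  meta <- utils::read.csv(meta_path)
  vmat <- as.matrix(utils::read.table(file.path(dir, "voltage.csv"), sep = ","))
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  if (nrow(vmat) != nrow(meta)) stop("trial store corrupt: voltage/meta mismatch")
  lapply(seq_len(nrow(meta)), function(i) {
    st <- spikes$spike_time_s[spikes$trial_id == meta$trial_id[i]]
    structure(list(voltage = as.numeric(vmat[i, ]),
                   fs = meta$fs[i],
                   condition = condition(meta$speed[i], meta$direction[i]),
                   true_spike_times = as.numeric(st),
                   true_contact_window = c(meta$win_start[i], meta$win_end[i]),
                   jitter = meta$jitter[i],
                   trial_duration = meta$trial_duration[i],
                   trial_id = meta$trial_id[i]),
              class = "raw_trial")
  })
}

#' Per-trial spike-time table
#'
#' @param trials List of \code{raw_trial} objects with ground-truth spikes.
#' @return Data frame with columns \code{trial_id}, \code{condition}
#'   (label), \code{spike_time_s}.
#' @export
spike_times_table <- function(trials) {
  rows <- lapply(trials, function(tr) {
    if (!length(tr$true_spike_times)) return(NULL)
    data.frame(trial_id = tr$trial_id %||% NA_integer_,
               condition = paste0(tr$condition$speed, "_", tr$condition$direction),
               spike_time_s = tr$true_spike_times)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(trial_id = integer(), condition = character(),
                      spike_time_s = numeric())
}
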
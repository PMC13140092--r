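#' Continuous multichannel EEG recording
#'
#' Light container for a continuous voltage time-series: a channel-by-sample
#' matrix in microvolts, the sampling rate, and an aligned events table.
#'
#' @param channels Character vector of channel names.
#' @param rate_hz Sampling rate in Hz.
#' @param data Numeric matrix, `length(channels)` rows by n-samples columns,
#'   in microvolts.
#' @param events Events data frame with at least columns `onset` (seconds)
#'   and `sample` (0-based sample index); see [empty_events()] for the full
#'   column set used by the oddball generator.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(channels, rate_hz, data, events = empty_events()) {
  stopifnot(is.matrix(data), nrow(data) == length(channels), rate_hz > 0)
  if (nrow(events) > 0) {
    stopifnot(all(events$sample >= 0), all(events$sample < ncol(data)))
  }
  structure(
    list(channels = as.character(channels), rate_hz = rate_hz,
         data = data, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, nrow(x$events)))
  invisible(x)
}

# canonical empty events table (column contract shared with the events TSV)
empty_events <- function() {
  data.frame(
    onset = numeric(0), sample = integer(0),
    trial_type = character(0), condition = character(0),
    response = character(0), correct = integer(0), rt_ms = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Set of peristimulus epochs
#'
#' Per-trial voltage segments on a fixed peristimulus time grid, with trial
#' labels and artifact-rejection flags. Rejection never drops epochs; it only
#' flags them, so the epoch count always equals the event count.
#'
#' @param times_ms Numeric vector, the peristimulus time grid in ms.
#' @param data 3-d numeric array `trial x channel x time` in microvolts.
#' @param labels Data frame with one row per trial; columns `class`,
#'   `condition`, `participant` (further columns are carried along).
#' @param channels Channel names (length = `dim(data)[2]`).
#' @param rejected Logical vector per trial.
#' @param reject_reason Character per trial: `""`, `"amplitude"` or `"edge"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(times_ms, data, labels, channels,
                      rejected = rep(FALSE, dim(data)[1]),
                      reject_reason = rep("", dim(data)[1])) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == nrow(labels),
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times_ms),
            length(rejected) == dim(data)[1])
  structure(
    list(times_ms = times_ms, data = data, labels = labels,
         channels = as.character(channels), rejected = rejected,
         reject_reason = reject_reason),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples [%g, %g] ms; %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms), sum(x$rejected)))
  invisible(x)
}

# number of clean (unrejected) epochs, optionally for one stimulus class
n_clean_epochs <- function(epochs, class = NULL) {
  keep <- !epochs$rejected
  if (!is.null(class)) keep <- keep & epochs$labels$class %in% class
  sum(keep)
}

#' Trial-averaged ERP waveform
#'
#' @param channels Channel names.
#' @param times_ms Peristimulus time grid in ms.
#' @param voltages Channel-by-time matrix of averaged voltages (microvolts).
#' @param n_trials Number of clean trials contributing to the average.
#' @param class,condition,participant Labels for the averaged cell.
#' @return An object of class `erp_waveform`.
#' @export
erp_waveform <- function(channels, times_ms, voltages, n_trials,
                         class = NA_character_, condition = NA_character_,
                         participant = NA_character_) {
  stopifnot(is.matrix(voltages), nrow(voltages) == length(channels),
            ncol(voltages) == length(times_ms), n_trials >= 1)
  structure(
    list(channels = as.character(channels), times_ms = times_ms,
         voltages = voltages, n_trials = n_trials, class = class,
         condition = condition, participant = participant),
    class = "erp_waveform"
  )
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s/%s participant %s: %d channels, %d samples, n_trials = %d\n",
              x$class, x$condition, x$participant,
              length(x$channels), length(x$times_ms), x$n_trials))
  invisible(x)
}
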
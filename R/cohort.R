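#' Write / read a BIDS-events-like TSV
#'
#' Columns: `onset` (seconds, 6 decimals), `sample` (0-based), `trial_type`,
#' `condition`, `response`, `correct` (0/1/NA), `rt_ms`.
#'
#' @param events Events data frame ([empty_events()] layout).
#' @param path Destination TSV path.
#' @return `path` invisibly (writer); events data frame (reader).
#' @export
write_events_tsv <- function(events, path) {
  out <- events
  out$onset <- sprintf("%.6f", out$onset)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                   stringsAsFactors = FALSE)
  ev$onset <- as.numeric(ev$onset)
  ev
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one EDF recording plus one events TSV per (participant,
#' condition), and a manifest table linking each file pair to the
#' ground-truth parameters that generated it. Every stream (sequence,
#' recording noise, artifacts, behavior) is seeded from the cohort master
#' seed via [derive_seed()], so rerunning with the same spec reproduces
#' identical files.
#'
#' @param spec A [cohort_spec()].
#' @param output_dir Writable output directory (created if needed).
#' @param template An [erp_template()]; its condition effects are the
#'   cohort's ground truth.
#' @return The manifest data frame (also written to
#'   `manifest.tsv` in `output_dir`): participant, condition, file paths,
#'   trial count, ground-truth P3 gain and effect.
#' @export
generate_cohort <- function(spec, output_dir,
                            template = default_erp_template(spec$p3b_effect_uV)) {
  if (spec$n_participants < 1) stop("n_participants must be >= 1")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)
  rows <- list()
  for (p in seq_len(spec$n_participants)) {
    gain <- participant_p3_gain(spec, p)
    for (cond in POSTURE_CONDITIONS) {
      seqn <- generate_stimulus_sequence(
        n_trials = spec$n_trials, seed = derive_seed(spec$seed, p, cond, "seq"))
      rec <- generate_recording(seqn, template, cond, spec, participant_id = p,
                                p3_gain = gain)
      beh <- generate_behavior(seqn, cond, spec,
                               seed = derive_seed(spec$seed, p, cond, "beh"))
      rec$events$response <- beh$response
      rec$events$correct <- beh$correct
      rec$events$rt_ms <- beh$rt_ms
      base <- sprintf("sub-%03d_%s", p, cond)
      edf_path <- file.path(output_dir, paste0(base, ".edf"))
      ev_path <- file.path(output_dir, paste0(base, "_events.tsv"))
      ok <- tryCatch({
        write_edf(rec, edf_path)
        write_events_tsv(rec$events, ev_path)
        TRUE
      }, error = function(e) {
        stop("I/O failure writing ", edf_path, ": ", conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, condition = cond,
        edf = basename(edf_path), events = basename(ev_path),
        n_trials = spec$n_trials, p3_gain = gain,
        p3b_effect_uV = spec$p3b_effect_uV,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(output_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Load one cohort recording (EDF plus events)
#'
#' @param edf_path Path to the EDF file.
#' @param events_path Path to the matching events TSV; defaults to the EDF
#'   path with `.edf` replaced by `_events.tsv`.
#' @return An [eeg_recording()] with the events table attached.
#' @export
read_recording <- function(edf_path,
                           events_path = sub("\\.edf$", "_events.tsv", edf_path)) {
  rec <- read_edf(edf_path)
  rec$events <- read_events_tsv(events_path)
  stopifnot(all(rec$events$sample >= 0), all(rec$events$sample < ncol(rec$data)))
  rec
}
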
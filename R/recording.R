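#' Generate 1/f ("pink") noise series
#'
#' Spectrally shaped Gaussian noise: white noise is filtered in the
#' frequency domain with amplitude weights `1/sqrt(max(f, 1 Hz))` (power
#' proportional to 1/f above 1 Hz, flat below, no DC), then rescaled so the
#' theoretical per-sample standard deviation equals `sd`. Used as the
#' background activity of every synthetic channel.
#'
#' @param n Series length in samples.
#' @param m Number of independent series (columns).
#' @param sd Target per-sample standard deviation.
#' @param rate_hz Sampling rate, Hz (sets the frequency axis).
#' @return Numeric matrix `n x m`.
#' @export
pink_noise <- function(n, m = 1, sd = 1, rate_hz = 250) {
  if (sd == 0) return(matrix(0, n, m))
  f <- (seq_len(n) - 1) * rate_hz / n
  f <- pmin(f, rate_hz - f)            # mirror for the upper half-spectrum
  w <- 1 / sqrt(pmax(f, 1))
  w[f == 0] <- 0
  scale <- sd / sqrt(sum(w^2) / n)
  x <- matrix(rnorm(n * m), n, m)
  sh <- mvfft(mvfft(x) * w, inverse = TRUE) / n
  Re(sh) * scale
}

#' Generate a continuous synthetic EEG recording
#'
#' Renders one run: 1/f background noise on the 8-channel montage at 250 Hz,
#' the stimulus-locked ERP template injected at every onset of the stimulus
#' sequence, and -- at the condition's configured artifact rate -- a square
#' 150 uV excursion on one random channel spanning 200-600 ms post-onset,
#' which guarantees that the affected epoch trips the downstream +/- 100 uV
#' rejection gate.
#'
#' @param sequence A [generate_stimulus_sequence()] result.
#' @param template An [erp_template()].
#' @param condition `"standing"` or `"sitting"`.
#' @param spec A [cohort_spec()].
#' @param participant_id Integer participant index (selects the
#'   participant's P3 gain stream).
#' @param seed Integer seed for noise and artifact placement. Defaults to a
#'   child of the cohort seed keyed by participant and condition.
#' @param p3_gain Participant P3 gain; defaults to the participant's
#'   cohort-derived gain (shared across conditions).
#' @return An [eeg_recording()] whose events table is aligned to sample
#'   indices (behavioral columns are filled by [generate_behavior()]).
#' @export
generate_recording <- function(sequence, template, condition, spec,
                               participant_id = 1, seed = NULL, p3_gain = NULL) {
  stopifnot(inherits(sequence, "stim_sequence"), nrow(sequence$trials) > 0,
            condition %in% POSTURE_CONDITIONS)
  if (!all(template$channels %in% POSTURE_CHANNELS)) {
    stop("unknown channel names in template: ",
         paste(setdiff(template$channels, POSTURE_CHANNELS), collapse = ", "))
  }
  noise_sd <- spec$noise_sd_uV[[condition]]
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (is.null(seed)) seed <- derive_seed(spec$seed, participant_id, condition, "rec")
  if (is.null(p3_gain)) p3_gain <- participant_p3_gain(spec, participant_id)

  fs <- spec$rate_hz
  nchan <- length(template$channels)
  n_samp <- ceiling(sequence$run_duration_s * fs)
  trials <- sequence$trials
  tpl_times <- seq(0, 800, by = 1000 / fs)
  tpl <- lapply(STIM_CLASSES, function(cl) {
    if (any(template$components$class == cl)) {
      template_signal(template, cl, condition, tpl_times, p3_gain)
    } else NULL
  })
  names(tpl) <- STIM_CLASSES

  rho <- spec$channel_cor
  with_seed(seed, {
    own <- t(pink_noise(n_samp, nchan, noise_sd, fs))
    shared <- pink_noise(n_samp, 1, noise_sd, fs)[, 1]
    data <- sqrt(rho) * matrix(shared, nchan, n_samp, byrow = TRUE) +
      sqrt(1 - rho) * own
    onset_samples <- round(trials$onset_s * fs)
    art_rate <- participant_artifact_rate(spec, participant_id, condition)
    art_hit <- runif(nrow(trials)) < art_rate
    art_chan <- sample.int(nchan, nrow(trials), replace = TRUE)
    art_sign <- sample(c(-1, 1), nrow(trials), replace = TRUE)
    for (i in seq_len(nrow(trials))) {
      sig <- tpl[[trials$class[i]]]
      idx <- onset_samples[i] + seq_len(ncol(sig)) # 1-based, onset at t = 0
      data[, idx] <- data[, idx] + sig
      if (art_hit[i]) {
        aidx <- onset_samples[i] + seq(0.2 * fs, 0.6 * fs)
        data[art_chan[i], aidx] <- data[art_chan[i], aidx] + art_sign[i] * 150
      }
    }
    events <- data.frame(
      onset = trials$onset_s,
      sample = as.integer(onset_samples),   # 0-based once written to TSV
      trial_type = trials$class,
      condition = condition,
      response = "none", correct = NA_integer_, rt_ms = NA_real_,
      stringsAsFactors = FALSE
    )
    eeg_recording(template$channels, fs, data, events)
  })
}

#' Simulate a baseline-ready epoch set directly
#'
#' Fast path for statistical calibration: draws clean epochs straight on the
#' peristimulus grid (-200 to 796 ms at 250 Hz) as template-plus-pink-noise,
#' without rendering, filtering and cutting a continuous recording. No
#' artifact bursts are added; epochs are returned unrejected and not yet
#' baseline corrected.
#'
#' @param counts Named integer vector of trials per stimulus class.
#' @param template An [erp_template()].
#' @param condition Condition label.
#' @param spec A [cohort_spec()].
#' @param participant_id Participant index (selects the P3 gain).
#' @param seed Seed; defaults to a child of the cohort seed.
#' @param p3_gain Override for the participant P3 gain.
#' @return An [epoch_set()].
#' @export
simulate_epochs <- function(counts = c(frequent = 40, rare = 5, novelty = 5),
                            template = default_erp_template(),
                            condition = "sitting", spec = cohort_spec(),
                            participant_id = 1, seed = NULL, p3_gain = NULL) {
  stopifnot(all(names(counts) %in% STIM_CLASSES), all(counts >= 0))
  if (is.null(seed)) seed <- derive_seed(spec$seed, participant_id, condition, "epochs")
  if (is.null(p3_gain)) p3_gain <- participant_p3_gain(spec, participant_id)
  fs <- spec$rate_hz
  times <- epoch_time_grid(fs)
  nchan <- length(template$channels)
  classes <- rep(names(counts), counts)
  ntr <- length(classes)
  rho <- spec$channel_cor
  with_seed(seed, {
    nt <- length(times)
    own <- pink_noise(nt, ntr * nchan, spec$noise_sd_uV[[condition]], fs)
    shared <- pink_noise(nt, ntr, spec$noise_sd_uV[[condition]], fs)
    noise <- sqrt(1 - rho) * own +
      sqrt(rho) * shared[, rep(seq_len(ntr), each = nchan)]
    data <- aperm(array(noise, c(nt, nchan, ntr)), c(3, 2, 1))
    for (cl in unique(classes)) {
      sig <- template_signal(template, cl, condition, times, p3_gain)
      rows <- which(classes == cl)
      data[rows, , ] <- data[rows, , , drop = FALSE] +
        rep(sig, each = length(rows))
    }
    labels <- data.frame(class = classes, condition = condition,
                         participant = as.character(participant_id),
                         stringsAsFactors = FALSE)
    epoch_set(times, data, labels, template$channels)
  })
}

# canonical peristimulus grid: half-open [-200, 800) ms, t = -200 + k/fs
epoch_time_grid <- function(rate_hz = 250, window_ms = c(-200, 800)) {
  step <- 1000 / rate_hz
  seq(window_ms[1], window_ms[2] - step, by = step)
}
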
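#' Generate behavioral responses for one run
#'
#' Frequent and rare stimuli require a button press (bottom and top button
#' respectively); novel sounds are to be ignored and are marked as requiring
#' no response. Each required response is produced with probability
#' `1 - lapse_rate`; produced responses use the correct button, and their
#' reaction time is drawn from the condition- and class-specific normal
#' distribution truncated below at 150 ms (a physiological floor for simple
#' auditory reactions).
#'
#' @param sequence A [generate_stimulus_sequence()] result.
#' @param condition Condition label.
#' @param spec A [cohort_spec()] (reaction-time and lapse parameters).
#' @param seed Integer seed.
#' @return Data frame, one row per trial: `class`, `response` (`top`,
#'   `bottom`, `none`), `responded`, `correct` (NA for novelty), `rt_ms`
#'   (NA when not responded).
#' @export
generate_behavior <- function(sequence, condition, spec, seed = 1) {
  stopifnot(inherits(sequence, "stim_sequence"), condition %in% POSTURE_CONDITIONS)
  if (any(spec$rt_mean_ms <= 0) || any(spec$rt_sd_ms <= 0)) {
    stop("reaction-time parameters must be positive")
  }
  classes <- sequence$trials$class
  n <- length(classes)
  with_seed(seed, {
    responded <- rep(FALSE, n)
    rt <- rep(NA_real_, n)
    response <- rep("none", n)
    correct <- rep(NA_integer_, n)
    need <- classes %in% c("frequent", "rare")
    responded[need] <- runif(sum(need)) >= spec$lapse_rate
    for (cl in c("frequent", "rare")) {
      key <- paste(cl, condition, sep = "_")
      idx <- which(classes == cl & responded)
      if (length(idx)) {
        r <- rnorm(length(idx), spec$rt_mean_ms[[key]], spec$rt_sd_ms[[key]])
        rt[idx] <- pmax(r, 150)
        response[idx] <- if (cl == "frequent") "bottom" else "top"
      }
    }
    correct[need] <- as.integer(responded[need])
    data.frame(class = classes, response = response, responded = responded,
               correct = correct, rt_ms = rt, stringsAsFactors = FALSE)
  })
}

#' Summarize behavioral performance per condition
#'
#' Counts correct responses for the frequent and rare stimuli and averages
#' reaction times over correct responses, per condition, pooling the given
#' per-run records -- the layout of a standard oddball behavioral table.
#'
#' @param records A list of (or single) data frames as returned by
#'   [generate_behavior()], each with an attached `condition` column or a
#'   `condition` argument per record; alternatively a single data frame with
#'   a `condition` column.
#' @return Data frame: `condition`, `class`, `n_correct`, `n_trials`,
#'   `mean_rt_ms` (NA when no correct responses carry a reaction time).
#' @export
summarize_behavior <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  stopifnot(length(records) > 0)
  all <- do.call(rbind, records)
  if (is.null(all$condition)) stop("records need a 'condition' column")
  cells <- expand.grid(condition = unique(all$condition),
                       class = c("frequent", "rare"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- all[all$condition == cells$condition[i] & all$class == cells$class[i], ]
    ok <- sub$correct %in% 1
    rts <- sub$rt_ms[ok & !is.na(sub$rt_ms)]
    data.frame(condition = cells$condition[i], class = cells$class[i],
               n_correct = sum(ok), n_trials = nrow(sub),
               mean_rt_ms = if (length(rts)) mean(rts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
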
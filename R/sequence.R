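#' Generate an auditory oddball stimulus sequence
#'
#' Builds one run of the auditory novelty oddball task: by default 50 trials
#' of which 40 (80 %) are frequent standards, 5 (10 %) rare targets and
#' 5 (10 %) novel distractors, presented with an inter-stimulus interval of
#' 1900 ms jittered uniformly by +/- 200 ms, and ordered so that every rare
#' or novelty stimulus is immediately preceded by a frequent stimulus.
#'
#' The ordering constraint is satisfied by construction: deviants (rare and
#' novelty trials) are assigned to distinct "slots" following the frequent
#' trials, so no two deviants are ever adjacent and the run starts with a
#' frequent stimulus whenever any deviant is present.
#'
#' @param n_trials Number of trials in the run.
#' @param proportions Named fractions over `frequent`, `rare`, `novelty`;
#'   must sum to 1 and imply integer counts for `n_trials`.
#' @param isi_ms Inter-stimulus interval center, ms.
#' @param jitter_ms Half-range of the uniform ISI jitter, ms.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param lead_in_s Silence before the first onset (leaves room for the
#'   prestimulus baseline), seconds.
#' @return A `stim_sequence`: list with `trials` (data frame `onset_s`,
#'   `class`, `isi_ms`) and `run_duration_s`.
#' @examples
#' seq1 <- generate_stimulus_sequence(seed = 1)
#' table(seq1$trials$class)
#' @export
generate_stimulus_sequence <- function(n_trials = 50,
                                       proportions = c(frequent = 0.8, rare = 0.1, novelty = 0.1),
                                       isi_ms = 1900, jitter_ms = 200,
                                       seed = 1, lead_in_s = 1) {
  stopifnot(n_trials >= 1, jitter_ms >= 0, isi_ms > jitter_ms)
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("stimulus class proportions must sum to 1")
  }
  if (!all(names(proportions) %in% STIM_CLASSES)) {
    stop("unknown stimulus class in proportions: ",
         paste(setdiff(names(proportions), STIM_CLASSES), collapse = ", "))
  }
  counts <- proportions * n_trials
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("proportions do not give integer class counts for n_trials = ", n_trials)
  }
  counts <- round(counts)
  n_f <- if ("frequent" %in% names(counts)) counts[["frequent"]] else 0
  n_d <- sum(counts[setdiff(names(counts), "frequent")])
  if (n_d > n_f) {
    stop("ordering constraint unsatisfiable: ", n_d,
         " deviants but only ", n_f, " frequent trials")
  }

  with_seed(seed, {
    classes <- rep("frequent", n_trials)
    if (n_d > 0) {
      deviants <- rep(setdiff(names(counts), "frequent"),
                      counts[setdiff(names(counts), "frequent")])
      deviants <- sample(deviants)
      # slot i = position right after the i-th frequent trial
      slots <- sort(sample.int(n_f, n_d))
      classes <- character(0)
      d <- 1
      for (i in seq_len(n_f)) {
        classes <- c(classes, "frequent")
        if (d <= n_d && slots[d] == i) {
          classes <- c(classes, deviants[d])
          d <- d + 1
        }
      }
    }
    isi <- isi_ms + runif(n_trials, -jitter_ms, jitter_ms)
    onsets <- lead_in_s + c(0, cumsum(isi[-n_trials])) / 1000
    trials <- data.frame(onset_s = onsets, class = classes, isi_ms = isi,
                         stringsAsFactors = FALSE)
    structure(
      list(trials = trials,
           run_duration_s = lead_in_s + sum(isi) / 1000 + 1),
      class = "stim_sequence"
    )
  })
}

#' @export
print.stim_sequence <- function(x, ...) {
  tab <- table(factor(x$trials$class, levels = STIM_CLASSES))
  cat(sprintf("<stim_sequence> %d trials (%s), %.1f s\n",
              nrow(x$trials),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$run_duration_s))
  invisible(x)
}
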
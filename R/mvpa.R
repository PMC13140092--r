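#' Decoding analysis specification
#'
#' Parameters of the time-resolved standing-vs-sitting decoding: 3-fold
#' cross-validation over averaged pseudo-trials, re-randomized over 100
#' iterations. In `frequent_only` mode a dataset needs at least 36 clean
#' frequent epochs per condition (12 trials per averaged pseudo-trial); in
#' `merged` mode, 45 clean epochs pooled over frequent, rare and novelty
#' stimuli (15 per pseudo-trial). The equalized trial count is fixed at the
#' inclusion threshold for every included participant.
#'
#' @param mode `"frequent_only"` or `"merged"`.
#' @param n_folds Number of cross-validation folds.
#' @param n_iterations Number of re-randomized iterations.
#' @param seed Master seed for the decoding streams.
#' @param cost Soft-margin cost of the linear SVM (fixed unit
#'   regularization by default; features are microvolts on a common scale
#'   and are not standardized).
#' @return An object of class `decoding_spec`.
#' @export
decoding_spec <- function(mode = c("frequent_only", "merged"), n_folds = 3,
                          n_iterations = 100, seed = 1, cost = 1) {
  mode <- match.arg(mode)
  min_trials <- if (mode == "frequent_only") 36L else 45L
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (min_trials %% n_folds != 0) {
    stop("min_trials (", min_trials, ") must be divisible by n_folds (", n_folds, ")")
  }
  structure(
    list(mode = mode, n_folds = as.integer(n_folds),
         n_iterations = as.integer(n_iterations),
         min_trials = min_trials,
         trials_per_average = min_trials %/% n_folds,
         classes = POSTURE_CONDITIONS, seed = as.integer(seed), cost = cost),
    class = "decoding_spec"
  )
}

#' Count clean epochs relevant to a decoding mode
#'
#' @param epochs An [epoch_set()].
#' @param mode Decoding mode (`frequent_only` counts clean frequent epochs,
#'   `merged` counts all clean epochs).
#' @return Integer count.
#' @export
count_clean_epochs <- function(epochs, mode = c("frequent_only", "merged")) {
  mode <- match.arg(mode)
  n_clean_epochs(epochs, class = if (mode == "frequent_only") "frequent" else NULL)
}

#' Select datasets for the decoding analysis
#'
#' A participant enters the analysis iff both conditions reach the clean-
#' epoch threshold of the mode (36 frequent-only, 45 merged).
#'
#' @param counts Data frame with columns `participant`, `condition`,
#'   `n_clean` (clean-epoch counts relevant to the mode).
#' @param spec A [decoding_spec()].
#' @return List: `included` (participant ids), `excluded` (data frame of
#'   excluded participants with their limiting count), `summary` (data
#'   frame: n_total, n_included, pct_included).
#' @export
select_datasets <- function(counts, spec) {
  stopifnot(all(c("participant", "condition", "n_clean") %in% names(counts)))
  ids <- unique(counts$participant)
  minc <- vapply(ids, function(p) {
    sub <- counts[counts$participant == p, ]
    if (!all(POSTURE_CONDITIONS %in% sub$condition)) {
      stop("participant ", p, " lacks counts for both conditions")
    }
    min(sub$n_clean)
  }, numeric(1))
  inc <- minc >= spec$min_trials
  list(
    included = ids[inc],
    excluded = data.frame(participant = ids[!inc], min_clean = minc[!inc],
                          threshold = spec$min_trials, stringsAsFactors = FALSE),
    summary = data.frame(n_total = length(ids), n_included = sum(inc),
                         pct_included = 100 * sum(inc) / length(ids))
  )
}

# clean-epoch indices usable for the mode; flatten trials to (trial x feature)
.decode_trials <- function(epochs, mode) {
  keep <- which(!epochs$rejected &
                  (mode == "merged" | epochs$labels$class == "frequent"))
  d <- dim(epochs$data)
  X <- matrix(epochs$data, d[1], d[2] * d[3])  # column = t * nchan + c (0-based)
  X[keep, , drop = FALSE]
}

#' Build averaged pseudo-trials for one cross-validation split
#'
#' Draws exactly `min_trials` clean epochs per class (condition) without
#' replacement, partitions them into `n_folds` disjoint groups, and
#' averages each group into one pseudo-trial, so both classes contribute
#' one pseudo-trial per fold.
#'
#' @param epochs_standing,epochs_sitting [epoch_set()]s of the two
#'   conditions for one participant.
#' @param spec A [decoding_spec()].
#' @param seed Integer seed for the random assignment.
#' @return List with `pseudo`: array `fold x class x channel x time`
#'   (class order standing, sitting), and `assignment`: the per-class fold
#'   assignment of the drawn trials.
#' @export
make_averaged_erps <- function(epochs_standing, epochs_sitting, spec, seed = 1) {
  Xs <- .decode_trials(epochs_standing, spec$mode)
  Xi <- .decode_trials(epochs_sitting, spec$mode)
  for (nm in c("standing", "sitting")) {
    n <- if (nm == "standing") nrow(Xs) else nrow(Xi)
    if (n < spec$min_trials) {
      stop("insufficient clean trials for ", nm, ": ", n, " < ", spec$min_trials,
           " (participant skipped)")
    }
  }
  nchan <- dim(epochs_standing$data)[2]
  nt <- dim(epochs_standing$data)[3]
  with_seed(seed, {
    grp <- rep(seq_len(spec$n_folds), each = spec$trials_per_average)
    draw_s <- sample.int(nrow(Xs), spec$min_trials)
    draw_i <- sample.int(nrow(Xi), spec$min_trials)
    ps <- rowsum(Xs[draw_s, , drop = FALSE], grp) / spec$trials_per_average
    pi_ <- rowsum(Xi[draw_i, , drop = FALSE], grp) / spec$trials_per_average
    pseudo <- array(0, c(spec$n_folds, 2, nchan, nt))
    pseudo[, 1, , ] <- array(ps, c(spec$n_folds, nchan, nt))
    pseudo[, 2, , ] <- array(pi_, c(spec$n_folds, nchan, nt))
    list(pseudo = pseudo,
         assignment = list(standing = split(draw_s, grp),
                           sitting = split(draw_i, grp)))
  })
}

#' Train and test the per-timepoint classifier
#'
#' Linear soft-margin SVM on the channel voltages at one timepoint; test
#' cases falling exactly on the decision boundary are assigned the
#' first-listed class (standing).
#'
#' @param train_x Numeric matrix, training cases by channels.
#' @param train_y Labels: `"standing"`/`"sitting"` or +1/-1 (+1 =
#'   standing).
#' @param test_x Numeric matrix, test cases by channels.
#' @param cost Soft-margin cost.
#' @return Predicted labels for the test cases, in the label type given.
#' @export
decode_timepoint <- function(train_x, train_y, test_x, cost = 1) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  chr <- is.character(train_y)
  y <- if (chr) ifelse(train_y == "standing", 1L, -1L) else as.integer(train_y)
  if (length(unique(y)) < 2) stop("need at least one training case per class")
  p <- .svm_decode_batch(train_x, y, test_x, ncol(train_x), 1L, cost)[, 1]
  if (chr) ifelse(p > 0, "standing", "sitting") else p
}

#' Run the full time-resolved decoding for one participant
#'
#' For each of `n_iterations` iterations, trial-to-average assignment is
#' re-randomized, and each fold serves as test set exactly once while the
#' classifier is trained on the remaining folds, separately at every
#' timepoint. Accuracy per timepoint is the proportion of correctly
#' classified test cases pooled over iterations, folds and cases; every
#' prediction is stored so that permutation inference can reuse them
#' without retraining.
#'
#' @param epochs_standing,epochs_sitting [epoch_set()]s for one participant.
#' @param spec A [decoding_spec()].
#' @param participant Participant label for the result.
#' @param seed Seed; defaults to a child of `spec$seed` keyed by the
#'   participant label.
#' @return A `decoding_result`: `participant`, `times_ms`, `accuracy`
#'   (per-timepoint, in `[0, 1]`), `pred` (array iteration x fold x case x
#'   time of +/-1), `truth` (case labels +1 standing, -1 sitting), and the
#'   spec dimensions.
#' @export
run_decoding <- function(epochs_standing, epochs_sitting, spec,
                         participant = epochs_standing$labels$participant[1],
                         seed = NULL) {
  stopifnot(inherits(spec, "decoding_spec"))
  if (is.null(seed)) seed <- derive_seed(spec$seed, as.character(participant), "decode")
  nt <- length(epochs_standing$times_ms)
  nchan <- length(epochs_standing$channels)
  k <- spec$n_folds
  pred <- array(NA_integer_, c(spec$n_iterations, k, 2, nt))
  truth <- c(1L, -1L)  # case 1 standing, case 2 sitting in every fold
  for (it in seq_len(spec$n_iterations)) {
    av <- make_averaged_erps(epochs_standing, epochs_sitting, spec,
                             seed = derive_seed(seed, it))
    flat <- matrix(av$pseudo, k * 2, nchan * nt)
    # row index of (fold f, class c) in flat: f + (c - 1) * k
    for (f in seq_len(k)) {
      test_rows <- c(f, f + k)
      train_rows <- setdiff(seq_len(2 * k), test_rows)
      y <- ifelse(train_rows <= k, 1L, -1L)
      p <- .svm_decode_batch(flat[train_rows, , drop = FALSE], y,
                             flat[test_rows, , drop = FALSE],
                             nchan, nt, spec$cost)
      pred[it, f, , ] <- p
    }
  }
  correct <- sweep(pred, 3, truth, `==`)
  accuracy <- apply(correct, 4, mean)
  structure(
    list(participant = as.character(participant),
         times_ms = epochs_standing$times_ms, accuracy = accuracy,
         pred = pred, truth = truth, mode = spec$mode,
         n_iterations = spec$n_iterations, n_folds = k),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> participant %s (%s): %d iterations x %d folds, mean accuracy %.3f\n",
              x$participant, x$mode, x$n_iterations, x$n_folds, mean(x$accuracy)))
  invisible(x)
}

#' Grand-average decoding accuracy
#'
#' Unweighted mean across participants of the per-timepoint accuracies.
#'
#' @param results List of `decoding_result`s.
#' @return Numeric vector, one mean accuracy per timepoint.
#' @export
grand_average_decoding <- function(results) {
  stopifnot(length(results) >= 1)
  rowMeans(vapply(results, `[[`, numeric(length(results[[1]]$accuracy)),
                  "accuracy"))
}

#' Confusion matrix over a time window
#'
#' Pools the stored predicted labels over iterations, folds, cases and all
#' timepoints inside the window, per participant and true class, then
#' averages the per-participant predicted-class proportions across
#' participants. Rows are predicted classes, columns true classes; each
#' column of the mean matrix sums to 1.
#'
#' @param results List of `decoding_result`s.
#' @param window_ms Time window, ms (half-open, like the measurement
#'   windows). Default: the P3 window.
#' @return List of class `confusion_matrix`: `window_ms`, `mean` and `sd`
#'   (2 x 2 matrices, predicted x true), `n_participants`.
#' @export
confusion_matrix <- function(results, window_ms = c(250, 550)) {
  stopifnot(length(results) >= 1)
  sel <- .window_samples(results[[1]]$times_ms, window_ms)
  if (!length(sel)) stop("empty window: no timepoints inside ",
                         window_ms[1], "-", window_ms[2], " ms")
  per <- vapply(results, function(r) {
    p_std_given_std <- mean(r$pred[, , 1, sel] == 1)
    p_std_given_sit <- mean(r$pred[, , 2, sel] == 1)
    c(p_std_given_std, p_std_given_sit)
  }, numeric(2))
  per <- matrix(per, nrow = 2)
  mean_mat <- matrix(c(mean(per[1, ]), 1 - mean(per[1, ]),
                       mean(per[2, ]), 1 - mean(per[2, ])), 2, 2)
  sd_mat <- matrix(c(sd(per[1, ]), sd(per[1, ]),
                     sd(per[2, ]), sd(per[2, ])), 2, 2)
  if (length(results) == 1) sd_mat[] <- 0
  dimnames(mean_mat) <- dimnames(sd_mat) <-
    list(predicted = POSTURE_CONDITIONS, true = POSTURE_CONDITIONS)
  structure(list(window_ms = window_ms, mean = mean_mat, sd = sd_mat,
                 n_participants = length(results)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %g-%g ms, %d participants (mean +/- SD)\n",
              x$window_ms[1], x$window_ms[2], x$n_participants))
  for (i in 1:2) {
    cat(sprintf("  predicted %-8s: %s\n", rownames(x$mean)[i],
                paste(sprintf("%.2f +/- %.2f", x$mean[i, ], x$sd[i, ]),
                      collapse = "   ")))
  }
  invisible(x)
}
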
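#' Single-trial mean amplitudes for one measurement cell
#'
#' Window-mean voltage of every clean epoch of a cell (class/condition) at
#' one channel -- the per-trial scores entering the analytic standardized
#' measurement error.
#'
#' @param epochs An [epoch_set()].
#' @param channel Channel name.
#' @param window_ms Measurement window, ms.
#' @param class,condition Optional cell filters.
#' @return Numeric vector, one mean amplitude (uV) per clean trial.
#' @export
single_trial_amplitudes <- function(epochs, channel, window_ms = c(250, 550),
                                    class = NULL, condition = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) stop("channel not present: ", channel)
  keep <- !epochs$rejected
  if (!is.null(class)) keep <- keep & epochs$labels$class %in% class
  if (!is.null(condition)) keep <- keep & epochs$labels$condition %in% condition
  sel <- .window_samples(epochs$times_ms, window_ms)
  if (!length(sel)) stop("window contains no samples")
  rowMeans(matrix(epochs$data[keep, ch, sel], sum(keep), length(sel)))
}

#' Analytic standardized measurement error (aSME)
#'
#' The standard error of a participant's mean-amplitude score: the sample
#' standard deviation (n-1 denominator) of the per-trial window means,
#' divided by the square root of the number of trials.
#'
#' @param single_trial_amplitudes Numeric vector of per-trial mean
#'   amplitudes (uV), e.g. from [single_trial_amplitudes()].
#' @return aSME in microvolts; `NA_real_` when fewer than 2 trials are
#'   available (the SD is undefined).
#' @examples
#' asme(c(1, 2, 3))  # sd = 1, n = 3 -> 1/sqrt(3)
#' @export
asme <- function(single_trial_amplitudes) {
  x <- single_trial_amplitudes[!is.na(single_trial_amplitudes)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Bootstrapped standardized measurement error (bSME) for latency
#'
#' The fractional-area latency is a nonlinear function of the averaged
#' waveform, so its measurement error is estimated by bootstrap: the cell's
#' clean epochs are resampled with replacement, each resample is averaged
#' into a new ERP waveform, its fractional-area latency is computed, and
#' the bSME is the sample standard deviation of the latencies over
#' `n_bootstrap` replicates (10,000 by default). Replicates whose latency
#' is undefined (no positive area) are dropped and counted, never imputed.
#'
#' Per the analysis design this is typically applied to the merged cell
#' (frequent, rare and novelty epochs of one condition pooled); restrict
#' with `class` for per-class values.
#'
#' @param epochs An [epoch_set()] (one participant, one condition).
#' @param channel Channel name.
#' @param window_ms Measurement window, ms.
#' @param fraction Area fraction (0.5 = 50 %).
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param class,condition Optional cell filters.
#' @return List: `value` (bSME, ms; `NA` if every replicate was
#'   undefined), `n_trials`, `n_bootstrap`, `n_dropped` (undefined
#'   replicates).
#' @export
bsme <- function(epochs, channel, window_ms = c(250, 550), fraction = 0.5,
                 n_bootstrap = 10000, seed = 1, class = NULL, condition = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), n_bootstrap >= 2)
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) stop("channel not present: ", channel)
  keep <- !epochs$rejected
  if (!is.null(class)) keep <- keep & epochs$labels$class %in% class
  if (!is.null(condition)) keep <- keep & epochs$labels$condition %in% condition
  n <- sum(keep)
  if (n < 2) stop("need at least 2 clean epochs, got ", n)
  sel <- .window_samples(epochs$times_ms, window_ms)
  if (length(sel) < 2) stop("degenerate window: need at least 2 samples")
  E <- matrix(epochs$data[keep, ch, sel], n, length(sel))
  with_seed(seed, {
    M <- matrix(0, n_bootstrap, length(sel))
    for (j in seq_len(n)) {
      M <- M + E[sample.int(n, n_bootstrap, replace = TRUE), , drop = FALSE]
    }
    M <- M / n
    lat <- .fal_matrix(M, epochs$times_ms[sel], fraction)
    ok <- !is.na(lat)
    list(value = if (sum(ok) >= 2) sd(lat[ok]) else NA_real_,
         n_trials = n, n_bootstrap = n_bootstrap,
         n_dropped = sum(!ok))
  })
}

#' Compare SME values between conditions
#'
#' Dependent (paired) t-test of per-participant SME values, standing versus
#' sitting.
#'
#' @param standing,sitting Numeric vectors of per-participant SME values.
#' @return As [compare_paired()] with `test = "paired_t"`.
#' @export
compare_sme <- function(standing, sitting) {
  compare_paired(standing, sitting, test = "paired_t")
}
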
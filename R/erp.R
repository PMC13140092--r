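#' Average clean epochs into an ERP waveform
#'
#' Pointwise mean over the clean (unrejected) epochs of one stimulus class
#' and condition. Rejected epochs never contribute.
#'
#' @param epochs An [epoch_set()].
#' @param class Stimulus class to average (`NULL` = all classes pooled).
#' @param condition Condition to average (`NULL` = all).
#' @return An [erp_waveform()], or `NULL` (with a message) when no clean
#'   epoch matches -- never a silent all-zero waveform.
#' @export
average_erp <- function(epochs, class = NULL, condition = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- !epochs$rejected
  if (!is.null(class)) keep <- keep & epochs$labels$class %in% class
  if (!is.null(condition)) keep <- keep & epochs$labels$condition %in% condition
  if (!any(keep)) {
    message("average_erp: no clean epochs for class=", paste(class, collapse = "/"),
            " condition=", paste(condition, collapse = "/"))
    return(NULL)
  }
  idx <- which(keep)
  v <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  erp_waveform(epochs$channels, epochs$times_ms, v, n_trials = length(idx),
               class = if (is.null(class)) "all" else paste(class, collapse = "+"),
               condition = if (is.null(condition)) "all" else condition,
               participant = epochs$labels$participant[idx[1]])
}

#' Rare minus frequent difference wave
#'
#' @param rare,frequent [erp_waveform()]s on identical channel sets and
#'   time grids.
#' @return An [erp_waveform()] of the pointwise difference; `n_trials` is
#'   the smaller of the two inputs' trial counts.
#' @export
difference_wave <- function(rare, frequent) {
  stopifnot(inherits(rare, "erp_waveform"), inherits(frequent, "erp_waveform"))
  if (!identical(rare$channels, frequent$channels) ||
      length(rare$times_ms) != length(frequent$times_ms) ||
      any(abs(rare$times_ms - frequent$times_ms) > 1e-9)) {
    stop("difference_wave: channel sets / time grids do not match")
  }
  erp_waveform(rare$channels, rare$times_ms, rare$voltages - frequent$voltages,
               n_trials = min(rare$n_trials, frequent$n_trials),
               class = paste0(rare$class, "-", frequent$class),
               condition = rare$condition, participant = rare$participant)
}

# in-window sample selector shared by the amplitude/latency measures
.window_samples <- function(times_ms, window_ms) {
  which(times_ms >= window_ms[1] & times_ms < window_ms[2])
}

#' Mean amplitude in a measurement window
#'
#' Arithmetic mean of the samples with `window[1] <= t < window[2]` (the
#' same half-open convention as the epoch grid). The default window is the
#' P3 window, 250-550 ms.
#'
#' @param erp An [erp_waveform()].
#' @param channel Channel name.
#' @param window_ms Measurement window, ms.
#' @return Mean amplitude in microvolts.
#' @export
mean_amplitude <- function(erp, channel, window_ms = c(250, 550)) {
  stopifnot(inherits(erp, "erp_waveform"))
  ch <- match(channel, erp$channels)
  if (is.na(ch)) stop("channel not present: ", channel)
  sel <- .window_samples(erp$times_ms, window_ms)
  if (!length(sel)) stop("window contains no samples")
  mean(erp$voltages[ch, sel])
}

# fractional-area latency on a matrix of waveforms (rows), vectorized.
# Positive-area convention: samples are rectified at zero first, so the
# interpolated waveform is piecewise linear and the cumulative area is
# piecewise quadratic; the crossing is solved exactly per segment.
.fal_matrix <- function(M, times, fraction = 0.5) {
  n <- ncol(M)
  if (n < 2) stop("degenerate window: need at least 2 samples")
  P <- pmax(M, 0)
  dt <- diff(times)
  # trapezoid areas per segment: (p_k + p_{k+1})/2 * dt
  seg <- (P[, -n, drop = FALSE] + P[, -1, drop = FALSE]) / 2 *
    rep(dt, each = nrow(M))
  C <- t(apply(seg, 1, cumsum))
  if (nrow(M) == 1) C <- matrix(C, 1)
  total <- C[, n - 1]
  out <- rep(NA_real_, nrow(M))
  ok <- total > 0
  if (!any(ok)) return(out)
  target <- fraction * total
  C0 <- cbind(0, C)
  for (i in which(ok)) {
    k <- which(C0[i, -1] >= target[i] - 1e-12)[1]   # crossing segment
    a <- P[i, k]; b <- P[i, k + 1]; d <- dt[k]
    r <- target[i] - C0[i, k]
    # area(tau) = a*tau + (b - a) * tau^2 / (2 d)  on tau in [0, d]
    tau <- if (abs(b - a) < 1e-12) {
      if (a > 0) r / a else d / 2
    } else {
      q <- a^2 + 2 * r * (b - a) / d
      (-a + sqrt(max(q, 0))) / ((b - a) / d)
    }
    out[i] <- times[k] + min(max(tau, 0), d)
  }
  out
}

#' Fractional-area latency
#'
#' The latency `t*` at which the cumulative positive area between the
#' window start and `t*` reaches `fraction` of the total positive area in
#' the window (the standard positive-going component latency measure; 50 %
#' by default). Negative samples contribute zero area. The waveform is
#' rectified at the samples and linearly interpolated between them, and the
#' crossing is solved exactly on the resulting piecewise-quadratic
#' cumulative area. When the window contains no positive area the latency
#' is undefined and `NA` is returned.
#'
#' @param erp An [erp_waveform()].
#' @param channel Channel name.
#' @param window_ms Measurement window, ms.
#' @param fraction Area fraction in (0, 1).
#' @return Latency in ms, or `NA_real_` when undefined.
#' @export
fractional_area_latency <- function(erp, channel, window_ms = c(250, 550),
                                    fraction = 0.5) {
  stopifnot(inherits(erp, "erp_waveform"), fraction > 0, fraction < 1)
  ch <- match(channel, erp$channels)
  if (is.na(ch)) stop("channel not present: ", channel)
  sel <- .window_samples(erp$times_ms, window_ms)
  if (length(sel) < 2) stop("degenerate window: need at least 2 samples")
  .fal_matrix(matrix(erp$voltages[ch, sel], 1), erp$times_ms[sel], fraction)[1]
}

#' Paired condition comparison
#'
#' Compares per-participant values between standing and sitting with either
#' the Wilcoxon signed-rank test (exact for n <= 25 without ties/zeros,
#' normal approximation with continuity correction otherwise) or the paired
#' t-test; two-sided p-values. Pairs with a missing value in either
#' condition are dropped listwise (and counted in the result).
#'
#' @param standing,sitting Equal-length numeric vectors, one value per
#'   participant.
#' @param test `"signed_rank"` or `"paired_t"`.
#' @return List: `test`, `statistic`, `p_value`, `n` (complete pairs),
#'   `n_dropped`, `degenerate` (TRUE when all differences are zero for the
#'   signed-rank test, in which case statistic and p are NA).
#' @export
compare_paired <- function(standing, sitting, test = c("signed_rank", "paired_t")) {
  test <- match.arg(test)
  stopifnot(length(standing) == length(sitting))
  ok <- !is.na(standing) & !is.na(sitting)
  n_dropped <- sum(!ok)
  x <- standing[ok]; y <- sitting[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  d <- x - y
  if (test == "paired_t") {
    if (sd(d) == 0) {
      # identical pairings: t = 0, p = 1; constant nonzero shift: t = +/-Inf
      t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(list(test = test, statistic = t0,
                  p_value = if (t0 == 0) 1 else 0,
                  n = n, n_dropped = n_dropped, degenerate = mean(d) == 0))
    }
    ht <- t.test(x, y, paired = TRUE)
    return(list(test = test, statistic = unname(ht$statistic),
                p_value = ht$p.value, n = n, n_dropped = n_dropped,
                degenerate = FALSE))
  }
  if (all(d == 0)) {
    return(list(test = test, statistic = NA_real_, p_value = NA_real_,
                n = n, n_dropped = n_dropped, degenerate = TRUE))
  }
  dz <- d[d != 0]                     # zero differences drop, as usual
  nz <- length(dz)
  r <- rank(abs(dz))                  # average ranks under ties
  v <- sum(r[dz > 0])
  if (nz <= 25) {
    p <- .signed_rank_exact_p(r, v)
  } else {
    mu <- nz * (nz + 1) / 4
    sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 -
      sum(table(r)^3 - table(r)) / 48  # tie correction
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(test = test, statistic = v, p_value = p,
       n = n, n_dropped = n_dropped, degenerate = FALSE)
}

# exact two-sided signed-rank p-value by dynamic programming over the 2^n
# sign assignments; doubled ranks keep tied (half-integer average) ranks on
# an integer lattice
.signed_rank_exact_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- c(1, rep(0, total))       # counts[w + 1] = #assignments with sum w
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  w <- as.integer(round(2 * v))
  p_le <- sum(counts[seq_len(w + 1)])
  p_ge <- sum(counts[(w + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Tidy measures table for one participant cell
#'
#' Convenience wrapper producing one row of the measures table written by
#' the pipeline: mean amplitude and fractional-area latency for a channel
#' and window.
#'
#' @param erp An [erp_waveform()].
#' @param channel Channel name.
#' @param window_ms Measurement window, ms.
#' @param fraction Area fraction for the latency.
#' @return One-row data frame: participant, condition, class, channel,
#'   window, mean_amplitude_uV, fal_ms, n_trials.
#' @export
measure_erp <- function(erp, channel, window_ms = c(250, 550), fraction = 0.5) {
  data.frame(
    participant = erp$participant, condition = erp$condition,
    class = erp$class, channel = channel,
    window_start_ms = window_ms[1], window_end_ms = window_ms[2],
    mean_amplitude_uV = mean_amplitude(erp, channel, window_ms),
    fal_ms = fractional_area_latency(erp, channel, window_ms, fraction),
    n_trials = erp$n_trials, stringsAsFactors = FALSE
  )
}
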
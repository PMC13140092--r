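# centered running-mean operator with clipped windows, as a matrix so the
# same smoothing applies to single series and to stacked permutation rows
.smooth_matrix <- function(n, span = 5) {
  half <- (span - 1) %/% 2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    W[i, j] <- 1 / length(j)
  }
  W
}

#' Running-average smoothing of an accuracy series
#'
#' Centered moving mean over `span` points; near the edges the window is
#' clipped to the available samples, so output length equals input length
#' and a constant (or linear, away from the edges) series is unchanged.
#'
#' @param series Numeric vector (or matrix with series in rows).
#' @param span Window length in points (odd; default 5).
#' @return Smoothed series, same shape as the input.
#' @export
smooth_accuracy <- function(series, span = 5) {
  stopifnot(span >= 1, span %% 2 == 1)
  if (is.matrix(series)) {
    n <- ncol(series)
    if (n < 1) stop("series must have length >= 1")
    return(series %*% t(.smooth_matrix(n, span)))
  }
  n <- length(series)
  if (n < 1) stop("series must have length >= 1")
  as.numeric(.smooth_matrix(n, span) %*% series)
}

# one-sample t across participants per timepoint (columns), one-tailed
# against chance; zero-variance columns get +/-Inf by the sign of the mean
.pointwise_t <- function(accmat, chance, alpha) {
  n <- nrow(accmat)
  m <- colMeans(accmat)
  v <- (colSums(accmat^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  s <- sqrt(v)
  t <- rep(0, length(m))
  zero <- s == 0
  t[!zero] <- (m[!zero] - chance) / (s[!zero] / sqrt(n))
  t[zero & m > chance] <- Inf
  t[zero & m < chance] <- -Inf
  p <- pt(t, df = n - 1, lower.tail = FALSE)
  list(t = t, p = p, mask = p < alpha)
}

#' Pointwise one-tailed tests of accuracy against chance
#'
#' One-sample t-test across participants at every timepoint, alternative
#' "accuracy greater than chance" (below-chance decoding is not
#' meaningful for this classifier, so the test is one-tailed). Timepoints
#' with zero variance across participants get `t = +Inf` (significant) when
#' the mean exceeds chance and `t = -Inf` (not significant) otherwise.
#'
#' @param accmat Numeric matrix, participants x timepoints.
#' @param chance Chance accuracy (0.5 for balanced two-class decoding).
#' @param alpha Pointwise significance level.
#' @return List: `t`, `p` (one-tailed), `mask` (p < alpha).
#' @export
pointwise_tests <- function(accmat, chance = 0.5, alpha = 0.05) {
  stopifnot(is.matrix(accmat), nrow(accmat) >= 3)
  .pointwise_t(accmat, chance, alpha)
}

#' Form clusters of consecutive significant timepoints
#'
#' Maximal runs of consecutive `TRUE` mask points; each cluster's mass is
#' the sum of the pointwise t-values inside the run. Length-1 clusters are
#' allowed -- the permutation correction, not a minimum-length rule,
#' controls the error rate.
#'
#' @param sig_mask Logical vector.
#' @param t_series Numeric vector, same length.
#' @param times_ms Optional time axis for reporting.
#' @return Data frame: `start_idx`, `end_idx`, `start_ms`, `end_ms`,
#'   `t_mass` (zero rows when the mask is empty).
#' @export
form_clusters <- function(sig_mask, t_series, times_ms = NULL) {
  stopifnot(length(sig_mask) == length(t_series))
  if (is.null(times_ms)) times_ms <- seq_along(sig_mask)
  r <- rle(as.logical(sig_mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    start_idx = starts[keep], end_idx = ends[keep],
    start_ms = times_ms[starts[keep]], end_ms = times_ms[ends[keep]],
    t_mass = vapply(keep, function(k) sum(t_series[starts[k]:ends[k]]), numeric(1))
  )
}

#' Null distribution of the maximum cluster t-mass
#'
#' Reuses the stored test-set predictions: for each permutation the true
#' labels are shuffled within every (participant, iteration, fold) block --
#' preserving the class balance of each test fold -- accuracies are
#' recomputed from the stored predictions without any retraining, the
#' 5-point running average is applied exactly as for the observed data,
#' the pointwise tests and clustering are rerun on post-stimulus
#' timepoints, and the mass of the largest cluster is recorded (zero when
#' no cluster forms).
#'
#' Because each fold's two test cases carry one label of each class, the
#' within-block shuffle either keeps or swaps the pair; a swap flips the
#' correctness of both stored predictions, which lets the whole null be
#' computed with per-participant matrix products.
#'
#' @param results List of `decoding_result`s (with stored predictions).
#' @param n_permutations Number of permutations (1000 gives p-resolution
#'   0.001).
#' @param seed Integer seed.
#' @param span Smoothing span in points.
#' @param alpha Pointwise significance level.
#' @param chance Chance accuracy.
#' @return Numeric vector of `n_permutations` max cluster masses.
#' @export
permutation_null <- function(results, n_permutations = 1000, seed = 1,
                             span = 5, alpha = 0.05, chance = 0.5) {
  stopifnot(length(results) >= 3)
  times <- results[[1]]$times_ms
  nt <- length(times)
  W <- t(.smooth_matrix(nt, span))
  npart <- length(results)
  SUM <- matrix(0, n_permutations, nt)
  SSQ <- matrix(0, n_permutations, nt)
  with_seed(seed, {
    for (r in results) {
      if (is.null(r$pred) || anyNA(r$pred)) {
        stop("stored predictions missing for participant ", r$participant)
      }
      correct <- sweep(r$pred, 3, r$truth, `==`)         # it x fold x 2 x nt
      nb <- r$n_iterations * r$n_folds
      B <- matrix(correct[, , 1, ] + correct[, , 2, ], nb, nt)
      S <- matrix(runif(n_permutations * nb) < 0.5, n_permutations, nb)
      acc <- (matrix(colSums(B), n_permutations, nt, byrow = TRUE) +
                2 * rowSums(S) - 2 * (S %*% B)) / (2 * nb)
      acc <- acc %*% W
      SUM <- SUM + acc
      SSQ <- SSQ + acc^2
    }
  })
  sel <- which(times >= 0)
  M <- SUM[, sel, drop = FALSE] / npart
  V <- (SSQ[, sel, drop = FALSE] - npart * M^2) / (npart - 1)
  V[V < 0] <- 0
  sdm <- sqrt(V)
  tmat <- matrix(0, n_permutations, length(sel))
  nz <- sdm > 0
  tmat[nz] <- (M[nz] - chance) / (sdm[nz] / sqrt(npart))
  tmat[!nz & M > chance] <- Inf
  tmat[!nz & M < chance] <- -Inf
  crit <- qt(1 - alpha, df = npart - 1)
  maskmat <- tmat > crit
  vapply(seq_len(n_permutations), function(i) {
    cl <- form_clusters(maskmat[i, ], tmat[i, ])
    if (nrow(cl) == 0) 0 else max(cl$t_mass)
  }, numeric(1))
}

#' Cluster p-values against a permutation null
#'
#' `p = #(null >= observed) / n_permutations`, floored at
#' `1/n_permutations`; when the observed mass exceeds every null mass the
#' p-value is reported as "< 1/n_permutations" (e.g. "<0.001" with 1000
#' permutations). A cluster is significant when its mass lies above the
#' 95th percentile of the null (i.e. the unfloored p is below `alpha`).
#'
#' @param clusters Data frame from [form_clusters()].
#' @param null Numeric vector of null max masses.
#' @param alpha Familywise significance level.
#' @return The `clusters` data frame with `p_value` (floored), `p_label`,
#'   `significant` columns appended.
#' @export
cluster_pvalues <- function(clusters, null, alpha = 0.05) {
  stopifnot(length(null) > 0)
  nperm <- length(null)
  res <- clusters
  cnt <- vapply(clusters$t_mass, function(m) sum(null >= m), numeric(1))
  p_raw <- cnt / nperm
  res$p_value <- pmax(p_raw, 1 / nperm)
  res$p_label <- ifelse(cnt == 0, sprintf("<%g", 1 / nperm),
                        sprintf("%.4g", p_raw))
  res$significant <- p_raw < alpha
  res
}

#' Cluster-mass permutation test of decoding accuracy
#'
#' The full observed-data pipeline: per-participant accuracy series are
#' smoothed with the running average, post-stimulus timepoints are tested
#' one-tailed against chance across participants, consecutive significant
#' timepoints form clusters scored by summed t, and cluster p-values come
#' from the label-permutation null ([permutation_null()]), which applies
#' the identical smoothing/test/clustering pipeline.
#'
#' @param results List of `decoding_result`s.
#' @param n_permutations,alpha,seed,span,chance See [permutation_null()].
#' @return A `cluster_result`: `clusters` (with p-values), `pointwise_t`,
#'   `sig_mask`, `times_ms` (post-stimulus axis), `null`, `alpha`,
#'   `n_permutations`.
#' @export
cluster_test <- function(results, n_permutations = 1000, alpha = 0.05,
                         seed = 1, span = 5, chance = 0.5) {
  stopifnot(length(results) >= 3)
  times <- results[[1]]$times_ms
  accmat <- t(vapply(results, `[[`, numeric(length(times)), "accuracy"))
  accmat <- smooth_accuracy(accmat, span)
  sel <- which(times >= 0)
  pw <- .pointwise_t(accmat[, sel, drop = FALSE], chance, alpha)
  clusters <- form_clusters(pw$mask, pw$t, times[sel])
  null <- permutation_null(results, n_permutations, seed, span, alpha, chance)
  structure(
    list(clusters = cluster_pvalues(clusters, null, alpha),
         pointwise_t = pw$t, sig_mask = pw$mask, times_ms = times[sel],
         null = null, alpha = alpha, n_permutations = n_permutations),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters, %d permutations, alpha = %g\n",
              nrow(x$clusters), x$n_permutations, x$alpha))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
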
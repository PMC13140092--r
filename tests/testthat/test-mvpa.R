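test_that("decoding specs encode the equalization arithmetic", {
  sf <- decoding_spec("frequent_only")
  expect_equal(sf$min_trials, 36L)
  expect_equal(sf$trials_per_average, 12L)
  sm <- decoding_spec("merged")
  expect_equal(sm$min_trials, 45L)
  expect_equal(sm$trials_per_average, 15L)
  expect_error(decoding_spec("frequent_only", n_folds = 5), "divisible")
  expect_error(decoding_spec(n_iterations = 0), "n_iterations")
})

test_that("dataset selection applies the per-condition clean-count threshold", {
  counts <- data.frame(
    participant = rep(1:3, each = 2),
    condition = rep(c("standing", "sitting"), 3),
    n_clean = c(35, 40, 36, 36, 40, 40)
  )
  sel <- select_datasets(counts, decoding_spec("frequent_only"))
  expect_equal(sel$included, c(2, 3))           # 35 standing epochs excludes p1
  expect_equal(sel$excluded$participant, 1)
  expect_equal(sel$summary$pct_included, 100 * 2 / 3)
})

test_that("pseudo-trial assignment partitions the drawn trials disjointly", {
  spec <- cohort_spec()
  tpl <- default_erp_template()
  es <- simulate_epochs(c(frequent = 40), tpl, "standing", spec, 1, seed = 1)
  ei <- simulate_epochs(c(frequent = 40), tpl, "sitting", spec, 1, seed = 2)
  dspec <- decoding_spec("frequent_only")
  av <- make_averaged_erps(es, ei, dspec, seed = 5)
  expect_equal(dim(av$pseudo), c(3, 2, 8, 250))
  for (cls in c("standing", "sitting")) {
    groups <- av$assignment[[cls]]
    expect_equal(lengths(groups), c(`1` = 12L, `2` = 12L, `3` = 12L))
    expect_equal(length(unique(unlist(groups))), 36)  # disjoint and exhaustive
  }
  # each pseudo-trial is the plain mean of its 12 assigned trials
  X <- matrix(es$data, 40, 8 * 250)
  want <- colMeans(X[av$assignment$standing[[2]], ])
  expect_equal(as.numeric(matrix(av$pseudo[2, 1, , ], 1, 8 * 250)), want)

  e_small <- simulate_epochs(c(frequent = 30), tpl, "standing", spec, 1, seed = 3)
  expect_error(make_averaged_erps(e_small, ei, dspec, 1), "insufficient clean trials")
})

test_that("merged mode pools stimulus classes and uses 15 trials per average", {
  spec <- cohort_spec()
  tpl <- default_erp_template()
  es <- simulate_epochs(c(frequent = 40, rare = 5, novelty = 5), tpl,
                        "standing", spec, 1, seed = 1)
  ei <- simulate_epochs(c(frequent = 40, rare = 5, novelty = 5), tpl,
                        "sitting", spec, 1, seed = 2)
  av <- make_averaged_erps(es, ei, decoding_spec("merged"), seed = 4)
  expect_equal(lengths(av$assignment$standing), c(`1` = 15L, `2` = 15L, `3` = 15L))
})

test_that("the timepoint decoder separates classes and resolves ties to standing", {
  tr <- rbind(matrix(5, 2, 8), matrix(-5, 2, 8))
  y <- c("standing", "standing", "sitting", "sitting")
  expect_equal(decode_timepoint(tr, y, rbind(rep(4, 8), rep(-4, 8))),
               c("standing", "sitting"))
  # exactly on the boundary -> first-listed class
  expect_equal(decode_timepoint(tr, y, matrix(0, 1, 8)), "standing")
  expect_error(decode_timepoint(tr[1:2, ], y[1:2], matrix(0, 1, 8)),
               "per class")
})

test_that("the SVM agrees with a nearest-class-mean oracle when separable", {
  set.seed(20)
  agree <- 0; total <- 0
  for (r in 1:100) {
    mu <- rnorm(8, 0, 4)
    tr <- rbind(matrix(rnorm(2 * 8, 0, 0.5), 2, 8) + rep(mu, each = 2),
                matrix(rnorm(2 * 8, 0, 0.5), 2, 8) - rep(mu, each = 2))
    te <- rbind(rnorm(8, 0, 0.5) + mu, rnorm(8, 0, 0.5) - mu)
    got <- decode_timepoint(tr, c(1L, 1L, -1L, -1L), te)
    m1 <- colMeans(tr[1:2, ]); m2 <- colMeans(tr[3:4, ])
    ncm <- apply(te, 1, function(x) {
      if (sum((x - m1)^2) <= sum((x - m2)^2)) 1L else -1L
    })
    agree <- agree + sum(got == ncm); total <- total + 2
  }
  expect_gte(agree / total, 0.95)
})

test_that("the SVM matches an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  agree <- 0; total <- 0
  for (r in 1:100) {
    tr <- matrix(rnorm(4 * 8), 4, 8)
    y <- c(1L, 1L, -1L, -1L)
    te <- matrix(rnorm(3 * 8), 3, 8)
    got <- decode_timepoint(tr, y, te)
    m <- e1071::svm(tr, factor(y, levels = c(1, -1)), kernel = "linear",
                    cost = 1, scale = FALSE)
    ref <- as.integer(as.character(predict(m, te)))
    agree <- agree + sum(got == ref); total <- total + 3
  }
  expect_gte(agree / total, 0.98)
})

test_that("decoding runs are deterministic and internally consistent", {
  spec <- cohort_spec()
  tpl <- default_erp_template()
  es <- baseline_correct(simulate_epochs(c(frequent = 40), tpl, "standing", spec, 1, seed = 1))
  ei <- baseline_correct(simulate_epochs(c(frequent = 40), tpl, "sitting", spec, 1, seed = 2))
  dspec <- decoding_spec("frequent_only", n_iterations = 4, seed = 9)
  r1 <- run_decoding(es, ei, dspec, participant = 1)
  r2 <- run_decoding(es, ei, dspec, participant = 1)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$pred, r2$pred)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
  # accuracy equals the fraction of stored correct predictions, exactly
  correct <- sweep(r1$pred, 3, r1$truth, `==`)
  expect_identical(r1$accuracy, apply(correct, 4, mean))
})

test_that("noise-free recordings with a large effect decode near-perfectly", {
  spec <- cohort_spec(noise_sd_uV = c(standing = 0.2, sitting = 0.2),
                      p3b_effect_uV = -3)
  tpl <- default_erp_template(-3)
  r <- h_decode_participant(1, spec, tpl,
                            decoding_spec("frequent_only", n_iterations = 5, seed = 2))
  w <- r$times_ms >= 350 & r$times_ms < 450
  expect_gt(mean(r$accuracy[w]), 0.99)
  expect_lt(abs(mean(r$accuracy[r$times_ms < 0]) - 0.5), 0.1)
})

test_that("condition effects are detected inside and not before their window", {
  # narrow artificial P3 so the effect is confined to ~350-450 ms
  comp <- data.frame(class = "frequent", component = "P3",
                     peak_ms = 400, width_ms = 60, stringsAsFactors = FALSE)
  comp[CHANNELS] <- as.list(c(1, 1, 2, 3, 4, 1, 0.5, 0.5))
  tpl <- erp_template(comp, CHANNELS,
                      data.frame(component = "P3", channel = "Pz",
                                 condition = "standing", offset_uV = -8,
                                 stringsAsFactors = FALSE))
  spec <- cohort_spec(noise_sd_uV = c(standing = 1.5, sitting = 1.5))
  res <- lapply(1:6, h_decode_participant, spec = spec, tpl = tpl,
                dspec = decoding_spec("frequent_only", n_iterations = 5, seed = 3),
                seed_base = 31)
  ga <- grand_average_decoding(res)
  times <- res[[1]]$times_ms
  expect_gt(mean(ga[times >= 380 & times <= 420]), 0.9)
  expect_lt(abs(mean(ga[times >= 0 & times <= 200]) - 0.5), 0.06)
})

test_that("grand averaging is the unweighted participant mean", {
  r1 <- list(accuracy = rep(0.4, 10)); r2 <- list(accuracy = rep(0.6, 10))
  expect_equal(grand_average_decoding(list(r1)), rep(0.4, 10))
  expect_equal(grand_average_decoding(list(r1, r2)), rep(0.5, 10))
})

test_that("confusion matrices are column-normalized and diagonal when perfect", {
  res <- h_separable_results(n_participants = 4, n_iterations = 2)
  cm <- confusion_matrix(res, c(250, 550))
  expect_equal(colSums(cm$mean), c(standing = 1, sitting = 1))
  w <- res[[1]]$times_ms >= 350 & res[[1]]$times_ms < 450
  cm_peak <- confusion_matrix(res, c(350, 450))
  expect_gt(cm_peak$mean[1, 1], 0.95)
  expect_gt(cm_peak$mean[2, 2], 0.95)
  expect_error(confusion_matrix(res, c(900, 950)), "empty window")
})
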
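test_that("averaging uses clean epochs only and records trial counts", {
  ep <- h_const_epochs(c(1, 3))
  erp <- average_erp(ep)
  expect_true(all(erp$voltages == 2))
  expect_equal(erp$n_trials, 2)

  ep3 <- h_const_epochs(c(1, 3, 100))
  ep3$rejected[3] <- TRUE
  erp3 <- average_erp(ep3)
  expect_equal(erp3$n_trials, 2)
  expect_true(all(erp3$voltages == 2))

  ep_all_rej <- h_const_epochs(c(1, 2))
  ep_all_rej$rejected[] <- TRUE
  expect_message(res <- average_erp(ep_all_rej), "no clean epochs")
  expect_null(res)
})

test_that("difference waves are pointwise and linear", {
  times <- seq(-200, 796, 4)
  a <- h_erp(sin(times / 50), times)
  b <- h_erp(sin(times / 50), times)
  expect_true(all(difference_wave(a, b)$voltages == 0))

  b2 <- b; b2$voltages <- b$voltages + 2
  expect_true(all(abs(difference_wave(b2, b)$voltages - 2) < 1e-12))

  a3 <- a; a3$voltages <- 3 * a$voltages
  b3 <- b; b3$voltages <- 3 * b$voltages
  expect_equal(difference_wave(a3, b3)$voltages,
               3 * difference_wave(a, b)$voltages)

  short <- h_erp(1:10, seq(0, 36, 4))
  expect_error(difference_wave(a, short), "match")
})

test_that("mean amplitude follows the half-open window convention", {
  times <- seq(-200, 796, 4)
  expect_equal(mean_amplitude(h_erp(rep(1, 250), times), "Pz"), 1)

  # ramp defined on a grid containing 250 ms: 0 uV at 250 up to 4 uV at 546
  times2 <- seq(-150, by = 4, length.out = 250)
  stopifnot(250 %in% times2)
  v <- rep(0, 250)
  win <- times2 >= 250 & times2 < 550
  expect_equal(sum(win), 75)
  v[win] <- seq(0, 4, length.out = 75)
  expect_equal(mean_amplitude(h_erp(v, times2), "Pz"), 2)

  erp <- h_erp(rnorm(250), times)
  erp2 <- erp; erp2$voltages <- 2 * erp$voltages
  expect_equal(mean_amplitude(erp2, "Pz"), 2 * mean_amplitude(erp, "Pz"))
  expect_error(mean_amplitude(erp, "XX"), "channel")
})

test_that("fractional-area latency matches symmetry and midpoint cases", {
  times <- seq(-200, 796, 4)
  tri <- pmax(0, 1 - abs(times - 400) / 100)     # symmetric triangle at 400
  expect_equal(fractional_area_latency(h_erp(tri, times), "Pz"), 400,
               tolerance = 1e-6)

  const <- rep(2, 250)
  fal <- fractional_area_latency(h_erp(const, times), "Pz")
  win <- times[times >= 250 & times < 550]
  expect_equal(fal, (min(win) + max(win)) / 2, tolerance = 1e-6)

  neg <- rep(-1, 250)
  expect_true(is.na(fractional_area_latency(h_erp(neg, times), "Pz")))
})

test_that("fractional-area latency matches a fine-grid brute-force oracle", {
  # oracle: rectify at samples, interpolate on a 0.001 ms grid, accumulate
  oracle_fal <- function(v, times, window = c(250, 550), fraction = 0.5) {
    sel <- times >= window[1] & times < window[2]
    tt <- times[sel]; vv <- pmax(v[sel], 0)
    grid <- seq(min(tt), max(tt), by = 0.001)
    fine <- approx(tt, vv, xout = grid)$y
    area <- cumsum((fine[-1] + fine[-length(fine)]) / 2) * 0.001
    if (max(area) <= 0) return(NA_real_)
    grid[which(area >= fraction * max(area))[1] + 1]
  }
  times <- seq(-200, 796, 4)
  set.seed(11)
  for (i in 1:100) {
    v <- as.numeric(arima.sim(list(ar = 0.9), 250)) + runif(1, -1, 2)
    got <- fractional_area_latency(h_erp(v, times), "Pz")
    want <- oracle_fal(v, times)
    if (is.na(want)) expect_true(is.na(got)) else expect_lt(abs(got - want), 0.1)
  }
})

test_that("fractional-area latency is invariant to positive scaling", {
  times <- seq(-200, 796, 4)
  set.seed(3)
  v <- abs(rnorm(250))
  f1 <- fractional_area_latency(h_erp(v, times), "Pz")
  f2 <- fractional_area_latency(h_erp(5 * v, times), "Pz")
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("mean amplitude commutes with the difference wave", {
  times <- seq(-200, 796, 4)
  set.seed(4)
  r <- h_erp(rnorm(250), times)
  f <- h_erp(rnorm(250), times)
  expect_equal(mean_amplitude(difference_wave(r, f), "Pz"),
               mean_amplitude(r, "Pz") - mean_amplitude(f, "Pz"),
               tolerance = 1e-12)
})

test_that("paired comparisons match closed-form and enumerated references", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3)
  t_same <- compare_paired(x, x, "paired_t")
  expect_equal(t_same$statistic, 0)
  expect_equal(t_same$p_value, 1)

  # all differences +1, n = 6: exact signed-rank p = 2 * (1 / 2^6) = 0.03125
  sr <- compare_paired(x + 1, x, "signed_rank")
  expect_equal(sr$p_value, 0.03125)

  deg <- compare_paired(x, x, "signed_rank")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))

  # missing pairs dropped listwise and counted
  xm <- c(x, NA); ym <- c(x + 1, 5)
  cp <- compare_paired(ym, xm, "signed_rank")
  expect_equal(cp$n, 6)
  expect_equal(cp$n_dropped, 1)
  expect_error(compare_paired(1:2, 2:3), "at least 3")
})

test_that("exact signed-rank p-values match the reference distribution", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- compare_paired(a, b, "signed_rank")
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("recovered P3b condition difference matches the template ground truth", {
  eff <- -1.5
  spec <- cohort_spec(p3b_effect_uV = eff)
  tpl <- default_erp_template(eff)
  times <- seq(-200, 796, 4)
  win <- times >= 250 & times < 550
  truth <- mean(template_signal(tpl, "frequent", "standing", times)[5, win]) -
    mean(template_signal(tpl, "frequent", "sitting", times)[5, win])
  n <- 25
  d <- vapply(seq_len(n), function(p) {
    es <- baseline_correct(simulate_epochs(c(frequent = 40), tpl, "standing",
                                           spec, p, seed = derive_seed(21, p, 1)))
    ei <- baseline_correct(simulate_epochs(c(frequent = 40), tpl, "sitting",
                                           spec, p, seed = derive_seed(21, p, 2)))
    mean_amplitude(average_erp(es, "frequent"), "Pz") -
      mean_amplitude(average_erp(ei, "frequent"), "Pz")
  }, numeric(1))
  expect_lt(abs(mean(d) - truth), 2 * sd(d) / sqrt(n))
})

test_that("behavior summaries count correct responses and average RTs", {
  rec <- data.frame(
    class = c(rep("frequent", 40), rep("rare", 5), rep("novelty", 5)),
    response = c(rep("bottom", 40), rep("top", 5), rep("none", 5)),
    responded = c(rep(TRUE, 45), rep(FALSE, 5)),
    correct = c(rep(1L, 45), rep(NA, 5)),
    rt_ms = c(rep(400, 45), rep(NA, 5)),
    condition = "sitting", stringsAsFactors = FALSE
  )
  s <- summarize_behavior(rec)
  expect_equal(s$n_correct[s$class == "frequent"], 40)
  expect_equal(s$n_correct[s$class == "rare"], 5)
  expect_equal(s$mean_rt_ms, c(400, 400))

  none <- rec
  none$responded <- FALSE; none$correct[1:45] <- 0L; none$rt_ms <- NA_real_
  s0 <- summarize_behavior(none)
  expect_equal(s0$n_correct, c(0, 0))
  expect_true(all(is.na(s0$mean_rt_ms)))
})
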
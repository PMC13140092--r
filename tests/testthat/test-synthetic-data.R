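test_that("default 50-trial sequence has exact class counts and valid ISIs", {
  s <- generate_stimulus_sequence(seed = 1)
  tab <- table(s$trials$class)
  expect_equal(unname(tab[["frequent"]]), 40)
  expect_equal(unname(tab[["rare"]]), 5)
  expect_equal(unname(tab[["novelty"]]), 5)
  expect_true(all(s$trials$isi_ms >= 1700 & s$trials$isi_ms <= 2100))
  expect_true(all(diff(s$trials$onset_s) > 0))
})

test_that("every rare/novelty trial follows a frequent trial, across many seeds", {
  for (seed in 1:1000) {
    cl <- generate_stimulus_sequence(seed = seed)$trials$class
    dev <- which(cl != "frequent")
    expect_true(all(dev > 1))
    expect_true(all(cl[dev - 1] == "frequent"))
  }
})

test_that("degenerate jitter gives exactly constant ISIs", {
  s <- generate_stimulus_sequence(10, c(frequent = 1), jitter_ms = 0, seed = 0)
  expect_equal(nrow(s$trials), 10)
  expect_true(all(s$trials$class == "frequent"))
  expect_equal(s$trials$isi_ms, rep(1900, 10))
})

test_that("run duration is close to n_trials * nominal ISI", {
  s <- generate_stimulus_sequence(seed = 2)
  expect_gt(s$run_duration_s, 0.95 * 50 * 1.9)
  expect_lt(s$run_duration_s, 1.05 * 50 * 1.9)
  # sum of sampled ISIs accounts for the duration up to lead-in and tail
  expect_equal(s$run_duration_s, 1 + sum(s$trials$isi_ms) / 1000 + 1)
})

test_that("invalid sequence requests are rejected", {
  expect_error(generate_stimulus_sequence(50, c(frequent = 0.85, rare = 0.15)),
               "integer class counts")
  expect_error(generate_stimulus_sequence(10, c(frequent = 0.2, rare = 0.4, novelty = 0.4)),
               "unsatisfiable")
  expect_error(generate_stimulus_sequence(50, c(frequent = 0.5, rare = 0.5), seed = 1),
               NA)
  expect_error(generate_stimulus_sequence(50, c(frequent = 0.6, rare = 0.2)),
               "sum to 1")
})

test_that("sequence generation is deterministic in the seed", {
  expect_identical(generate_stimulus_sequence(seed = 7),
                   generate_stimulus_sequence(seed = 7))
  s1 <- generate_stimulus_sequence(seed = 7)
  s2 <- generate_stimulus_sequence(seed = 8)
  expect_false(identical(s1$trials$isi_ms, s2$trials$isi_ms))
})

test_that("noise-free recording reproduces the template exactly at onsets", {
  spec <- cohort_spec(noise_sd_uV = c(standing = 0, sitting = 0),
                      artifact_rate = c(standing = 0, sitting = 0))
  tpl <- default_erp_template()
  s <- generate_stimulus_sequence(5, c(frequent = 0.6, rare = 0.2, novelty = 0.2),
                                  seed = 4)
  rec <- generate_recording(s, tpl, "sitting", spec, 1, p3_gain = 1)
  for (i in seq_len(nrow(s$trials))) {
    on <- round(s$trials$onset_s[i] * 250)
    seg <- rec$data[, on + 1:201]
    ref <- template_signal(tpl, s$trials$class[i], "sitting", seq(0, 800, 4), 1)
    expect_equal(max(abs(seg - ref)), 0)
  }
  # P3 peak voltage at Pz equals the template amplitude for a frequent trial
  on <- round(s$trials$onset_s[1] * 250)
  pz <- match("Pz", rec$channels)
  ref_peak <- template_signal(tpl, s$trials$class[1], "sitting", 400, 1)[pz, 1]
  expect_equal(rec$data[pz, on + 100 + 1], unname(ref_peak))
})

test_that("recordings are bit-identical under the same seed", {
  spec <- cohort_spec()
  tpl <- default_erp_template()
  s <- generate_stimulus_sequence(seed = 5)
  r1 <- generate_recording(s, tpl, "standing", spec, 3, seed = 11)
  r2 <- generate_recording(s, tpl, "standing", spec, 3, seed = 11)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
})

test_that("background noise has a 1/f-like spectrum", {
  set.seed(42)
  x <- pink_noise(5000, 8, sd = 6, rate_hz = 250)
  f <- (seq_len(5000) - 1) * 250 / 5000
  pw <- rowMeans(abs(mvfft(x))^2)
  low <- mean(pw[f >= 1 & f <= 4])
  high <- mean(pw[f >= 20 & f <= 30])
  expect_gt(low, high)
  expect_equal(apply(x, 2, sd), rep(6, 8), tolerance = 0.25)
})

test_that("simulated epochs carry the condition effect at Pz", {
  spec <- cohort_spec(p3b_effect_uV = -2)
  tpl <- default_erp_template(-2)
  ds <- template_signal(tpl, "frequent", "standing", 400, 1) -
    template_signal(tpl, "frequent", "sitting", 400, 1)
  expect_equal(unname(ds[match("Pz", CHANNELS), 1]), -2)
  es <- simulate_epochs(c(frequent = 200), tpl, "standing", spec, 1, seed = 1,
                        p3_gain = 1)
  ei <- simulate_epochs(c(frequent = 200), tpl, "sitting", spec, 1, seed = 2,
                        p3_gain = 1)
  ti <- which(es$times_ms == 400)
  pz <- match("Pz", es$channels)
  d <- mean(es$data[, pz, ti]) - mean(ei$data[, pz, ti])
  se <- sqrt(var(es$data[, pz, ti]) / 200 + var(ei$data[, pz, ti]) / 200)
  expect_lt(abs(d - (-2)), 3 * se)
})

test_that("participant artifact rates average to the cohort rate and match inclusion", {
  spec <- cohort_spec(seed = 2)
  rates <- t(vapply(1:3000, function(p) {
    c(postureP3:::participant_artifact_rate(spec, p, "standing"),
      postureP3:::participant_artifact_rate(spec, p, "sitting"))
  }, numeric(2)))
  expect_equal(mean(rates[, 1]), 919 / 6300, tolerance = 0.02)
  expect_equal(mean(rates[, 2]), 215 / 6300, tolerance = 0.1)
  # noisy participants are noisy in both conditions (monotone coupling)
  expect_equal(cor(rates[, 1], rates[, 2], method = "spearman"), 1)
  # implied inclusion fraction for the frequent-trial decoding analysis
  pass <- pbinom(4, 40, rates[, 1]) * pbinom(4, 40, rates[, 2])
  expect_equal(mean(pass), 0.7063, tolerance = 0.05)
  # degenerate settings collapse to the uniform rate
  u <- cohort_spec(artifact_concentration = Inf)
  expect_equal(postureP3:::participant_artifact_rate(u, 1, "standing"),
               919 / 6300)
})

test_that("behavioral generator respects lapse-rate extremes and RT anchors", {
  spec0 <- cohort_spec(lapse_rate = 0)
  s <- generate_stimulus_sequence(seed = 1)
  b0 <- generate_behavior(s, "sitting", spec0, seed = 1)
  need <- b0$class %in% c("frequent", "rare")
  expect_true(all(b0$responded[need]))
  expect_true(all(is.na(b0$rt_ms[!need])))
  expect_true(all(b0$rt_ms[need] > 0))

  spec1 <- cohort_spec(lapse_rate = 1)
  b1 <- generate_behavior(s, "sitting", spec1, seed = 1)
  expect_equal(sum(b1$correct %in% 1), 0)

  # frequent sitting RTs anchored at 448 +/- 159 ms
  sl <- generate_stimulus_sequence(1000, c(frequent = 1), seed = 3)
  bl <- generate_behavior(sl, "sitting", spec0, seed = 4)
  expect_lt(abs(mean(bl$rt_ms) - 448), 3 * 159 / sqrt(1000))
})

test_that("EDF files round-trip through the writer/reader", {
  spec <- cohort_spec()
  s <- generate_stimulus_sequence(seed = 9)
  rec <- generate_recording(s, default_erp_template(), "standing", spec, 1)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$rate_hz, 250)
  n <- ncol(rec$data)
  # 16-bit quantization over +/-400 uV: resolution ~0.0122 uV
  expect_lt(max(abs(back$data[, 1:n] - rec$data)), 0.0123)
})

test_that("cohort generation writes a deterministic manifest and valid files", {
  spec <- cohort_spec(n_participants = 2, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  expect_equal(nrow(m1), 4)  # 2 participants x 2 conditions
  expect_identical(m1[setdiff(names(m1), c("edf", "events"))],
                   m2[setdiff(names(m2), c("edf", "events"))])
  expect_identical(unname(tools::md5sum(file.path(d1, m1$edf))),
                   unname(tools::md5sum(file.path(d2, m2$edf))))
  rec <- read_recording(file.path(d1, m1$edf[1]))
  expect_equal(nrow(rec$events), 50)
  expect_true(all(rec$events$trial_type %in% c("frequent", "rare", "novelty")))
  expect_error(generate_cohort(cohort_spec(n_participants = 0), d1),
               "n_participants")
})
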
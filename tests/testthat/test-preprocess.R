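test_that("centile rejection keeps the interquartile band of sweep amplitudes", {
  # 4 identical sweeps: all percentiles coincide, everything kept
  m <- matrix(rep(c(0, 5, -3, 1), each = 4), nrow = 4)
  expect_equal(nrow(centile_rejection(m)), 4)

  # peak-to-peak {1,2,3,100}: only the 100 sweep falls outside the band
  sw <- rbind(c(0, 1, 0), c(0, 2, 0), c(0, 3, 0), c(0, 100, 0))
  kept <- centile_rejection(sw)
  expect_equal(attr(kept, "kept"), 1:3)

  expect_error(centile_rejection(sw[1:3, ]), "at least 4")
})

test_that("trace averaging is the pointwise mean and records kept counts", {
  expect_equal(as.numeric(average_traces(rbind(c(0, 2), c(2, 0)))), c(1, 1))
  one <- matrix(c(3, 1, 4), nrow = 1)
  expect_equal(as.numeric(average_traces(one)), c(3, 1, 4))

  # 60 noisy sweeps: residual noise shrinks like 1/sqrt(n)
  set.seed(101)
  truth <- erg_model_mean(erg_model_params(noise_sd = 0),
                          seq(-20, 104, by = 0.5))
  sweeps <- t(replicate(60, truth + rnorm(length(truth), 0, 4)))
  avg <- average_traces(sweeps)
  expect_equal(sd(avg - truth), 4 / sqrt(60), tolerance = 0.2)
  expect_equal(attr(avg, "n_kept"), 60)

  # recording interface propagates rejection metadata
  tmpl <- flat_recording()
  truth256 <- erg_model_mean(erg_model_params(noise_sd = 0), tmpl$time_ms)
  recs <- lapply(1:6, function(i) {
    r <- tmpl
    r$amplitude_uv <- truth256 + i  # constant offsets, equal ptp
    r
  })
  out <- average_traces(recs, rejection = TRUE)
  expect_s3_class(out, "erg_recording")
  expect_equal(out$metadata$n_total, 6)
})

test_that("QC rules match the inclusion criteria with inclusive electrode boundary", {
  r <- flat_recording()
  expect_false(qc_filter(r, a_amp = 0.5)$passed)
  expect_match(qc_filter(r, a_amp = 0.5)$reasons, "a_wave_too_small")
  expect_false(qc_filter(r, a_amp = 1)$passed)       # strict > 1 uV
  expect_true(qc_filter(r, a_amp = 5, electrode_height_mm = -2)$passed)
  rep3 <- qc_filter(r, a_amp = 5, electrode_height_mm = -3)
  expect_false(rep3$passed)
  expect_match(rep3$reasons, "electrode_too_low")
  expect_true(qc_filter(r, a_amp = 5, electrode_height_mm = NA)$passed)
  # pure predicate: same answer regardless of other recordings
  expect_identical(qc_filter(r, a_amp = 5)$passed,
                   qc_filter(flat_recording(3, id = "px"), a_amp = 5)$passed)
})

test_that("epoch resampling interpolates linearly and never extrapolates", {
  r <- flat_recording()
  out <- resample_epoch(r)
  expect_identical(out$amplitude_uv, r$amplitude_uv)
  expect_true(out$metadata$analysis_ready)

  r2 <- erg_recording("p", "control", "right", 1, time_ms = c(0, 1),
                      amplitude_uv = c(0, 10))
  out2 <- resample_epoch(r2, target_rate_hz = 2000,
                         epoch = list(start_ms = 0, n_samples = 2))
  expect_equal(out2$amplitude_uv, c(0, 5))

  expect_error(resample_epoch(r2, target_rate_hz = 1000,
                              epoch = list(start_ms = 0, n_samples = 10)),
               "range error")
})

test_that("resampling preserves band-limited peaks within 1%", {
  p <- erg_model_params(noise_sd = 0)
  fine <- synth_erg(p, epoch_grid(sampling_rate_hz = 8192, n_samples = 1024))
  coarse <- resample_epoch(fine)
  expect_equal(max(coarse$amplitude_uv), max(fine$amplitude_uv),
               tolerance = 0.01)
  expect_equal(min(coarse$amplitude_uv), min(fine$amplitude_uv),
               tolerance = 0.01)
})
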
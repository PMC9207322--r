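test_that("noiseless two-kernel waveform matches its designed trough and peak", {
  # narrow kernels so a-trough/b-peak overlap is < 2%
  p <- erg_model_params(a_amp = 10, a_time = 15, a_width = 3,
                        b_amp = 20, b_time = 30, b_width = 4,
                        op_amp = 0, noise_sd = 0)
  r <- synth_erg(p)
  expect_equal(min(r$amplitude_uv), -10, tolerance = 0.02)
  expect_equal(max(r$amplitude_uv), 20, tolerance = 0.02)
  expect_equal(r$time_ms[which.min(r$amplitude_uv)], 15, tolerance = 0.5)
  expect_equal(r$time_ms[which.max(r$amplitude_uv)], 30, tolerance = 0.5)
  # pre-stimulus samples are at baseline
  expect_lt(max(abs(r$amplitude_uv[r$time_ms < 0])), 0.05)
})

test_that("zero amplitudes give an identically zero trace and seeds are reproducible", {
  p0 <- erg_model_params(a_amp = 0, b_amp = 0, op_amp = 0, noise_sd = 0)
  expect_true(all(synth_erg(p0)$amplitude_uv == 0))

  p <- erg_model_params()
  expect_identical(synth_erg(p, seed = 42)$amplitude_uv,
                   synth_erg(p, seed = 42)$amplitude_uv)
  expect_false(identical(synth_erg(p, seed = 42)$amplitude_uv,
                         synth_erg(p, seed = 43)$amplitude_uv))
  # too-short epoch is rejected
  expect_error(synth_erg(p, epoch_grid(start_ms = 0, n_samples = 64)),
               "epoch")
})

test_that("cohort generation books one recording per participant x flash x eye", {
  spec <- cohort_spec(group_sizes = c(ASD = 3, control = 4, ADHD = 2),
                      seed = 9)
  st <- generate_cohort(spec)
  expect_equal(length(st), 9 * 5 * 2)
  groups <- vapply(st$recordings, function(r) r$group, character(1))
  expect_equal(sum(groups == "control"), 4 * 5 * 2)

  st2 <- generate_cohort(spec)
  expect_identical(
    lapply(st$recordings, `[[`, "amplitude_uv"),
    lapply(st2$recordings, `[[`, "amplitude_uv"))
})

test_that("group presets are pure data with the documented directions", {
  pr <- group_presets()
  expect_identical(pr$control, list(b_scale = 1, op_scale = 1, a_scale = 1))
  expect_gt(pr$ADHD$op_scale, 1)
  expect_lt(pr$ASD$op_scale, 1)
  expect_gt(pr$ADHD$b_scale, 1)
  expect_identical(group_presets(), pr)
})

noiseless_descriptors <- function(op_scale = 1, amp_scale = 1,
                                  mode = "rss") {
  base <- erg_model_params(noise_sd = 0)
  p <- erg_model_params(
    a_amp = base$a_amp * amp_scale,
    b_amp = base$b_amp * amp_scale,
    op_amp = base$op_amp * op_scale * amp_scale,
    noise_sd = 0)
  r <- synth_erg(p)
  extract_descriptors(build_scalogram(haar_dwt(r)), mode = mode)
}

test_that("OP-band energy increases strictly with op_scale on noiseless traces", {
  for (mode in c("rss", "max_abs", "sum_abs")) {
    ops <- vapply(c(0.5, 0.8, 1, 1.4, 2), function(s) {
      d <- noiseless_descriptors(op_scale = s, mode = mode)
      d$op80 + d$op160
    }, numeric(1))
    expect_true(all(diff(ops) > 0), info = mode)
  }
})

test_that("global amplitude scaling scales every descriptor linearly", {
  for (mode in c("rss", "max_abs", "sum_abs")) {
    d1 <- noiseless_descriptors(mode = mode)
    d2 <- noiseless_descriptors(amp_scale = 2.5, mode = mode)
    for (v in c("a20", "a40", "b20", "b40", "op80", "op160"))
      expect_equal(d2[[v]], 2.5 * d1[[v]], tolerance = 1e-12)
    expect_equal(d2$pct_ops, d1$pct_ops, tolerance = 1e-12)
  }
})
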
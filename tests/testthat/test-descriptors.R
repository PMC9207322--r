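# Build a length-256 pyramid holding a single unit coefficient at the
# given level/position (everything else zero).
unit_pyramid <- function(level, k) {
  details <- lapply(1:8, function(j) numeric(256 / 2^j))
  details[[level]][k] <- 1
  structure(list(details = details, approx = 0, n = 256,
                 sampling_rate_hz = 2048, epoch_start_ms = -20),
            class = "haar_pyramid")
}

test_that("zero signal yields zero descriptors and undefined %OPs", {
  d <- extract_descriptors(build_scalogram(haar_dwt(rep(0, 256))))
  for (v in c("a20", "a40", "b20", "b40", "op80", "op160"))
    expect_equal(d[[v]], 0)
  expect_true(is.na(d$pct_ops))
})

test_that("a unit coefficient synthesized into each band/window hits exactly its descriptor", {
  # one representative (level, k) per descriptor, chosen so the segment
  # midpoint falls inside the target window
  cases <- list(
    a20 = list(level = 6, k = 1),    # midpoint  -4.375 in [-20, 17.5]
    a40 = list(level = 5, k = 2),    # midpoint   3.4375 in [0, 17.5]
    b20 = list(level = 6, k = 2),    # midpoint  26.875 in [17.5, 55]
    b40 = list(level = 5, k = 4),    # midpoint  34.6875 in [17.5, 55]
    op80 = list(level = 4, k = 7),   # midpoint  30.78125 in [8.125, 55]
    op160 = list(level = 3, k = 14)  # midpoint  32.734375 in [8.125, 55]
  )
  for (target in names(cases)) {
    x <- inverse_haar_dwt(unit_pyramid(cases[[target]]$level,
                                       cases[[target]]$k))
    for (mode in c("max_abs", "rss")) {
      d <- extract_descriptors(build_scalogram(haar_dwt(x)), mode = mode)
      for (v in c("a20", "a40", "b20", "b40", "op80", "op160")) {
        expected <- if (v == target) 1 else 0
        # a20/b20 and op windows overlap their band partners only when the
        # same coefficient lies in both windows; these picks do not
        expect_equal(d[[v]], expected, tolerance = 1e-9,
                     info = sprintf("%s / %s / %s", target, v, mode))
      }
    }
  }
})

test_that("descriptors are positively homogeneous and ignore out-of-window coefficients", {
  set.seed(21)
  x <- rnorm(256, sd = 3)
  for (mode in c("rss", "max_abs", "sum_abs")) {
    d1 <- extract_descriptors(build_scalogram(haar_dwt(x)), mode = mode)
    d2 <- extract_descriptors(build_scalogram(haar_dwt(2 * x)), mode = mode)
    for (v in c("a20", "a40", "b20", "b40", "op80", "op160"))
      expect_equal(d2[[v]], 2 * d1[[v]], tolerance = 1e-9)
  }
  # adding energy whose segment midpoints lie outside every window (late
  # 20-band segments at 58.125 and 89.375 ms) changes nothing
  base <- haar_dwt(rep(0, 256))
  bump <- unit_pyramid(6, 3)
  bump$details[[6]][4] <- 2
  d0 <- extract_descriptors(build_scalogram(base))
  d1 <- extract_descriptors(build_scalogram(
    haar_dwt(inverse_haar_dwt(bump))))
  for (v in c("a20", "a40", "b20", "b40", "op80", "op160"))
    expect_equal(d1[[v]], d0[[v]], tolerance = 1e-9)
})

test_that("%OPs follows the stated energy-ratio formula", {
  expect_equal(percent_ops(list(b20 = 1, b40 = 1, op80 = 1, op160 = 1)), 50)
  expect_equal(percent_ops(list(b20 = 2, b40 = 1, op80 = 0, op160 = 0)), 0)
  expect_true(is.na(percent_ops(list(b20 = 0, b40 = 0, op80 = 0,
                                     op160 = 0))))
  # applying the formula to published-scale descriptor medians
  # (65.2, 55.5, 20.2, 10.8) gives ~20.4%
  expect_equal(percent_ops(list(b20 = 65.2, b40 = 55.5, op80 = 20.2,
                                op160 = 10.8)), 20.4, tolerance = 0.005)
})

test_that("time-domain features measure the designed waveform and ignore DC", {
  p <- erg_model_params(a_amp = 10, a_time = 15, a_width = 3,
                        b_amp = 20, b_time = 30, b_width = 4,
                        op_amp = 0, noise_sd = 0)
  r <- synth_erg(p)
  td <- time_domain_features(r)
  expect_equal(td$a_amp, 10, tolerance = 0.02)
  expect_equal(td$b_amp, 30, tolerance = 0.02)
  expect_lt(td$a_time_ms, td$b_time_ms)

  z <- flat_recording(0)
  tz <- time_domain_features(z)
  expect_equal(tz$a_amp, 0)
  expect_equal(tz$b_amp, 0)

  r_dc <- r
  r_dc$amplitude_uv <- r$amplitude_uv + 5
  td_dc <- time_domain_features(r_dc)
  expect_equal(td_dc$a_amp, td$a_amp, tolerance = 1e-12)
  expect_equal(td_dc$b_amp, td$b_amp, tolerance = 1e-12)

  short <- erg_recording("p", "control", "right", 1,
                         time_ms = seq(0, 40, by = 0.5),
                         amplitude_uv = rep(0, 81))
  expect_error(time_domain_features(short), "range error")
})
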
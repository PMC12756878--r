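test_that("flux of an exact linear decline matches the closed form", {
  tr <- linearTrace(rate = 0.1)
  fx <- estimateFluxSeries(tr, window_s = 40)
  expect_equal(fluxPerVolume(fx)[validMask(fx)],
               rep(100, sum(validMask(fx))), tolerance = 1e-10)
  # half-window edges are masked
  expect_false(validMask(fx)[1])
  expect_false(validMask(fx)[length(fx)])

  # instrumental background subtraction: 0.102 uM/s slope, a0 = 2
  tr2 <- linearTrace(rate = 0.102)
  fx2 <- estimateFluxSeries(tr2, calib = backgroundCalibration(a0 = 2))
  expect_equal(mean(fluxPerVolume(fx2)[validMask(fx2)]), 100,
               tolerance = 1e-10)
})

test_that("samples inside open intervals are masked", {
  tr <- linearTrace(duration = 600,
                    open_intervals = matrix(c(200, 300), ncol = 2))
  fx <- estimateFluxSeries(tr)
  t <- timeS(fx)
  expect_false(any(validMask(fx)[t >= 200 & t < 300]))
  expect_true(any(validMask(fx)[t < 180]))
})

test_that("flux is linear in the concentration signal", {
  t <- seq(0, 400, by = 2)
  C <- 180 - 0.08 * t + 0.3 * sin(t / 40)
  tr1 <- oxygraphTrace(t, C)
  tr2 <- oxygraphTrace(t, 2.5 * C + 10)
  f1 <- fluxPerVolume(estimateFluxSeries(tr1))
  f2 <- fluxPerVolume(estimateFluxSeries(tr2))
  ok <- !is.na(f1) & !is.na(f2)
  expect_equal(f2[ok], 2.5 * f1[ok], tolerance = 1e-10)
})

test_that("mark rates aggregate valid samples with dispersion and O2", {
  fx <- fluxFixture(rep(50, 20), o2 = rep(100, 20))
  r <- markRate(fx, list(t_start_s = 0, t_end_s = 40))
  expect_equal(r$value, 50)
  expect_equal(r$sd, 0)
  expect_equal(r$o2_mean, 100)

  fx2 <- fluxFixture(c(99, 100, 101))
  r2 <- markRate(fx2, list(t_start_s = 0, t_end_s = 6))
  expect_equal(r2$value, 100)
  expect_equal(r2$sd, 1)
  expect_equal(r2$n, 3)

  # median available for spike-contaminated marks
  fx3 <- fluxFixture(c(10, 10, 10, 500))
  expect_equal(markRate(fx3, list(t_start_s = 0, t_end_s = 8),
                        aggregator = "median")$value, 10)
})

test_that("a mark overlapping a reoxygenation uses only closed samples", {
  J <- rep(80, 30)
  valid <- rep(TRUE, 30)
  valid[11:20] <- FALSE            # open stretch inside the mark
  fx <- fluxFixture(J, valid = valid)
  r <- markRate(fx, list(t_start_s = 0, t_end_s = 60))
  expect_equal(r$n, 20)
  expect_equal(r$value, 80)
  expect_error(markRate(fx, list(t_start_s = 20, t_end_s = 40)),
               "too narrow or fully masked")
})

test_that("rates normalize to mass-, protein- and cell-specific units", {
  r <- normalizeRate(100, "wet_mass_mg_per_mL", 2)
  expect_equal(r$rate, 50)
  expect_equal(r$units, "pmol.s-1.mg-1")
  r2 <- normalizeRate(100, "cell_count_per_mL", 1e6)
  expect_equal(r2$rate, 100)
  expect_equal(r2$units, "amol.s-1.x-1")
  expect_equal(normalizeRate(42, "protein_mg_per_mL", 1)$rate, 42)
  expect_error(normalizeRate(1, "protein_mg_per_mL", 0), "> 0")
  expect_error(normalizeRate(1, "bogus", 1), "basis")
})

test_that("declared intervals pass through and reoxygenations are inferred", {
  oi <- matrix(c(100, 150), ncol = 2)
  tr <- linearTrace(duration = 400, open_intervals = oi)
  iv <- detectIntervals(tr, detect_reox = FALSE)
  expect_equal(unname(iv$open_intervals), unname(oi))

  # 60-s exponential rise to air saturation is detected as open
  t <- seq(0, 600, by = 2)
  C <- ifelse(t < 300, 120 - 0.1 * t,
        ifelse(t < 360, 180 - (180 - 90) * exp(-(t - 300) / 15),
               180 - 0.1 * (t - 360)))
  tr2 <- oxygraphTrace(t, C)
  iv2 <- detectIntervals(tr2, detect_reox = TRUE)
  expect_equal(nrow(iv2$open_intervals), 1)
  expect_lt(iv2$open_intervals[1, 1], 310)
  expect_gt(iv2$open_intervals[1, 2], 340)

  # titration events get the configured exclusion window
  tr3 <- linearTrace(events = data.frame(time_s = 100, label = "2D"))
  iv3 <- detectIntervals(tr3, spike_pre_s = 5, spike_post_s = 20)
  expect_equal(unname(iv3$spike_windows), matrix(c(95, 120), nrow = 1))
})

test_that("noisy slope recovery is unbiased over seeded replicates", {
  set.seed(42)
  errs <- replicate(200, {
    t <- seq(0, 400, by = 2)
    tr <- oxygraphTrace(t, 180 - 0.1 * t + rnorm(length(t), 0, 0.5))
    fx <- estimateFluxSeries(tr, window_s = 40)
    markRate(fx, list(t_start_s = 100, t_end_s = 300))$value - 100
  })
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)))
})

test_that("exclusion windows do not perturb rates of disjoint marks", {
  tr <- linearTrace(duration = 800,
                    events = data.frame(time_s = 600, label = "2D"))
  mark <- list(t_start_s = 100, t_end_s = 300)
  r1 <- markRate(estimateFluxSeries(tr), mark)$value
  iv <- detectIntervals(tr, spike_pre_s = 5, spike_post_s = 60)
  r2 <- markRate(estimateFluxSeries(tr, intervals = iv), mark)$value
  expect_identical(r1, r2)
})

test_that("degenerate windows and fully-masked traces are rejected", {
  tr <- linearTrace(duration = 100)
  expect_error(estimateFluxSeries(tr, window_s = 500), "larger than every")
  tr2 <- linearTrace(duration = 100,
                     open_intervals = matrix(c(0, 200), ncol = 2))
  expect_error(estimateFluxSeries(tr2), "masked")
})
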
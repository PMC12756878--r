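test_that("a noiseless single state declines at exactly J/1000 uM per s", {
  spec <- simulationSpec(miniProtocol(),
                         true_state_fluxes = c("1X" = 100),
                         chb_coefficients = c(0, 0),
                         spike_amplitude_uM = 0, state_duration_s = 200)
  run <- simulateRun(spec)
  d <- diff(o2Conc(run$trace)) / diff(timeS(run$trace))
  expect_equal(d, rep(-0.1, length(d)), tolerance = 1e-12)
})

test_that("the same seed reproduces the run bit-for-bit", {
  spec <- simulationSpec("RP1", seed = 11, noise_sd_uM = 0.5,
                         state_duration_s = 200)
  r1 <- simulateRun(spec)
  r2 <- simulateRun(spec)
  expect_identical(o2Conc(r1$trace), o2Conc(r2$trace))
  expect_identical(r1$marks, r2$marks)
  r3 <- simulateRun(simulationSpec("RP1", seed = 12, noise_sd_uM = 0.5,
                                   state_duration_s = 200))
  expect_false(identical(o2Conc(r1$trace), o2Conc(r3$trace)))
})

test_that("oxygen stays non-negative and above threshold while closed", {
  run <- simulateRun(simulationSpec("RP1", seed = 2, noise_sd_uM = 0.5))
  expect_true(all(o2Conc(run$trace) >= 0))
  # reoxygenations were inserted (high fluxes must deplete 180 uM)
  expect_gt(nrow(openIntervals(run$trace)), 0)
})

test_that("mass balance holds over noiseless closed intervals", {
  spec <- simulationSpec(miniProtocol(),
                         true_state_fluxes = c("1X" = 120),
                         background = backgroundCalibration(a0 = 1,
                                                            b0 = 0.01),
                         chb_coefficients = c(0, 0),
                         spike_amplitude_uM = 0, state_duration_s = 300)
  run <- simulateRun(spec)
  t <- timeS(run$trace); C <- o2Conc(run$trace)
  # total flux at each step includes the instrumental background
  J <- 120 + 1 + 0.01 * C[-length(C)]
  expect_equal(diff(C), -diff(t) * J / 1000, tolerance = 1e-12)
})

test_that("ground truth and pipeline tables match step for step", {
  run <- simulateRun(simulationSpec("RP1", seed = 5))
  rp1 <- builtinProtocol("RP1")
  expect_equal(nrow(run$truth$steps), 14)
  tab <- recoverTable(run, rp1)
  rows <- stateRates(tab)
  expect_equal(rows$step, protocolSteps(rp1)$label)
  got <- ifelse(is.na(rows$rate_corrected), rows$rate_total,
                rows$rate_corrected)
  truth <- unname(run$truth$corrected[rows$step])
  expect_equal(got, truth, tolerance = 1e-3)
})

test_that("an infeasible flux fails naming the step", {
  expect_error(
    simulateRun(simulationSpec(miniProtocol(),
                               true_state_fluxes = c("1X" = 60000),
                               chb_coefficients = c(0, 0))),
    "'1X'.*too fast")
})

test_that("declining OXPHOS is flagged and E_corr restores the ratio", {
  spec <- simulationSpec("RP1", seed = 8, nonsteady = c("2c" = 0.2))
  run <- simulateRun(spec)
  iv <- detectIntervals(run$trace, detect_reox = FALSE)
  fx <- estimateFluxSeries(run$trace, intervals = iv)
  # P1: the step's own mark; P2: a window immediately before uncoupling
  mk <- run$marks
  m2c <- mk[mk$label == "2c", ]
  p1_win <- list(t_start_s = m2c$t_start_s,
                 t_end_s = m2c$t_start_s + 0.3 * (m2c$t_end_s - m2c$t_start_s))
  p2_win <- list(t_start_s = m2c$t_end_s - 60, t_end_s = m2c$t_end_s)
  P1 <- markRate(fx, p1_win)$value
  P2 <- markRate(fx, p2_win)$value
  rep <- stepAnalysis(data.frame(state = "N{PM}_P", Z = P1, Y_next = P2))
  expect_equal(rep$status, "declining")
  E <- max(stateRates(suppressWarnings(
    assignStates(mk, builtinProtocol("RP1"), fx)))$rate_total[
      stateRates(suppressWarnings(
        assignStates(mk, builtinProtocol("RP1"), fx)))$step == "3U"])
  Ec <- ecorr(P1, P2, E)
  expect_equal(P1 / Ec, P2 / E, tolerance = 1e-12)
})

test_that("cohorts preserve true ratios and scale between samples", {
  base <- simulationSpec("RP1", seed = 1, state_duration_s = 200)
  same <- simulateCohort(3, 0, base, seed = 2)
  expect_equal(same$scales, rep(1, 3))
  expect_identical(o2Conc(same$runs[[1]]$trace),
                   o2Conc(same$runs[[1]]$trace))

  coh <- simulateCohort(4, 0.15, base, seed = 2)
  expect_equal(length(coh$runs), 4)
  expect_gt(sd(coh$scales), 0)
  expect_equal(coh$true_ratios$L_over_P, 0.2, tolerance = 1e-12)
  # recovered per-sample L/P stays at the shared truth despite scaling
  lp <- vapply(coh$runs, function(run) {
    tab <- recoverTable(run, builtinProtocol("RP1"))
    v <- stateRates(tab)
    L <- v$rate_corrected[v$step == "1PM"]
    P <- v$rate_corrected[v$step == "2c"]
    L / P
  }, numeric(1))
  expect_equal(lp, rep(0.2, 4), tolerance = 0.01)
})

test_that("spec validation rejects inconsistent settings", {
  expect_error(simulationSpec("RP1", true_state_fluxes = c(bogus = 5)),
               "unknown step")
  expect_error(simulationSpec("RP1", reox_threshold_uM = 200),
               "reox_threshold")
  expect_error(simulationSpec("RP1", uncoupler_fractions = c(0.8, 0.9)),
               "uncoupler_fractions")
})
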
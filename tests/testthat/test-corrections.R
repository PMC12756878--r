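test_that("rox baseline correction subtracts only from coupling states", {
  tab <- tableFixture(c("2D" = 105, "1PM" = 4, "9Ama" = 5, "+Dig" = 8,
                        "11Azd" = 2),
                      c("P", "L", "rox", "ren", "chb"))
  out <- baselineCorrectRox(tab)
  rows <- stateRates(out)
  expect_equal(rows$rate_corrected[rows$step == "2D"], 100)
  # rox > L: negative rate reported and flagged, not clamped
  expect_equal(rows$rate_corrected[rows$step == "1PM"], -1)
  expect_match(rows$flags[rows$step == "1PM"], "negative_corrected")
  # auxiliary rates stay as totals
  expect_true(all(is.na(rows$rate_corrected[rows$step %in%
                                            c("9Ama", "+Dig", "11Azd")])))
  expect_true(isRoxCorrected(out))
})

test_that("rox correction is idempotent and tolerates a missing rox row", {
  tab <- baselineCorrectRox(rp1TableFixture())
  twice <- baselineCorrectRox(tab)
  expect_equal(stateRates(twice), stateRates(tab))

  norox <- tableFixture(c("2D" = 100), "P")
  expect_warning(out <- baselineCorrectRox(norox), "rox row absent")
  expect_false(isRoxCorrected(out))
  expect_match(stateRates(out)$flags, "rox_missing")
})

test_that("FAO capacity is the malate-subtracted octanoylcarnitine flux", {
  expect_equal(faoCapacity(50, 20)$F_P, 30)
  expect_equal(faoCapacity(20, 20)$F_P, 0)
  neg <- faoCapacity(15, 20)
  expect_equal(neg$F_P, -5)
  expect_equal(neg$flag, "no_detectable_F_capacity")
})

test_that("cytochrome-c control efficiency flags outer-membrane damage", {
  expect_equal(cytcControlEfficiency(80, 100)$efficiency, 0.2)
  expect_true(cytcControlEfficiency(80, 100)$damaged)
  expect_equal(cytcControlEfficiency(100, 100)$efficiency, 0)
  inh <- cytcControlEfficiency(100, 90)
  expect_equal(inh$efficiency, -1 / 9)
  expect_false(inh$damaged)
  expect_error(cytcControlEfficiency(50, 0), "positive")
  # scale invariance of the flag logic: equal inputs at any magnitude
  for (m in c(1e-3, 1, 1e4))
    expect_false(cytcControlEfficiency(m, m)$damaged)
})

test_that("chemical background fits exclude points below 50 uM", {
  o2 <- c(160, 130, 100, 70, 40)
  pts <- data.frame(o2_uM = o2, J = 2 + 0.04 * o2)
  suppressMessages(fit <- calibrateChemicalBackground(pts))
  expect_equal(fit$a_chb, 2, tolerance = 1e-12)
  expect_equal(fit$b_chb, 0.04, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)
  expect_equal(fit$n_points, 4)
  expect_equal(fit$n_excluded, 1)
  expect_error(calibrateChemicalBackground(
    data.frame(o2_uM = c(40, 45, 60), J = 1:3)), "at least 2")
})

test_that("Complex IV activity works in matched and fit modes", {
  expect_equal(civActivity(120, 100, J_azd = 6, o2_azd = 98)$CIV_E, 114)
  fit <- list(a_chb = 2, b_chb = 0.04, valid_range = c(60, 160))
  expect_equal(civActivity(120, 100, chb_fit = fit)$CIV_E, 114)
  expect_error(civActivity(120, 100, J_azd = 6, o2_azd = 60),
               "mismatch.*fit mode")
  expect_error(civActivity(120, 200, chb_fit = fit), "outside")
  # fit mode equals matched mode when the azide point lies on the line
  o2m <- 97
  matched <- civActivity(120, o2m, J_azd = 2 + 0.04 * o2m, o2_azd = o2m)
  viafit <- civActivity(120, o2m, chb_fit = fit)
  expect_equal(viafit$CIV_E, matched$CIV_E, tolerance = 1e-12)
})

test_that("step analysis classifies drift between shared-state rates", {
  rep <- stepAnalysis(data.frame(
    state = c("P", "Q", "R"), Z = c(100, 100, 100),
    Y_next = c(100, 90, 104)), tol = 0.03)
  expect_equal(rep$status, c("steady", "declining", "rising"))
  expect_equal(rep$d, c(0, 0.1, -0.04))
  # the default 5% tolerance treats a 4% excursion as steady
  expect_equal(stepAnalysis(data.frame(state = "R", Z = 100,
                                       Y_next = 104))$status, "steady")
})

test_that("the declining-P correction restores the P/E identity", {
  expect_equal(ecorr(110, 100, 100), 110)
  expect_equal(ecorr(95, 95, 80), 80)
  P1 <- 117.3; P2 <- 104.9; E <- 111.2
  expect_equal(P1 / ecorr(P1, P2, E), P2 / E, tolerance = 1e-15)
  expect_error(ecorr(100, 0, 90), "P2")
})
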
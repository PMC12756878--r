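test_that("flux control ratios normalize by the reference state", {
  tab <- tableFixture(c("1PM" = 10, "2D" = 80, "5S" = 100),
                      c("L", "P", "E"))
  f <- fluxControlRatios(tab, reference = "5S")
  expect_equal(unname(f[c("1PM", "2D", "5S")]), c(0.1, 0.8, 1.0))
  # default reference comes from the protocol definition
  full <- baselineCorrectRox(rp1TableFixture())
  f2 <- fluxControlRatios(full)
  expect_equal(unname(f2["5S"]), 1)
  # invariance under normalization (common positive factor)
  scaled <- tab
  scaled@rows$rate_total <- scaled@rows$rate_total / 7.3
  expect_equal(fluxControlRatios(scaled, reference = "5S"), f)
  expect_error(fluxControlRatios(tab, reference = "9Ama"), "not present")
})

test_that("coupling efficiencies follow their defining ratios", {
  # L/P = 0.18 gives a P-L control efficiency of 0.82
  ce <- couplingEfficiencies(L = 18, P = 100, E = 100)
  expect_equal(ce$pl_eff, 0.82)
  expect_equal(ce$L_over_P, 0.18)
  # fully dyscoupled: L = E
  expect_equal(couplingEfficiencies(100, 100, 100)$el_eff, 0)
  # P = E: no excess capacity, and the two efficiencies coincide
  ce2 <- couplingEfficiencies(20, 90, 90)
  expect_equal(ce2$ep_eff, 0)
  expect_equal(ce2$pl_eff, ce2$el_eff)
  # E < P is flagged as theoretically impossible
  expect_warning(ce3 <- couplingEfficiencies(10, 100, 91), "impossible")
  expect_true(ce3$flag_E_lt_P)
  expect_error(couplingEfficiencies(10, 0, 90), "P must")
})

test_that("el_eff + L/E = 1 for any admissible rates", {
  set.seed(1)
  for (i in 1:50) {
    E <- runif(1, 10, 300)
    L <- runif(1, 0, E)
    P <- runif(1, L + 1e-6, E)
    ce <- couplingEfficiencies(L, P, E)
    expect_equal(ce$el_eff + ce$L_over_E, 1, tolerance = 1e-12)
  }
})

test_that("step control efficiency measures relative stimulation", {
  expect_equal(stepControlEfficiency(100, 100), 0)
  expect_equal(stepControlEfficiency(80, 100), 0.2)
  expect_equal(stepControlEfficiency(100, 95), -1 / 19)
  expect_error(stepControlEfficiency(10, 0), "positive")
})

test_that("NS-N control efficiency measures succinate stimulation", {
  expect_equal(nsNControlEfficiency(60, 120), 0.5)
  expect_equal(nsNControlEfficiency(120, 120), 0)
  expect_equal(nsNControlEfficiency(30, 120), 0.75)
})

test_that("additivity index spans complete to zero additivity", {
  a <- additivityIndex(40, 60, 100)     # NS = N + S
  expect_equal(a$A, 1)
  expect_equal(a$dominant, "S")
  z <- additivityIndex(40, 100, 100)    # NS = S: no stimulation by N
  expect_equal(z$A, 0)
  m <- additivityIndex(60, 90, 120)
  expect_equal(m$alpha, 0.75)
  expect_equal(m$beta, 0.5)
  expect_equal(m$dominant, "S")
  expect_equal(m$A, 0.5)
  expect_equal(m$N_over_S, 2 / 3)
  # exact tie: S is designated dominant, deterministically
  tie <- additivityIndex(70, 70, 100)
  expect_equal(tie$dominant, "S")
})

test_that("additivity agrees with a brute-force assignment oracle", {
  oracle <- function(N, S, NS) {
    # enumerate both pathway assignments, keep the one with alpha >= beta
    cand <- list(c(alpha = N / NS, beta = S / NS),
                 c(alpha = S / NS, beta = N / NS))
    pick <- cand[[which.max(vapply(cand, `[[`, numeric(1), "alpha"))]]
    (1 - pick[["alpha"]]) / pick[["beta"]]
  }
  set.seed(7)
  for (i in 1:1000) {
    N <- runif(1, 1, 200); S <- runif(1, 1, 200)
    NS <- runif(1, max(N, S) * 0.8, N + S + 50)
    expect_equal(additivityIndex(N, S, NS)$A, oracle(N, S, NS),
                 tolerance = 1e-12)
  }
})

test_that("correct RCR is the inverse mean linearized ratio", {
  expect_equal(aggregateRatio(25, 100)$correct_RCR, 4)
  agg <- aggregateRatio(c(10, 30), c(100, 100))
  expect_equal(agg$mean_L_over_P, 0.2)
  expect_equal(agg$correct_RCR, 5)
  expect_equal(agg$naive_RCR, (10 + 10 / 3) / 2)
  expect_gte(agg$naive_RCR, agg$correct_RCR)
  # equality iff all ratios are identical
  eq <- aggregateRatio(c(20, 40), c(100, 200))
  expect_equal(eq$correct_RCR, eq$naive_RCR)
  # a zero leak makes the naive mean undefined but not the correct RCR
  z <- aggregateRatio(c(0, 20), c(100, 100))
  expect_true(is.na(z$naive_RCR))
  expect_equal(z$correct_RCR, 10)
})

test_that("Jensen's inequality holds on random sample sets", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    P <- runif(n, 50, 200)
    L <- runif(n, 1, 0.5 * P)
    agg <- aggregateRatio(L, P)
    expect_gte(agg$naive_RCR + 1e-12, agg$correct_RCR)
  }
})

test_that("profiles summarize per-sample ratios, never ratios of means", {
  s1 <- list(rp1 = baselineCorrectRox(rp1TableFixture("a")),
             rp2 = baselineCorrectRox(rp2TableFixture("a")))
  prof1 <- buildProfile(list(a = s1))
  # single sample: medians equal the sample values
  m <- prof1$summaries
  expect_equal(m$median, m$mean)
  expect_true(all(m$n == 1))
  ref <- prof1$fcr[prof1$fcr$step == "5S" & prof1$fcr$protocol == "RP1", ]
  expect_equal(ref$fcr, 1)

  # scale one sample: ratios unchanged, so summaries have zero spread
  s2 <- list(rp1 = baselineCorrectRox(rp1TableFixture("b", scale = 3)),
             rp2 = baselineCorrectRox(rp2TableFixture("b", scale = 3)))
  prof <- buildProfile(list(a = s1, b = s2))
  lp <- prof$metrics[prof$metrics$metric == "L_over_P", "value"]
  expect_equal(lp[1], lp[2], tolerance = 1e-12)
  refsum <- prof$fcr_summaries
  r5 <- refsum[refsum$step == "5S" & refsum$protocol == "RP1", ]
  expect_equal(r5$median, 1)
  expect_equal(r5$q3 - r5$q1, 0)

  # mean-of-ratios differs from ratio-of-means on heterogeneous samples
  L <- c(10, 30, 20); P <- c(100, 80, 60)
  expect_false(isTRUE(all.equal(mean(L / P), mean(L) / mean(P))))
  expect_equal(aggregateRatio(L, P)$mean_L_over_P, mean(L / P))
})
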
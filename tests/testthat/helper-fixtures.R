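# Fixtures are built in code; no binary or stored data.

# Linear-decline trace: C(t) = c0 - rate * t, sampled every dt seconds.
linearTrace <- function(rate = 0.1, c0 = 180, duration = 400, dt = 2, ...) {
  t <- seq(0, duration, by = dt)
  oxygraphTrace(time_s = t, o2_uM = c0 - rate * t, ...)
}

# Hand-built flux series with a given J vector, all valid unless masked.
fluxFixture <- function(J, dt = 2, o2 = NULL, valid = NULL) {
  n <- length(J)
  t <- seq(0, by = dt, length.out = n)
  if (is.null(o2)) o2 <- seq(150, 140, length.out = n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  J[!valid] <- NA_real_
  new("FluxSeries", run_id = "fixture", time_s = t, J_V = J, o2_uM = o2,
      valid = valid, window_s = dt * 2, background = c(0, 0))
}

# Minimal single-state protocol for closed-form simulator checks.
miniProtocol <- function() {
  steps <- data.frame(
    label = "1X", titrant = "substrate", target_concentration = "1 mM",
    pathway_state = "N_P", coupling_state = "P", substrate_annotation = "",
    multi_titration = FALSE, role = "state", stringsAsFactors = FALSE)
  new("ProtocolDefinition", protocol_id = "MINI", steps = steps,
      reference_state = "1X")
}

# State-rate table built directly from named total rates.
tableFixture <- function(rates, coupling, pathway = NULL, protocol = "RP1",
                         run_id = "fixture", role = NULL) {
  if (is.null(pathway)) pathway <- names(rates)
  if (is.null(role)) role <- rep("state", length(rates))
  rows <- data.frame(
    step = names(rates), pathway_state = pathway,
    coupling_state = coupling, role = role,
    rate_total = unname(rates), rate_corrected = NA_real_,
    sd = 0, n = 10L, o2_mean = 120, flags = "",
    stringsAsFactors = FALSE)
  new("StateRateTable", run_id = run_id, protocol_id = protocol,
      rows = rows)
}

# Full RP1 table with the simulator's default magnitudes (totals).
rp1TableFixture <- function(run_id = "fix1", scale = 1) {
  rates <- c("ce1" = 30, "+Dig" = 8, "1PM" = 17, "2D" = 73, "2c" = 73,
             "3U" = 93, "4G" = 103, "5S" = 163, "6Oct" = 168, "7Rot" = 123,
             "8Gp" = 133, "9Ama" = 3, "10AsTm" = 224, "11Azd" = 4) * scale
  st <- protocolSteps(builtinProtocol("RP1"))
  tableFixture(rates[st$label], st$coupling_state, st$pathway_state,
               "RP1", run_id, st$role)
}

rp2TableFixture <- function(run_id = "fix2", scale = 1) {
  rates <- c("ce1" = 30, "+Dig" = 8, "+D" = 10, "+M.1" = 12, "1Oct" = 40,
             "1c" = 40, "2M2" = 48, "3P" = 73, "4G" = 78, "5S" = 158,
             "6Gp" = 173, "7U" = 183, "8Rot" = 133, "9Ama" = 3,
             "10AsTm" = 224, "11Azd" = 4) * scale
  st <- protocolSteps(builtinProtocol("RP2"))
  tableFixture(rates[st$label], st$coupling_state, st$pathway_state,
               "RP2", run_id, st$role)
}

# Quick full-pipeline recovery from a simulated run.
recoverTable <- function(run, protocol, window_s = 40) {
  iv <- detectIntervals(run$trace, detect_reox = FALSE)
  fx <- estimateFluxSeries(run$trace, window_s = window_s, intervals = iv)
  baselineCorrectRox(assignStates(run$marks, protocol, fx))
}
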
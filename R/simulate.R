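#' @include states.R
NULL

## Default true state fluxes (volumetric totals, pmol s^-1 mL^-1) emulating a
## permeabilized-cell run at 2e6 cells in a 2-mL chamber: routine ~30,
## leak/OXPHOS/ET coupling in the N-pathway, convergent-pathway ET rates,
## small residual oxygen consumption, and a Complex IV assay rate well above
## the ET reference. Chosen once as typical magnitudes; corrected L/P = 0.20
## and NS-additivity 0.4 fall inside the published ranges for permeabilized
## cells.
.defaultFluxes <- function(protocol_id) {
  switch(protocol_id,
    RP1 = c("ce1" = 30, "+Dig" = 8, "1PM" = 17, "2D" = 73, "2c" = 73,
            "3U" = 93, "4G" = 103, "5S" = 163, "6Oct" = 168, "7Rot" = 123,
            "8Gp" = 133, "9Ama" = 3, "10AsTm" = 220, "11Azd" = 0),
    RP2 = c("ce1" = 30, "+Dig" = 8, "+D" = 10, "+M.1" = 12, "1Oct" = 40,
            "1c" = 40, "2M2" = 48, "3P" = 73, "4G" = 78, "5S" = 158,
            "6Gp" = 173, "7U" = 183, "8Rot" = 133, "9Ama" = 3,
            "10AsTm" = 220, "11Azd" = 0),
    RP1_blood = c("ce1" = 30, "+Dig" = 8, "1PM" = 17, "2D" = 73, "2c" = 73,
                  "3U" = 93, "4G" = 103, "5S" = 163, "6Rot" = 123,
                  "7Gp" = 133, "8Ama" = 3, "9AsTm" = 220, "10Azd" = 0),
    stop("no default fluxes for protocol ", protocol_id))
}

#' Specification of a synthetic oxygraph run
#'
#' Collects every knob of the forward simulator: the protocol, the true
#' volumetric flux of each titration step, sampling and state duration,
#' reoxygenation behaviour, instrumental background, the oxygen-dependent
#' chemical background of the Complex IV assay, optional per-step linear
#' flux drift (non-steady states), optional cytochrome-c stimulation
#' (outer-membrane damage), titration-spike artifacts and measurement noise.
#'
#' @param protocol protocol id or \linkS4class{ProtocolDefinition}.
#' @param true_state_fluxes named vector of volumetric fluxes per step label;
#'   defaults to typical permeabilized-cell magnitudes for the built-in
#'   protocols.
#' @param state_duration_s closed measurement time per state, seconds.
#' @param sampling_interval_s sampling interval, seconds.
#' @param o2_start_uM initial oxygen concentration.
#' @param reox_threshold_uM reoxygenate when O2 falls below this (default 50).
#' @param reox_target_uM oxygen level the open chamber equilibrates to
#'   (air saturation ~180 uM for MiR05 at 37 C).
#' @param background instrumental \code{\link{backgroundCalibration}}.
#' @param chb_coefficients \code{c(a_c, b_c)} of the autoxidation flux
#'   \code{a_c + b_c * C}, active from the ascorbate+TMPD step on.
#' @param noise_sd_uM additive Gaussian measurement noise on O2.
#' @param nonsteady named vector of fractional linear flux declines over a
#'   step (e.g. \code{c("2D" = 0.1)} for 10\% decline during the OXPHOS
#'   state).
#' @param cytc_damage fractional stimulation of respiration at the
#'   cytochrome-c step (the simulated outer-membrane damage); 0 = intact.
#' @param spike_amplitude_uM,spike_width_s titration spike artifact size.
#' @param uncoupler_fractions per-dose fractions of the true ET capacity
#'   realized during the stepwise uncoupler titration; the optimum (1.0)
#'   must be among them.
#' @param chb_calibration_targets O2 levels (uM) at which the chemical
#'   background is re-measured after the azide step (chamber re-equilibrated
#'   by gas control between closed segments).
#' @param chb_segment_s closed measurement time per calibration level.
#' @param seed integer seed; runs are bit-reproducible for a fixed seed.
#' @return list of class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(protocol = "RP1", true_state_fluxes = NULL,
                           state_duration_s = 300, sampling_interval_s = 2,
                           o2_start_uM = 180, reox_threshold_uM = 50,
                           reox_target_uM = 180,
                           background = backgroundCalibration(),
                           chb_coefficients = c(a_c = 8, b_c = 0.1),
                           noise_sd_uM = 0, nonsteady = numeric(0),
                           cytc_damage = 0, spike_amplitude_uM = 3,
                           spike_width_s = 10,
                           uncoupler_fractions = c(0.9, 1, 0.97),
                           chb_calibration_targets = c(180, 150, 125, 100,
                                                       75, 55, 40),
                           chb_segment_s = 1200, seed = 1L) {
  proto <- if (is(protocol, "ProtocolDefinition")) protocol
           else builtinProtocol(protocol)
  fluxes <- tryCatch(.defaultFluxes(proto@protocol_id),
                     error = function(e) {
                       v <- numeric(0)
                       names(v) <- character(0)
                       v
                     })
  if (!is.null(true_state_fluxes)) {
    stopifnot(!is.null(names(true_state_fluxes)))
    unknown <- setdiff(names(true_state_fluxes), proto@steps$label)
    if (length(unknown))
      stop("true_state_fluxes for unknown step(s): ",
           paste(unknown, collapse = ", "))
    fluxes[names(true_state_fluxes)] <- true_state_fluxes
  }
  missing <- setdiff(proto@steps$label, names(fluxes))
  if (length(missing))
    stop("no true flux for step(s): ", paste(missing, collapse = ", "))
  if (any(fluxes < 0)) stop("state fluxes must be >= 0")
  stopifnot(state_duration_s > 0, sampling_interval_s > 0,
            reox_threshold_uM < reox_target_uM,
            cytc_damage >= 0, cytc_damage < 1,
            any(uncoupler_fractions == 1))
  ## cytochrome-c stimulation acts on the mitochondrial (rox-corrected)
  ## part of the flux: the post-c step rises above its pre-c level
  if (cytc_damage > 0) {
    rox_lab <- proto@steps$label[proto@steps$coupling_state == "rox"]
    rox_val <- if (length(rox_lab)) unname(fluxes[rox_lab[1]]) else 0
    cs <- proto@steps$label[proto@steps$substrate_annotation == "[c]"]
    for (lab in cs)
      fluxes[lab] <- (fluxes[lab] - rox_val) / (1 - cytc_damage) + rox_val
  }
  structure(list(
    protocol = proto, true_state_fluxes = fluxes[proto@steps$label],
    state_duration_s = state_duration_s,
    sampling_interval_s = sampling_interval_s,
    o2_start_uM = o2_start_uM, reox_threshold_uM = reox_threshold_uM,
    reox_target_uM = reox_target_uM, background = background,
    chb_coefficients = chb_coefficients, noise_sd_uM = noise_sd_uM,
    nonsteady = nonsteady, cytc_damage = cytc_damage,
    spike_amplitude_uM = spike_amplitude_uM, spike_width_s = spike_width_s,
    uncoupler_fractions = uncoupler_fractions,
    chb_calibration_targets = chb_calibration_targets,
    chb_segment_s = chb_segment_s, seed = as.integer(seed)),
    class = "SimulationSpec")
}

#' Forward-simulate a complete SUIT oxygraph run
#'
#' Integrates the chamber oxygen balance
#' \code{dC/dt = -(J_state(t) + a0 + b0 C + [chb active] (a_c + b_c C))/1000}
#' by explicit Euler at the sampling interval within closed-chamber
#' segments. When the concentration falls below the reoxygenation threshold
#' an open interval with exponential approach to the target level is
#' inserted. Titrations leave spike artifacts on the recorded concentration;
#' Gaussian measurement noise is added last. Marks are placed on the final
#' 60\% of each state's (last contiguous) closed plateau. The uncoupler step
#' is titrated stepwise through \code{uncoupler_fractions} of the true ET
#' capacity with one mark per dose. After the azide step the chemical
#' background is re-measured at several oxygen levels, yielding calibration
#' marks for \code{\link{calibrateChemicalBackground}}.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{trace} (\linkS4class{OxygraphTrace}),
#'   \code{marks} (protocol mark table), \code{chb_marks} (chemical
#'   background calibration windows) and \code{truth}: per-step true mark
#'   rates (\code{state_rates}), rox-corrected truth (\code{corrected}),
#'   nominal fluxes, drift endpoints, open intervals, the chb line, the true
#'   Complex IV flux and the cytochrome-c stimulation.
#' @export
simulateRun <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  proto <- spec$protocol
  st <- proto@steps
  dt <- spec$sampling_interval_s
  a0 <- spec$background[["a0"]]; b0 <- spec$background[["b0"]]
  a_c <- unname(spec$chb_coefficients[1])
  b_c <- unname(spec$chb_coefficients[2])
  thr <- spec$reox_threshold_uM; tgt <- spec$reox_target_uM

  env <- new.env()
  env$t <- 0; env$C <- spec$o2_start_uM
  env$time <- list(0); env$o2 <- list(spec$o2_start_uM)
  env$J_true <- list(NA_real_)   # instantaneous sample flux (no instrument bg)
  env$closed <- list(TRUE)
  env$k <- 1L
  env$open_iv <- NULL
  env$events <- NULL

  push <- function(tm, C, J, closed) {
    env$k <- env$k + 1L
    env$time[[env$k]] <- tm; env$o2[[env$k]] <- C
    env$J_true[[env$k]] <- J; env$closed[[env$k]] <- closed
  }

  reox <- function(target) {
    tau <- 15
    t0 <- env$t + dt
    C0 <- env$C
    off <- dt
    repeat {
      C <- target - (target - C0) * exp(-off / tau)
      push(env$t + off, C, NA_real_, FALSE)
      if (abs(C - target) < 1 || off > 240) break
      off <- off + dt
    }
    env$t <- env$t + off
    env$C <- target
    env$open_iv <- rbind(env$open_iv, c(t0, env$t + dt))
  }

  titrate <- function(label) {
    ev_t <- env$t + dt
    env$events <- rbind(env$events,
                        data.frame(time_s = ev_t, label = label,
                                   stringsAsFactors = FALSE))
  }

  ## integrate `duration` seconds of closed measurement; J_fun(tau, C) is the
  ## sample flux (mitochondrial + chemical background) at closed-time offset
  ## tau. Returns the time bounds of the contiguous closed runs produced.
  emit_closed <- function(J_fun, duration, step_label, thr_local = thr) {
    n <- round(duration / dt)
    runs <- NULL
    run_start <- env$t + dt
    tau <- 0
    for (i in seq_len(n)) {
      J <- J_fun(tau, env$C)
      Jtot <- J + a0 + b0 * env$C
      C_next <- env$C - dt * Jtot / 1000
      if (C_next < thr_local) {
        if ((tgt - thr_local) * 1000 / max(Jtot, 1e-9) < 3 * dt)
          stop("step '", step_label,
               "' consumes oxygen too fast to complete between ",
               "reoxygenations")
        runs <- rbind(runs, c(run_start, env$t + dt))
        reox(tgt)
        run_start <- env$t + dt
        J <- J_fun(tau, env$C)
        C_next <- env$C - dt * (J + a0 + b0 * env$C) / 1000
      }
      env$t <- env$t + dt
      env$C <- C_next
      push(env$t, env$C, J, TRUE)
      tau <- tau + dt
    }
    rbind(runs, c(run_start, env$t + dt))
  }

  place_mark <- function(runs, frac = 0.6) {
    len <- runs[, 2] - runs[, 1]
    r <- runs[which.max(len), ]
    c(r[2] - frac * (r[2] - r[1]), r[2])
  }

  marks <- NULL
  chb_marks <- NULL
  truth_rows <- NULL
  azd_like <- st$coupling_state %in% c("CIV", "chb")

  for (i in seq_len(nrow(st))) {
    lab <- st$label[i]
    J_base <- unname(spec$true_state_fluxes[lab])
    chb_on <- azd_like[i]
    drift <- if (lab %in% names(spec$nonsteady))
      unname(spec$nonsteady[lab]) else 0

    if (st$multi_titration[i]) {
      ## each uncoupler dose gets a full measurement interval of its own
      fr <- spec$uncoupler_fractions
      sub_dur <- spec$state_duration_s
      for (j in seq_along(fr)) {
        sub_lab <- paste0(lab, j)
        titrate(sub_lab)
        Jj <- J_base * fr[j]
        runs <- emit_closed(function(tau, C) Jj, sub_dur, sub_lab)
        mk <- place_mark(runs)
        marks <- rbind(marks, data.frame(
          label = sub_lab, t_start_s = mk[1], t_end_s = mk[2],
          role = "state", stringsAsFactors = FALSE))
      }
      truth_rows <- rbind(truth_rows, data.frame(
        step = lab, J_nominal = J_base, drift = 0,
        stringsAsFactors = FALSE))
    } else {
      ## the Complex IV assay opens the chamber for redox equilibration
      ## before the substrates act, so it starts reoxygenated
      if (st$coupling_state[i] == "CIV") reox(tgt)
      if (i > 1) titrate(lab)
      dur <- spec$state_duration_s
      J_fun <- function(tau, C) {
        J_base * (1 - drift * tau / dur) + if (chb_on) a_c + b_c * C else 0
      }
      runs <- emit_closed(J_fun, dur, lab)
      mk <- place_mark(runs)
      marks <- rbind(marks, data.frame(
        label = lab, t_start_s = mk[1], t_end_s = mk[2], role = "state",
        stringsAsFactors = FALSE))
      truth_rows <- rbind(truth_rows, data.frame(
        step = lab, J_nominal = J_base, drift = drift,
        stringsAsFactors = FALSE))
    }
  }

  ## chemical-background calibration levels after the azide step; these
  ## deliberately sample O2 below the reoxygenation threshold, so the
  ## threshold is suspended for them (the ETS is fully inhibited here)
  if ((a_c != 0 || b_c != 0) && any(st$coupling_state == "chb")) {
    for (j in seq_along(spec$chb_calibration_targets)) {
      reox(spec$chb_calibration_targets[j])
      runs <- emit_closed(function(tau, C) a_c + b_c * C,
                          spec$chb_segment_s, "chb_calibration",
                          thr_local = 0)
      mk <- place_mark(runs, frac = 0.95)
      chb_marks <- rbind(chb_marks, data.frame(
        label = paste0("chb_cal", j), t_start_s = mk[1], t_end_s = mk[2],
        role = "state", stringsAsFactors = FALSE))
    }
  }

  time <- unlist(env$time)
  o2 <- unlist(env$o2)
  J_true <- unlist(env$J_true)
  closed <- unlist(env$closed)

  ## titration spikes: symmetric triangular transient on the recorded O2
  if (!is.null(env$events) && spec$spike_amplitude_uM > 0) {
    hw <- spec$spike_width_s / 2
    for (ev_t in env$events$time_s) {
      w <- abs(time - ev_t) < hw
      o2[w] <- o2[w] + spec$spike_amplitude_uM * (1 - abs(time[w] - ev_t) / hw)
    }
  }
  if (spec$noise_sd_uM > 0)
    o2 <- pmax(o2 + stats::rnorm(length(o2), 0, spec$noise_sd_uM), 0)

  open_iv <- env$open_iv
  if (is.null(open_iv)) open_iv <- matrix(numeric(0), ncol = 2)
  trace <- oxygraphTrace(
    time_s = time, o2_uM = o2,
    run_id = sprintf("sim_%s_seed%d", proto@protocol_id, spec$seed),
    norm_basis = "cell_count_per_mL", norm_value = 1e6,
    events = env$events, open_intervals = open_iv)

  ## true mark rates: mean instantaneous sample flux over each mark window
  mark_truth <- function(mk) {
    sel <- closed & time >= mk["t_start_s"] & time < mk["t_end_s"]
    mean(J_true[sel], na.rm = TRUE)
  }
  all_marks <- validateMarks(marks, proto)
  state_rates <- vapply(split(all_marks, all_marks$step), function(mk) {
    max(vapply(seq_len(nrow(mk)), function(j)
      mark_truth(unlist(mk[j, c("t_start_s", "t_end_s")])), numeric(1)))
  }, numeric(1))
  state_rates <- state_rates[st$label]
  names(state_rates) <- st$label

  rox <- unname(spec$true_state_fluxes[st$label[st$coupling_state == "rox"]])
  corr <- ifelse(st$coupling_state %in% .CORRECTABLE_STATES,
                 state_rates - rox, state_rates)
  names(corr) <- st$label
  civ_lab <- st$label[st$coupling_state == "CIV"]

  truth <- list(
    steps = truth_rows,
    state_rates = state_rates,
    corrected = corr,
    rox = rox,
    open_intervals = open_iv,
    chb_line = c(a_chb = a_c, b_chb = b_c),
    civ_flux = if (length(civ_lab))
      unname(spec$true_state_fluxes[civ_lab]) else NA_real_,
    cytc_efficiency = spec$cytc_damage,
    nonsteady = spec$nonsteady)

  list(trace = trace, marks = all_marks, chb_marks = chb_marks,
       truth = truth)
}

#' Simulate a cohort of runs with between-sample variability
#'
#' Draws one lognormal scale factor per sample (unit mean, coefficient of
#' variation \code{between_sample_cv}) and applies it to all mitochondrial
#' state fluxes of the base specification. Scaling every rate of a sample by
#' a common factor preserves all true within-sample ratios (L/P, additivity,
#' efficiencies) exactly while reproducing the dominant source of real
#' between-sample spread, the amount of mitochondrial material in the
#' chamber. The chemical background, an instrument property, is not scaled.
#'
#' @param n_samples number of samples (>= 2).
#' @param between_sample_cv lognormal coefficient of variation (>= 0).
#' @param base_spec a \code{\link{simulationSpec}}.
#' @param seed root seed; per-sample child seeds are derived
#'   deterministically.
#' @return list with \code{runs} (per-sample \code{\link{simulateRun}}
#'   results), \code{scales}, and \code{true_ratios}: the per-sample true
#'   corrected L/P, additivity index and E-L coupling efficiency implied by
#'   the base fluxes (identical across samples by construction).
#' @export
simulateCohort <- function(n_samples, between_sample_cv, base_spec,
                           seed = 1L) {
  stopifnot(n_samples >= 2, between_sample_cv >= 0)
  set.seed(seed)
  sdlog <- sqrt(log(1 + between_sample_cv^2))
  scales <- if (between_sample_cv > 0)
    stats::rlnorm(n_samples, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else rep(1, n_samples)

  proto <- base_spec$protocol
  st <- proto@steps
  scale_steps <- st$label[st$coupling_state != "chb"]

  runs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    fx <- base_spec$true_state_fluxes
    fx[scale_steps] <- fx[scale_steps] * scales[i]
    sp <- base_spec
    sp$true_state_fluxes <- fx
    sp$seed <- as.integer((seed * 1009L + i) %% .Machine$integer.max)
    runs[[i]] <- simulateRun(sp)
  }

  fx0 <- base_spec$true_state_fluxes
  rox_lab <- st$label[st$coupling_state == "rox"]
  rox <- if (length(rox_lab)) unname(fx0[rox_lab]) else 0
  cval <- function(lab) unname(fx0[lab]) - rox
  ratios <- list()
  if (all(c("1PM", "2c") %in% st$label))
    ratios$L_over_P <- cval("1PM") / cval("2c")
  if (all(c("1PM", "3U") %in% st$label))
    ratios$el_eff <- (cval("3U") - cval("1PM")) / cval("3U")
  rot <- intersect(c("7Rot", "6Rot"), st$label)
  if (length(rot) == 1 && all(c("4G", "5S") %in% st$label))
    ratios$additivity <-
      additivityIndex(cval("4G"), cval(rot), cval("5S"))$A

  list(runs = runs, scales = scales, true_ratios = ratios)
}
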
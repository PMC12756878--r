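#' @include accessors.R
NULL

#' Instrumental background calibration
#'
#' The oxygraph's own oxygen consumption/backdiffusion is modelled as linear
#' in oxygen concentration, \code{a0 + b0 * C}, and subtracted from the
#' measured flux. The defaults (0, 0) disable the correction.
#'
#' @param a0 background flux at zero O2, pmol s^-1 mL^-1.
#' @param b0 O2 dependence, pmol s^-1 mL^-1 per uM.
#' @return named numeric vector \code{c(a0, b0)}.
#' @export
backgroundCalibration <- function(a0 = 0, b0 = 0) {
  stopifnot(is.finite(a0), is.finite(b0))
  c(a0 = as.numeric(a0), b0 = as.numeric(b0))
}

#' Detect measurement-interruption intervals
#'
#' Collects the intervals during which flux must not be read from the trace:
#' declared open-chamber intervals, inferred reoxygenations (a sustained O2
#' rise, which a closed chamber with respiring sample cannot produce), and
#' spike-exclusion windows around titration events.
#'
#' @param trace an \linkS4class{OxygraphTrace}.
#' @param detect_reox infer undeclared reoxygenation intervals.
#' @param min_rise_uM total O2 rise for a run of rising samples to count as a
#'   reoxygenation.
#' @param spike_pre_s,spike_post_s exclusion window around each titration
#'   event, seconds before and after.
#' @return list with elements \code{open_intervals} (declared plus inferred,
#'   two-column matrix) and \code{spike_windows} (two-column matrix).
#' @export
detectIntervals <- function(trace, detect_reox = TRUE, min_rise_uM = 5,
                            spike_pre_s = 5, spike_post_s = 20) {
  stopifnot(is(trace, "OxygraphTrace"))
  open_iv <- trace@open_intervals
  t <- trace@time_s
  C <- trace@o2_uM

  if (detect_reox && length(t) > 2) {
    ## smooth over ~10 s to keep sample noise from breaking rising runs
    dt <- stats::median(diff(t))
    k <- max(1L, ceiling(5 / dt))
    n <- length(C)
    ahead <- C[pmin(seq_len(n) + k, n)]
    rising <- (ahead - C) > 0.5
    r <- rle(rising)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- min(ends[j] + k, n)
      if (C[i1] - C[i0] >= min_rise_uM) {
        iv <- c(t[i0], t[i1])
        covered <- nrow(open_iv) > 0 &&
          any(open_iv[, 1] <= iv[1] & open_iv[, 2] >= iv[2])
        if (!covered) open_iv <- rbind(open_iv, iv)
      }
    }
  }
  if (nrow(open_iv) > 1) {
    open_iv <- open_iv[order(open_iv[, 1]), , drop = FALSE]
    merged <- open_iv[1, , drop = FALSE]
    for (i in 2:nrow(open_iv)) {
      last <- nrow(merged)
      if (open_iv[i, 1] <= merged[last, 2])
        merged[last, 2] <- max(merged[last, 2], open_iv[i, 2])
      else merged <- rbind(merged, open_iv[i, ])
    }
    open_iv <- merged
  }
  rownames(open_iv) <- NULL

  ev <- trace@events
  titr <- ev[!ev$label %in% c("open", "close"), , drop = FALSE]
  spikes <- if (nrow(titr) > 0)
    cbind(titr$time_s - spike_pre_s, titr$time_s + spike_post_s)
  else matrix(numeric(0), ncol = 2)
  list(open_intervals = open_iv, spike_windows = spikes)
}

.inIntervals <- function(t, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv)))
    hit <- hit | (t >= iv[i, 1] & t < iv[i, 2])
  hit
}

#' Estimate volumetric oxygen flux from a trace
#'
#' At each sample the local least-squares slope of the oxygen concentration
#' (uM/s) is computed over a centered window restricted to the surrounding
#' uninterrupted closed-chamber segment, then converted to flux:
#' \code{J_V = -slope * 1000 - (a0 + b0 * C)} in pmol s^-1 mL^-1 (the factor
#' 1000 converts nmol mL^-1 s^-1 to pmol s^-1 mL^-1). Samples inside open
#' intervals or spike windows, or closer than half a window to a segment
#' edge, are masked.
#'
#' @param trace an \linkS4class{OxygraphTrace}.
#' @param calib a \code{\link{backgroundCalibration}}.
#' @param window_s slope window, seconds; must span at least 3 samples.
#' @param intervals result of \code{\link{detectIntervals}}; computed from the
#'   trace's declared intervals and events when NULL.
#' @param detect_reox passed to \code{\link{detectIntervals}} when
#'   \code{intervals} is NULL.
#' @return A \linkS4class{FluxSeries}.
#' @export
estimateFluxSeries <- function(trace, calib = backgroundCalibration(),
                               window_s = 40, intervals = NULL,
                               detect_reox = FALSE) {
  stopifnot(is(trace, "OxygraphTrace"))
  t <- trace@time_s
  C <- trace@o2_uM
  n <- length(t)
  if (n >= 3 && window_s < 2 * stats::median(diff(t)))
    stop("window_s must span at least 3 samples")
  if (is.null(intervals))
    intervals <- detectIntervals(trace, detect_reox = detect_reox)

  usable <- !.inIntervals(t, intervals$open_intervals) &
            !.inIntervals(t, intervals$spike_windows)

  J <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  half <- window_s / 2

  r <- rle(usable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_len_max <- 0
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (i1 - i0 + 1 < 3) next
    ts <- t[i0:i1] - t[i0]
    ys <- C[i0:i1]
    seg_len_max <- max(seg_len_max, ts[length(ts)])
    Sx <- cumsum(ts); Sy <- cumsum(ys)
    Sxx <- cumsum(ts^2); Sxy <- cumsum(ts * ys)
    lo <- findInterval(ts - half, ts, left.open = TRUE) + 1L
    hi <- findInterval(ts + half, ts)
    for (k in seq_along(ts)) {
      if (ts[k] - half < 0 || ts[k] + half > ts[length(ts)]) next
      a <- lo[k]; b <- hi[k]
      m <- b - a + 1L
      if (m < 3L) next
      sx <- Sx[b] - if (a > 1) Sx[a - 1] else 0
      sy <- Sy[b] - if (a > 1) Sy[a - 1] else 0
      sxx <- Sxx[b] - if (a > 1) Sxx[a - 1] else 0
      sxy <- Sxy[b] - if (a > 1) Sxy[a - 1] else 0
      den <- m * sxx - sx^2
      if (den <= 0) next
      slope <- (m * sxy - sx * sy) / den
      i <- i0 + k - 1L
      J[i] <- -slope * 1000 - (calib[["a0"]] + calib[["b0"]] * C[i])
      valid[i] <- TRUE
    }
  }
  if (!any(valid)) {
    if (seg_len_max > 0 && window_s > seg_len_max)
      stop("slope window (", window_s,
           " s) is larger than every closed-chamber segment")
    stop("flux series is fully masked")
  }
  new("FluxSeries", run_id = trace@run_id, time_s = t, J_V = J, o2_uM = C,
      valid = valid, window_s = as.numeric(window_s),
      background = c(calib[["a0"]], calib[["b0"]]))
}

#' Read a state's rate from a flux series over a mark window
#'
#' Aggregates the valid flux samples inside \code{[t_start_s, t_end_s)} and
#' records the mean oxygen concentration over the mark (required to match O2
#' levels in the Complex IV assay).
#'
#' @param flux a \linkS4class{FluxSeries}.
#' @param mark one-row data.frame (or list) with \code{t_start_s},
#'   \code{t_end_s}.
#' @param aggregator \code{"mean"} (default; SD reported) or \code{"median"}
#'   for spike-contaminated marks.
#' @return list with \code{value}, \code{sd}, \code{n}, \code{o2_mean}.
#' @export
markRate <- function(flux, mark, aggregator = c("mean", "median")) {
  stopifnot(is(flux, "FluxSeries"))
  aggregator <- match.arg(aggregator)
  sel <- flux@time_s >= mark$t_start_s & flux@time_s < mark$t_end_s &
         flux@valid
  if (sum(sel) < 3)
    stop("mark too narrow or fully masked",
         if (!is.null(mark$label)) paste0(": ", mark$label) else "")
  x <- flux@J_V[sel]
  list(value = if (aggregator == "mean") mean(x) else stats::median(x),
       sd = stats::sd(x),
       n = sum(sel),
       o2_mean = mean(flux@o2_uM[sel]))
}

#' Normalize a volumetric rate to a sample-specific rate
#'
#' Wet-mass or protein basis divides by the mg/mL concentration, giving
#' pmol s^-1 mg^-1; cell-count basis divides by cells/mL and rescales to
#' amol s^-1 per cell (1 pmol = 1e6 amol).
#'
#' @param rate volumetric rate(s), pmol s^-1 mL^-1.
#' @param basis one of \code{"wet_mass_mg_per_mL"}, \code{"protein_mg_per_mL"},
#'   \code{"cell_count_per_mL"}.
#' @param value concentration on that basis; must be positive.
#' @return list with \code{rate} (numeric, same length as input) and
#'   \code{units}.
#' @export
normalizeRate <- function(rate, basis, value) {
  if (!basis %in% setdiff(.NORM_BASES, "none"))
    stop("unknown normalization basis: ", basis)
  if (!is.finite(value) || value <= 0)
    stop("normalization value must be > 0")
  if (basis == "cell_count_per_mL")
    list(rate = rate / value * 1e6, units = "amol.s-1.x-1")
  else
    list(rate = rate / value, units = "pmol.s-1.mg-1")
}

#' Normalize every rate column of a state-rate table
#'
#' @param table a \linkS4class{StateRateTable} in volumetric units.
#' @param basis,value normalization basis and value; default from the table's
#'   own metadata.
#' @return The table with rate columns divided by the basis concentration and
#'   units updated.
#' @export
normalizeStateTable <- function(table, basis = table@norm_basis,
                                value = table@norm_value) {
  stopifnot(is(table, "StateRateTable"))
  if (table@units != "pmol.s-1.mL-1")
    stop("table is already normalized (units ", table@units, ")")
  nr <- normalizeRate(1, basis, value)
  f <- nr$rate
  rows <- table@rows
  for (col in c("rate_total", "rate_corrected", "sd"))
    rows[[col]] <- rows[[col]] * f
  initialize(table, rows = rows, units = nr$units, norm_basis = basis,
             norm_value = value)
}
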
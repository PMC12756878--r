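#' @include AllGenerics.R
NULL

## ---- OxygraphTrace ----

#' Construct an OxygraphTrace
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param o2_uM oxygen concentration, micromolar.
#' @param run_id run identifier.
#' @param chamber_volume_mL chamber volume in mL.
#' @param temperature_C assay temperature.
#' @param norm_basis one of \code{"wet_mass_mg_per_mL"},
#'   \code{"protein_mg_per_mL"}, \code{"cell_count_per_mL"}, \code{"none"}.
#' @param norm_value sample concentration on that basis (> 0).
#' @param events data.frame with columns \code{time_s}, \code{label}.
#' @param open_intervals two-column matrix of \code{[t0, t1)} open-chamber
#'   intervals.
#' @return A validated \linkS4class{OxygraphTrace}.
#' @export
oxygraphTrace <- function(time_s, o2_uM, run_id = "run",
                          chamber_volume_mL = 2, temperature_C = 37,
                          norm_basis = "none", norm_value = 1,
                          events = NULL, open_intervals = NULL) {
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), label = character(0),
                         stringsAsFactors = FALSE)
  if (is.null(open_intervals))
    open_intervals <- matrix(numeric(0), ncol = 2)
  open_intervals <- matrix(as.numeric(open_intervals), ncol = 2)
  new("OxygraphTrace",
      run_id = as.character(run_id),
      time_s = as.numeric(time_s), o2_uM = as.numeric(o2_uM),
      chamber_volume_mL = as.numeric(chamber_volume_mL),
      temperature_C = as.numeric(temperature_C),
      norm_basis = norm_basis, norm_value = as.numeric(norm_value),
      events = events, open_intervals = open_intervals)
}

#' @describeIn oxygraphTrace run identifier
#' @param x an object.
#' @export
setMethod("runId", "OxygraphTrace", function(x) x@run_id)
#' @export
setMethod("timeS", "OxygraphTrace", function(x) x@time_s)
#' @export
setMethod("o2Conc", "OxygraphTrace", function(x) x@o2_uM)
#' @export
setMethod("events", "OxygraphTrace", function(x) x@events)
#' @export
setMethod("openIntervals", "OxygraphTrace", function(x) x@open_intervals)
#' @export
setMethod("normalization", "OxygraphTrace",
          function(x) list(basis = x@norm_basis, value = x@norm_value))
#' @export
setMethod("length", "OxygraphTrace", function(x) length(x@time_s))

setMethod("show", "OxygraphTrace", function(object) {
  cat(sprintf("OxygraphTrace '%s': %d samples, %.1f-%.1f s, O2 %.1f-%.1f uM\n",
              object@run_id, length(object@time_s),
              min(object@time_s), max(object@time_s),
              min(object@o2_uM), max(object@o2_uM)))
  cat(sprintf("  chamber %.2g mL at %.1f C; normalization: %s",
              object@chamber_volume_mL, object@temperature_C,
              object@norm_basis))
  if (object@norm_basis != "none")
    cat(sprintf(" = %g", object@norm_value))
  cat(sprintf("\n  %d events, %d open interval(s)\n",
              nrow(object@events), nrow(object@open_intervals)))
})

## ---- FluxSeries ----

#' @export
setMethod("runId", "FluxSeries", function(x) x@run_id)
#' @export
setMethod("timeS", "FluxSeries", function(x) x@time_s)
#' @export
setMethod("o2Conc", "FluxSeries", function(x) x@o2_uM)
#' @export
setMethod("fluxPerVolume", "FluxSeries", function(x) x@J_V)
#' @export
setMethod("validMask", "FluxSeries", function(x) x@valid)
#' @export
setMethod("length", "FluxSeries", function(x) length(x@time_s))

setMethod("show", "FluxSeries", function(object) {
  ok <- object@valid
  cat(sprintf("FluxSeries '%s': %d samples (%d valid), window %g s\n",
              object@run_id, length(ok), sum(ok), object@window_s))
  if (any(ok))
    cat(sprintf("  J_V range %.2f to %.2f pmol s-1 mL-1\n",
                min(object@J_V[ok]), max(object@J_V[ok])))
})

## ---- ProtocolDefinition ----

#' @export
setMethod("protocolId", "ProtocolDefinition", function(x) x@protocol_id)
#' @export
setMethod("protocolSteps", "ProtocolDefinition", function(x) x@steps)
#' @export
setMethod("referenceState", "ProtocolDefinition", function(x) x@reference_state)
#' @export
setMethod("length", "ProtocolDefinition", function(x) nrow(x@steps))

setMethod("show", "ProtocolDefinition", function(object) {
  cat(sprintf("ProtocolDefinition '%s': %d steps, reference state '%s'\n",
              object@protocol_id, nrow(object@steps),
              object@reference_state))
  cat("  ", paste(object@steps$label, collapse = " -> "), "\n", sep = "")
})

## ---- StateRateTable ----

#' @export
setMethod("runId", "StateRateTable", function(x) x@run_id)
#' @export
setMethod("protocolId", "StateRateTable", function(x) x@protocol_id)
#' @export
setMethod("stateRates", "StateRateTable", function(x) x@rows)
#' @export
setMethod("rateUnits", "StateRateTable", function(x) x@units)
#' @export
setMethod("isRoxCorrected", "StateRateTable", function(x) x@rox_corrected)
#' @export
setMethod("normalization", "StateRateTable",
          function(x) list(basis = x@norm_basis, value = x@norm_value))

setMethod("show", "StateRateTable", function(object) {
  cat(sprintf("StateRateTable '%s' (%s): %d steps, units %s%s\n",
              object@run_id, object@protocol_id, nrow(object@rows),
              object@units,
              if (object@rox_corrected) ", rox-corrected" else ""))
  print(object@rows[, c("step", "pathway_state", "coupling_state",
                        "rate_total", "rate_corrected")],
        row.names = FALSE, digits = 4)
})

## ---- InvertedRegressionFit ----

#' @export
setMethod("meanSlope", "InvertedRegressionFit", function(x) x@b_bar)
#' @export
setMethod("meanIntercept", "InvertedRegressionFit", function(x) x@a_bar)

setMethod("show", "InvertedRegressionFit", function(object) {
  cat(sprintf("InvertedRegressionFit (n = %d, r = %.3f)\n", object@n,
              object@r))
  cat(sprintf("  y-on-x: b_Y = %.4f, a_Y = %.4f\n", object@b_Y, object@a_Y))
  cat(sprintf("  x-on-y: b_X = %.4f, a_X = %.4f\n", object@b_X, object@a_X))
  cat(sprintf("  mean:   b   = %.4f, a   = %.4f\n", object@b_bar,
              object@a_bar))
})

## Extract a named vector of rates (corrected when available) from a table.
## Internal convenience used across the derived-quantity functions.
.rateVector <- function(table, corrected = TRUE) {
  rows <- table@rows
  v <- if (corrected && table@rox_corrected) {
    ifelse(is.na(rows$rate_corrected), rows$rate_total, rows$rate_corrected)
  } else rows$rate_total
  names(v) <- rows$step
  v
}

#' Look up the rate of one protocol step
#'
#' @param table a \linkS4class{StateRateTable}.
#' @param step step label.
#' @param corrected use the rox-corrected rate when available.
#' @return numeric(1); NA if the step is absent.
#' @export
stepRate <- function(table, step, corrected = TRUE) {
  stopifnot(is(table, "StateRateTable"))
  v <- .rateVector(table, corrected)
  if (!step %in% names(v)) return(NA_real_)
  unname(v[step])
}
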
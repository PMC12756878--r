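#' @import methods
NULL

## Coupling-control vocabulary: the seven rate categories a SUIT step can
## report. R/L/P/E are mitochondrial coupling states (rox-correctable);
## rox/ren/chb are auxiliary baseline rates; CIV is the Complex IV assay.
.COUPLING_STATES <- c("R", "L", "P", "E", "rox", "ren", "chb", "CIV")
.CORRECTABLE_STATES <- c("R", "L", "P", "E")
.NORM_BASES <- c("wet_mass_mg_per_mL", "protein_mg_per_mL",
                 "cell_count_per_mL", "none")

#' OxygraphTrace: a closed-chamber oxygen concentration time series
#'
#' Container for one oxygraph run: oxygen concentration (micromolar, equal to
#' nmol/mL) sampled over time in a stirred chamber, together with titration
#' events, declared open-chamber (reoxygenation) intervals and the metadata
#' needed to normalize volumetric flux to a specific rate.
#'
#' @slot run_id character(1), run identifier.
#' @slot time_s numeric, strictly increasing sample times in seconds.
#' @slot o2_uM numeric, oxygen concentration in micromolar, non-negative.
#' @slot chamber_volume_mL numeric(1), chamber volume in mL.
#' @slot temperature_C numeric(1), assay temperature.
#' @slot norm_basis character(1), one of \code{"wet_mass_mg_per_mL"},
#'   \code{"protein_mg_per_mL"}, \code{"cell_count_per_mL"} or \code{"none"}.
#' @slot norm_value numeric(1), concentration of sample in the chamber on the
#'   stated basis; must be positive when a basis is declared.
#' @slot events data.frame with columns \code{time_s}, \code{label}:
#'   titrations and chamber open/close annotations.
#' @slot open_intervals two-column numeric matrix of half-open intervals
#'   \code{[t0, t1)} during which the chamber was open and flux is not
#'   measured.
#' @exportClass OxygraphTrace
setClass("OxygraphTrace",
  representation(
    run_id = "character",
    time_s = "numeric",
    o2_uM = "numeric",
    chamber_volume_mL = "numeric",
    temperature_C = "numeric",
    norm_basis = "character",
    norm_value = "numeric",
    events = "data.frame",
    open_intervals = "matrix"
  ),
  prototype(
    run_id = "run",
    chamber_volume_mL = 2,
    temperature_C = 37,
    norm_basis = "none",
    norm_value = 1,
    events = data.frame(time_s = numeric(0), label = character(0),
                        stringsAsFactors = FALSE),
    open_intervals = matrix(numeric(0), ncol = 2)
  )
)

setValidity("OxygraphTrace", function(object) {
  msgs <- character(0)
  n <- length(object@time_s)
  if (length(object@o2_uM) != n)
    msgs <- c(msgs, "time_s and o2_uM must have equal length")
  if (n >= 2) {
    d <- diff(object@time_s)
    if (any(d <= 0)) {
      bad <- which(d <= 0)[1] + 1L
      msgs <- c(msgs, sprintf(
        "time_s must be strictly increasing; first violation at row %d (t = %g)",
        bad, object@time_s[bad]))
    }
  }
  if (any(object@o2_uM < 0, na.rm = TRUE))
    msgs <- c(msgs, "o2_uM must be non-negative")
  if (!object@norm_basis %in% .NORM_BASES)
    msgs <- c(msgs, sprintf("norm_basis must be one of: %s",
                            paste(.NORM_BASES, collapse = ", ")))
  if (object@norm_basis != "none" && object@norm_value <= 0)
    msgs <- c(msgs, "norm_value must be > 0")
  if (nrow(object@events) > 0 && n > 0) {
    rng <- range(object@time_s)
    off <- object@events$time_s < rng[1] | object@events$time_s > rng[2]
    if (any(off))
      msgs <- c(msgs, sprintf("event '%s' at t = %g lies outside the trace",
                              object@events$label[which(off)[1]],
                              object@events$time_s[which(off)[1]]))
  }
  oi <- object@open_intervals
  if (ncol(oi) != 2)
    msgs <- c(msgs, "open_intervals must have two columns")
  else if (nrow(oi) > 0) {
    if (any(oi[, 2] <= oi[, 1]))
      msgs <- c(msgs, "open intervals must satisfy t0 < t1")
    if (nrow(oi) > 1) {
      o <- oi[order(oi[, 1]), , drop = FALSE]
      if (any(o[-1, 1] < o[-nrow(o), 2]))
        msgs <- c(msgs, "open intervals must be pairwise disjoint")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FluxSeries: volumetric oxygen flux derived from a trace
#'
#' Output of \code{\link{estimateFluxSeries}}: negative local slope of the
#' oxygen concentration converted to pmol O2 per second per mL of chamber
#' volume and corrected for instrumental background. Samples inside open
#' intervals, spike-exclusion windows, or closer than half a slope window to
#' a segment edge are masked (\code{valid = FALSE}, \code{J_V = NA}).
#'
#' @slot run_id character(1).
#' @slot time_s numeric, sample times (same as the source trace).
#' @slot J_V numeric, O2 flux per volume in pmol s^-1 mL^-1; NA where masked.
#' @slot o2_uM numeric, source oxygen concentration (for O2-matched assays).
#' @slot valid logical mask.
#' @slot window_s numeric(1), slope window used.
#' @slot background numeric(2), instrumental background (a0, b0) applied.
#' @exportClass FluxSeries
setClass("FluxSeries",
  representation(
    run_id = "character",
    time_s = "numeric",
    J_V = "numeric",
    o2_uM = "numeric",
    valid = "logical",
    window_s = "numeric",
    background = "numeric"
  )
)

setValidity("FluxSeries", function(object) {
  msgs <- character(0)
  n <- length(object@time_s)
  if (length(object@J_V) != n || length(object@valid) != n ||
      length(object@o2_uM) != n)
    msgs <- c(msgs, "time_s, J_V, o2_uM and valid must have equal length")
  if (any(!is.na(object@J_V[!object@valid])))
    msgs <- c(msgs, "J_V must be NA wherever valid is FALSE")
  if (length(msgs)) msgs else TRUE
})

#' ProtocolDefinition: a SUIT titration sequence as a state machine
#'
#' Ordered titration steps of a substrate-uncoupler-inhibitor protocol. Each
#' step names its titrant, the ET-pathway state it establishes (N, S, F, Gp
#' and combinations, or CIV) and its coupling-control category. Preparatory
#' steps carry a "+" prefix and are first-class so that their rates remain
#' available to corrections (e.g. J(+M.1) for the FAO subtraction).
#'
#' @slot protocol_id character(1), e.g. "RP1".
#' @slot steps data.frame with columns \code{label}, \code{titrant},
#'   \code{target_concentration}, \code{pathway_state}, \code{coupling_state},
#'   \code{substrate_annotation}, \code{multi_titration}, \code{role}.
#' @slot reference_state character(1), step label whose rate is the common
#'   reference for flux control ratios.
#' @exportClass ProtocolDefinition
setClass("ProtocolDefinition",
  representation(
    protocol_id = "character",
    steps = "data.frame",
    reference_state = "character"
  )
)

setValidity("ProtocolDefinition", function(object) {
  msgs <- character(0)
  st <- object@steps
  need <- c("label", "titrant", "target_concentration", "pathway_state",
            "coupling_state", "substrate_annotation", "multi_titration",
            "role")
  if (!all(need %in% names(st)))
    msgs <- c(msgs, sprintf("steps must have columns: %s",
                            paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(st$label))
      msgs <- c(msgs, "step labels must be unique")
    if (!all(st$coupling_state %in% .COUPLING_STATES))
      msgs <- c(msgs, sprintf("coupling_state entries must be in {%s}",
                              paste(.COUPLING_STATES, collapse = ", ")))
    if (!object@reference_state %in% st$label)
      msgs <- c(msgs, sprintf("reference_state '%s' is not a step label",
                              object@reference_state))
    bad_multi <- st$multi_titration & st$titrant != "CCCP"
    if (any(bad_multi))
      msgs <- c(msgs, "multi_titration is reserved for uncoupler (CCCP) steps")
  }
  if (length(msgs)) msgs else TRUE
})

#' StateRateTable: per-run mapping of protocol steps to measured rates
#'
#' One row per marked protocol step with the total rate, the rox-corrected
#' rate (after \code{\link{baselineCorrectRox}}), dispersion, and the mean
#' oxygen concentration over the mark (needed for O2-matched assays).
#'
#' @slot run_id character(1).
#' @slot protocol_id character(1).
#' @slot rows data.frame with columns \code{step}, \code{pathway_state},
#'   \code{coupling_state}, \code{role}, \code{rate_total},
#'   \code{rate_corrected}, \code{sd}, \code{n}, \code{o2_mean}, \code{flags}.
#' @slot units character(1), units of the rate columns.
#' @slot norm_basis character(1), normalization basis applied (or "none").
#' @slot norm_value numeric(1).
#' @slot rox_corrected logical(1), whether \code{rate_corrected} is populated.
#' @slot provenance list of parameters used to derive the table.
#' @exportClass StateRateTable
setClass("StateRateTable",
  representation(
    run_id = "character",
    protocol_id = "character",
    rows = "data.frame",
    units = "character",
    norm_basis = "character",
    norm_value = "numeric",
    rox_corrected = "logical",
    provenance = "list"
  ),
  prototype(
    units = "pmol.s-1.mL-1",
    norm_basis = "none",
    norm_value = 1,
    rox_corrected = FALSE,
    provenance = list()
  )
)

setValidity("StateRateTable", function(object) {
  msgs <- character(0)
  need <- c("step", "pathway_state", "coupling_state", "role",
            "rate_total", "rate_corrected", "sd", "n", "o2_mean", "flags")
  if (!all(need %in% names(object@rows)))
    msgs <- c(msgs, sprintf("rows must have columns: %s",
                            paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@rows$step))
      msgs <- c(msgs, "at most one row per step")
    if (!all(object@rows$coupling_state %in% .COUPLING_STATES))
      msgs <- c(msgs, "coupling_state entries outside the defined vocabulary")
    if (!object@rox_corrected && any(!is.na(object@rows$rate_corrected)))
      msgs <- c(msgs, "rate_corrected must be NA before baseline correction")
  }
  if (length(msgs)) msgs else TRUE
})

#' InvertedRegressionFit: symmetric two-fit regression summary
#'
#' Ordinary least squares of y on x and of x on y, the latter re-expressed in
#' y-on-x form (slope 1/beta_X, intercept -alpha_X/beta_X), averaged into the
#' mean slope and intercept used to compare technical repeats against the
#' identity line without privileging either variable.
#'
#' @slot b_Y,a_Y numeric(1), slope/intercept of the y-on-x fit.
#' @slot b_X,a_X numeric(1), x-on-y fit re-expressed in y-on-x form.
#' @slot b_bar,a_bar numeric(1), means of the two slopes / intercepts.
#' @slot n integer(1), number of pairs.
#' @slot r numeric(1), Pearson correlation.
#' @exportClass InvertedRegressionFit
setClass("InvertedRegressionFit",
  representation(
    b_Y = "numeric", a_Y = "numeric",
    b_X = "numeric", a_X = "numeric",
    b_bar = "numeric", a_bar = "numeric",
    n = "integer", r = "numeric"
  )
)

setValidity("InvertedRegressionFit", function(object) {
  if (object@n < 3L) "n must be >= 3" else TRUE
})
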
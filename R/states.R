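#' @include flux.R protocols.R
NULL

#' Map marked rates onto the protocol's named states
#'
#' Produces one row per marked protocol step. For a multi-titration
#' (uncoupler) step the rate is the maximum over that step's titration marks
#' — the optimum uncoupler concentration — with ties broken toward the
#' earliest mark (the lower concentration, minimizing inhibition risk).
#' Preparatory steps are retained so their rates remain available to the
#' corrections (e.g. the fatty-acid oxidation subtraction).
#'
#' @param marks validated mark table (see \code{\link{readMarks}} /
#'   \code{\link{validateMarks}}).
#' @param protocol a \linkS4class{ProtocolDefinition}.
#' @param flux a \linkS4class{FluxSeries} for the same run.
#' @param aggregator passed to \code{\link{markRate}}.
#' @param norm_basis,norm_value normalization metadata recorded (not yet
#'   applied) in the table.
#' @return A \linkS4class{StateRateTable} in volumetric units.
#' @export
assignStates <- function(marks, protocol, flux,
                         aggregator = c("mean", "median"),
                         norm_basis = "none", norm_value = 1) {
  stopifnot(is(protocol, "ProtocolDefinition"), is(flux, "FluxSeries"))
  aggregator <- match.arg(aggregator)
  if (is.null(marks$step))
    marks <- validateMarks(marks, protocol)
  st <- protocol@steps
  rows <- NULL
  for (i in seq_len(nrow(st))) {
    lab <- st$label[i]
    mk <- marks[!is.na(marks$step) & marks$step == lab &
                marks$role != "artifact-exclusion", , drop = FALSE]
    if (nrow(mk) == 0L) {
      warning("no mark for step '", lab, "'; row absent")
      next
    }
    if (nrow(mk) > 1L && !st$multi_titration[i])
      stop("duplicate marks for step '", lab, "'")
    rates <- lapply(seq_len(nrow(mk)),
                    function(j) markRate(flux, mk[j, ], aggregator))
    vals <- vapply(rates, `[[`, numeric(1), "value")
    pick <- which.max(vals)  # which.max returns the first (earliest) maximum
    r <- rates[[pick]]
    rows <- rbind(rows, data.frame(
      step = lab,
      pathway_state = st$pathway_state[i],
      coupling_state = st$coupling_state[i],
      role = st$role[i],
      rate_total = r$value,
      rate_corrected = NA_real_,
      sd = r$sd,
      n = as.integer(r$n),
      o2_mean = r$o2_mean,
      flags = if (r$value < 0) "negative_total" else "",
      stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    stop("no marks matched any protocol step")
  new("StateRateTable",
      run_id = flux@run_id, protocol_id = protocol@protocol_id,
      rows = rows, units = "pmol.s-1.mL-1",
      norm_basis = norm_basis, norm_value = norm_value,
      rox_corrected = FALSE,
      provenance = list(aggregator = aggregator,
                        slope_window_s = flux@window_s,
                        background = as.list(stats::setNames(
                          flux@background, c("a0", "b0")))))
}

## Comparable-state catalogue: how a state reached in one protocol matches a
## state in the other. "identical" states are reached by the same titrations
## (usable as technical repeats); "harmonized" states share the
## substrate-inhibitor-coupling condition but arrive by different titration
## orders; the pre/post-octanoylcarnitine OXPHOS pair is comparable only when
## the fatty-acid pathway contributes nothing.
.comparableCatalogue <- list(
  list(state = "routine",  class = "identical",
       match1 = list(coupling = "R"),   match2 = list(coupling = "R")),
  list(state = "ren",      class = "identical",
       match1 = list(coupling = "ren"), match2 = list(coupling = "ren")),
  list(state = "SGp_E",    class = "harmonized",
       match1 = list(pathway = "SGp_E"), match2 = list(pathway = "SGp_E")),
  list(state = "rox",      class = "harmonized",
       match1 = list(coupling = "rox"), match2 = list(coupling = "rox")),
  list(state = "CIV_E",    class = "harmonized",
       match1 = list(coupling = "CIV"), match2 = list(coupling = "CIV")),
  list(state = "N{PM}[c]_P~FN{PM}_P", class = "possibly_comparable",
       match1 = list(pathway = "N{PM}[c]_P"),
       match2 = list(pathway = "FN{PM}_P"))
)

.matchRow <- function(rows, m) {
  sel <- rep(TRUE, nrow(rows))
  if (!is.null(m$coupling)) sel <- sel & rows$coupling_state == m$coupling
  if (!is.null(m$pathway)) sel <- sel & rows$pathway_state == m$pathway
  ## 'ren' appears on several preparatory steps in RP2 (+Dig, +D); the
  ## digitonin step is the one shared with RP1
  if (!is.null(m$coupling) && m$coupling == "ren" && sum(sel) > 1)
    sel <- sel & rows$step == "+Dig"
  which(sel)
}

#' Pair comparable states of two parallel protocol runs
#'
#' For a sample assayed with both reference protocols, returns the rate pairs
#' in comparable states: \emph{identical} states (routine respiration of
#' living cells, residual endogenous respiration) reached by the same
#' titrations, \emph{harmonized} states (SGp-pathway ET capacity, residual
#' oxygen consumption, Complex IV activity) reached by different titration
#' sequences, and the \emph{possibly comparable} OXPHOS pair (pyruvate+malate
#' with cytochrome c vs. the same after octanoylcarnitine), comparable only
#' under zero additivity of the fatty-acid pathway.
#'
#' @param rp1,rp2 \linkS4class{StateRateTable}s of the same sample.
#' @param corrected use rox-corrected rates when available.
#' @return data.frame with columns \code{state}, \code{class},
#'   \code{rate_rp1}, \code{rate_rp2}.
#' @export
comparableStatePairs <- function(rp1, rp2, corrected = TRUE) {
  stopifnot(is(rp1, "StateRateTable"), is(rp2, "StateRateTable"))
  v1 <- .rateVector(rp1, corrected)
  v2 <- .rateVector(rp2, corrected)
  out <- NULL
  for (entry in .comparableCatalogue) {
    i1 <- .matchRow(rp1@rows, entry$match1)
    i2 <- .matchRow(rp2@rows, entry$match2)
    if (length(i1) == 0L || length(i2) == 0L) {
      warning("comparable state '", entry$state,
              "' missing in one run; pair dropped")
      next
    }
    out <- rbind(out, data.frame(
      state = entry$state, class = entry$class,
      rate_rp1 = unname(v1[i1[1]]), rate_rp2 = unname(v2[i2[1]]),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(state = character(0), class = character(0),
                      rate_rp1 = numeric(0), rate_rp2 = numeric(0),
                      stringsAsFactors = FALSE)
  out
}
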
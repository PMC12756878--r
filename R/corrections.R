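#' @include states.R
NULL

#' Baseline-correct mitochondrial rates for residual oxygen consumption
#'
#' Subtracts the residual oxygen consumption (rox, the flux remaining after
#' full inhibition of the electron transfer system) from every routine, leak,
#' OXPHOS and ET row, writing the result into \code{rate_corrected}. The rox,
#' ren, chb and Complex IV rows are left as totals. The operation is
#' idempotent: the corrected column is always recomputed from the totals.
#' Negative corrected rates are reported, not clamped, and flagged.
#'
#' @param table a \linkS4class{StateRateTable}.
#' @return The corrected table; if the rox row is absent the table is
#'   returned uncorrected with a \code{rox_missing} flag on every row.
#' @export
baselineCorrectRox <- function(table) {
  stopifnot(is(table, "StateRateTable"))
  rows <- table@rows
  rox_i <- which(rows$coupling_state == "rox")
  addFlag <- function(flags, f) ifelse(
    flags == "", f, ifelse(grepl(f, flags, fixed = TRUE), flags,
                           paste(flags, f, sep = ",")))
  if (length(rox_i) == 0L) {
    warning("rox row absent; rates left as totals")
    rows$flags <- addFlag(rows$flags, "rox_missing")
    return(initialize(table, rows = rows, rox_corrected = FALSE))
  }
  rox <- rows$rate_total[rox_i[1]]
  corr <- rows$coupling_state %in% .CORRECTABLE_STATES
  rows$rate_corrected <- NA_real_
  rows$rate_corrected[corr] <- rows$rate_total[corr] - rox
  neg <- corr & !is.na(rows$rate_corrected) & rows$rate_corrected < 0
  rows$flags[neg] <- addFlag(rows$flags[neg], "negative_corrected")
  prov <- table@provenance
  prov$rox <- rox
  initialize(table, rows = rows, rox_corrected = TRUE, provenance = prov)
}

#' Fatty-acid oxidation capacity by subtraction
#'
#' The F-pathway OXPHOS capacity is the octanoylcarnitine-driven flux (after
#' cytochrome c) minus the flux supported by low (0.1 mM) malate alone, which
#' removes the contribution of anaplerotic malate oxidation and endogenous
#' substrates: \code{F_P = J(1Oct[c]) - J(+M.1)}. Both rates must come from
#' the same run and be corrected consistently.
#'
#' @param J_oct_c flux after octanoylcarnitine + cytochrome c.
#' @param J_M01 flux after 0.1 mM malate, before octanoylcarnitine.
#' @return list with \code{F_P} and \code{flag} (\code{""} or
#'   \code{"no_detectable_F_capacity"} when the difference is negative).
#' @export
faoCapacity <- function(J_oct_c, J_M01) {
  stopifnot(is.finite(J_oct_c), is.finite(J_M01))
  F_P <- J_oct_c - J_M01
  list(F_P = F_P,
       flag = if (F_P < 0) "no_detectable_F_capacity" else "")
}

#' Cytochrome c control efficiency (outer-membrane integrity test)
#'
#' The relative stimulation of respiration by exogenous cytochrome c:
#' \code{(J_with_c - J_without_c) / J_with_c}. Stimulation indicates loss of
#' cytochrome c through a damaged mitochondrial outer membrane; efficiencies
#' above \code{damage_threshold} are flagged. Negative values (an inhibitory
#' artifact) are reported without a damage flag.
#'
#' @param J_without_c rate before cytochrome c addition.
#' @param J_with_c rate after cytochrome c addition; must be positive.
#' @param damage_threshold flag threshold, default 0.15.
#' @return list with \code{efficiency} and logical \code{damaged}.
#' @export
cytcControlEfficiency <- function(J_without_c, J_with_c,
                                  damage_threshold = 0.15) {
  if (!is.finite(J_with_c) || J_with_c <= 0)
    stop("c-stimulated rate must be positive")
  eff <- (J_with_c - J_without_c) / J_with_c
  list(efficiency = eff, damaged = eff > damage_threshold)
}

#' Calibrate the chemical background of the Complex IV assay
#'
#' After inhibition of Complex IV, the remaining oxygen consumption is the
#' autoxidation of ascorbate and TMPD, a linear function of oxygen
#' concentration above 50 uM. Fits \code{J_chb(C) = a_chb + b_chb * C} by
#' ordinary least squares over the admitted points; points below
#' \code{min_o2_uM} are excluded and reported.
#'
#' @param points data.frame (or list) with columns/elements \code{o2_uM} and
#'   \code{J} (azide-inhibited flux, pmol s^-1 mL^-1).
#' @param min_o2_uM admission threshold, default 50 uM.
#' @return list with \code{a_chb}, \code{b_chb}, \code{n_points},
#'   \code{residual_sd}, \code{valid_range} (range of admitted O2) and
#'   \code{n_excluded}.
#' @export
calibrateChemicalBackground <- function(points, min_o2_uM = 50) {
  o2 <- points$o2_uM
  J <- points$J
  stopifnot(length(o2) == length(J))
  keep <- is.finite(o2) & is.finite(J) & o2 >= min_o2_uM
  if (sum(keep) < 2)
    stop("need at least 2 points with O2 >= ", min_o2_uM, " uM (have ",
         sum(keep), ")")
  if (any(!keep))
    message(sum(!keep), " point(s) below ", min_o2_uM, " uM excluded")
  fit <- stats::lm(J[keep] ~ o2[keep])
  cf <- unname(stats::coef(fit))
  res <- stats::residuals(fit)
  list(a_chb = cf[1], b_chb = cf[2], n_points = sum(keep),
       residual_sd = if (sum(keep) > 2) stats::sd(res) else 0,
       valid_range = range(o2[keep]), n_excluded = sum(!keep))
}

#' Complex IV activity corrected for chemical background
#'
#' \code{CIV_E = J(AsTm) - J(Azd)} at closely matched oxygen concentrations
#' (matched mode), or \code{J(AsTm) - (a_chb + b_chb * C)} using a fitted
#' chemical background line (fit mode, see
#' \code{\link{calibrateChemicalBackground}}).
#'
#' @param J_astm ascorbate+TMPD-stimulated flux.
#' @param o2_astm oxygen concentration at the AsTm mark, uM.
#' @param J_azd,o2_azd matched mode: azide-inhibited flux and its O2.
#' @param chb_fit fit mode: result of
#'   \code{\link{calibrateChemicalBackground}}.
#' @param tol_uM matched-O2 tolerance, default 5 uM.
#' @return list with \code{CIV_E} and \code{mode}.
#' @export
civActivity <- function(J_astm, o2_astm, J_azd = NULL, o2_azd = NULL,
                        chb_fit = NULL, tol_uM = 5) {
  if (!is.null(chb_fit)) {
    rng <- chb_fit$valid_range
    if (o2_astm < rng[1] || o2_astm > rng[2])
      stop("AsTm O2 (", o2_astm, " uM) outside the fitted background range [",
           rng[1], ", ", rng[2], "]")
    return(list(CIV_E = J_astm - (chb_fit$a_chb + chb_fit$b_chb * o2_astm),
                mode = "fit"))
  }
  if (is.null(J_azd) || is.null(o2_azd))
    stop("supply either (J_azd, o2_azd) or chb_fit")
  if (abs(o2_astm - o2_azd) > tol_uM)
    stop("O2 mismatch ", abs(o2_astm - o2_azd), " uM exceeds tolerance ",
         tol_uM, " uM; calibrate the chemical background and use fit mode")
  list(CIV_E = J_astm - J_azd, mode = "matched")
}

#' Steady-state step analysis
#'
#' In a step analysis each titration is bracketed by a background rate Y
#' (immediately before the titration) and a reference rate Z (after it), so
#' consecutive steps yield two rates, Z_i and Y_{i+1}, in the same
#' respiratory state. Their relative drift \code{d = (Z_i - Y_{i+1}) / Z_i}
#' is zero at steady state; positive drift means declining respiration
#' (corrections required, see \code{\link{ecorr}}), negative drift means the
#' rate was still rising (prolong monitoring).
#'
#' @param steps data.frame with columns \code{state}, \code{Z} (reference
#'   rate of the step) and \code{Y_next} (background rate of the following
#'   titration, same state).
#' @param tol steady-state tolerance on |d|, default 0.05.
#' @return data.frame with \code{state}, \code{Z}, \code{Y_next}, \code{d}
#'   and \code{status} in \{steady, declining, rising\}.
#' @export
stepAnalysis <- function(steps, tol = 0.05) {
  d <- (steps$Z - steps$Y_next) / steps$Z
  status <- ifelse(abs(d) <= tol, "steady",
                   ifelse(d > 0, "declining", "rising"))
  data.frame(state = steps$state, Z = steps$Z, Y_next = steps$Y_next,
             d = d, status = status, stringsAsFactors = FALSE)
}

#' Correct ET capacity for time-declining respiration
#'
#' When respiration declines between the OXPHOS mark (P1) and the rate just
#' before uncoupling (P2), the measured ET rate E corresponds to the later,
#' lower level; ratios against P1 would be inflated (P1/E can exceed 1,
#' which is theoretically impossible). Assuming the P/E ratio is unchanged,
#' the ET capacity on the P1 level is \code{E_corr = (P1 / P2) * E}, which
#' restores \code{P1 / E_corr = P2 / E} exactly.
#'
#' @param P1 OXPHOS rate at its own mark.
#' @param P2 same-state rate immediately before the uncoupler titration.
#' @param E measured ET rate.
#' @return \code{E_corr}.
#' @export
ecorr <- function(P1, P2, E) {
  stopifnot(is.finite(P1), is.finite(P2), is.finite(E))
  if (P2 <= 0) stop("P2 must be positive")
  if (P1 <= 0 || E <= 0) stop("P1 and E must be positive")
  (P1 / P2) * E
}
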
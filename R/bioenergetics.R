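#' @include corrections.R
NULL

#' Flux control ratios
#'
#' Normalizes every state's (rox-corrected) rate by the rate of a common
#' reference state, removing mitochondrial-content and normalization effects:
#' \code{FCR_s = rate_s / rate_ref}. FCRs are invariant under any positive
#' rescaling of all of a sample's rates, hence independent of the
#' normalization basis.
#'
#' @param table a \linkS4class{StateRateTable}.
#' @param reference reference step label; defaults to the protocol reference
#'   recorded for the table's protocol.
#' @param corrected use rox-corrected rates when available.
#' @return named numeric vector of FCRs keyed by step label.
#' @export
fluxControlRatios <- function(table, reference = NULL, corrected = TRUE) {
  stopifnot(is(table, "StateRateTable"))
  if (is.null(reference)) {
    reference <- tryCatch(
      referenceState(builtinProtocol(table@protocol_id)),
      error = function(e) stop("no reference step given and protocol '",
                               table@protocol_id, "' is not built in"))
  }
  v <- .rateVector(table, corrected)
  if (!reference %in% names(v))
    stop("reference step '", reference, "' not present in the table")
  ref <- v[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference rate must be positive (got ", ref, ")")
  v / ref
}

#' Coupling control efficiencies
#'
#' From the leak (L), OXPHOS (P) and ET (E) rates of one sample in one
#' pathway state: the P-L control efficiency \code{(P - L)/P}, the
#' biochemical E-L coupling efficiency \code{(E - L)/E} (the linearization of
#' the respiratory control ratio to the 0-1 range), and the E-P control
#' efficiency \code{(E - P)/E} (the normalized excess of ET over OXPHOS
#' capacity). Efficiencies must be computed per sample, never from group
#' means of numerators and denominators.
#'
#' @param L leak rate (>= 0).
#' @param P OXPHOS capacity (> 0).
#' @param E ET capacity (> 0).
#' @return list with \code{pl_eff}, \code{el_eff}, \code{ep_eff},
#'   \code{L_over_P}, \code{L_over_E} and logical \code{flag_E_lt_P}: E < P
#'   is theoretically impossible and indicates a non-steady-state artifact
#'   unless an E_corr record explains it.
#' @export
couplingEfficiencies <- function(L, P, E) {
  if (!is.finite(P) || P <= 0) stop("P must be positive")
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(L) || L < 0) stop("L must be non-negative")
  flag <- E < P
  if (flag)
    warning("E < P is theoretically impossible; ",
            "check for time-declining respiration (E_corr)")
  list(pl_eff = (P - L) / P,
       el_eff = (E - L) / E,
       ep_eff = (E - P) / E,
       L_over_P = L / P,
       L_over_E = L / E,
       flag_E_lt_P = flag)
}

#' Flux control efficiency of a titration step
#'
#' Relative stimulation by one titration: \code{(Z - Y)/Z} where Y is the
#' background rate before the titration and Z the reference rate after it.
#' Zero means no stimulation; negative values indicate an inhibitory step.
#'
#' @param Y background rate before the titration.
#' @param Z reference rate after the titration (> 0).
#' @return numeric(1).
#' @export
stepControlEfficiency <- function(Y, Z) {
  if (any(!is.finite(Z)) || any(Z <= 0)) stop("Z must be positive")
  (Z - Y) / Z
}

#' NS-N pathway control efficiency
#'
#' Relative stimulation of the combined NS-pathway rate over the NADH-linked
#' rate alone: \code{(NS - N)/NS}; 0.5 when succinate doubles the rate.
#'
#' @param N single N-pathway rate.
#' @param NS combined NS-pathway rate (> 0).
#' @return numeric(1).
#' @export
nsNControlEfficiency <- function(N, NS) {
  if (any(!is.finite(NS)) || any(NS <= 0)) stop("NS must be positive")
  (NS - N) / NS
}

#' Additivity of convergent electron flow at the Q-junction
#'
#' Relates the combined NS-pathway ET capacity to the separately measured N-
#' and S-pathway capacities. With pathway control ratios alpha = dominant
#' single rate / NS and beta = subdominant single rate / NS, the additivity
#' index is \code{A = (1 - alpha)/beta}: 1 at complete additivity
#' (NS = N + S), 0 when the combined capacity equals the dominant pathway
#' alone. When N/NS and S/NS tie exactly the S-pathway is designated
#' dominant (deterministic tie-break; S dominates in most mitochondria).
#'
#' @param N,S,NS positive rox-corrected ET-state rates of one sample.
#' @return list with \code{alpha}, \code{beta}, \code{dominant} ("N" or
#'   "S"), \code{A} and \code{N_over_S}.
#' @export
additivityIndex <- function(N, S, NS) {
  if (!is.finite(NS) || NS <= 0) stop("NS must be positive")
  if (!is.finite(N) || N <= 0 || !is.finite(S) || S <= 0)
    stop("N and S must be positive")
  rN <- N / NS; rS <- S / NS
  if (rN > rS) {
    alpha <- rN; beta <- rS; dominant <- "N"
  } else {
    alpha <- rS; beta <- rN; dominant <- "S"
  }
  list(alpha = alpha, beta = beta, dominant = dominant,
       A = (1 - alpha) / beta, N_over_S = N / S)
}

#' Aggregate coupling ratios across samples
#'
#' The respiratory control ratio P/L is bounded below by 1 and unbounded
#' above, so averaging P/L across samples is statistically incorrect. The
#' linearized ratio L/P (range 0-1) is averaged instead, and the correct
#' group RCR is its inverse: \code{1 / mean(L/P)}. The naive mean of P/L is
#' reported for comparison only and is always >= the correct RCR (Jensen's
#' inequality), with equality iff all samples share the same L/P.
#'
#' @param L,P numeric vectors of per-sample leak and OXPHOS rates (P > 0).
#' @return list with \code{mean_L_over_P}, \code{sd_L_over_P}, \code{n},
#'   \code{correct_RCR} and \code{naive_RCR} (NA if any L is 0, with
#'   \code{naive_RCR_note}).
#' @export
aggregateRatio <- function(L, P) {
  stopifnot(length(L) == length(P), length(L) >= 1)
  if (any(!is.finite(P)) || any(P <= 0)) stop("all P must be positive")
  if (any(!is.finite(L)) || any(L < 0)) stop("all L must be non-negative")
  lp <- L / P
  m <- mean(lp)
  naive <- if (any(L == 0)) NA_real_ else mean(P / L)
  list(mean_L_over_P = m,
       sd_L_over_P = if (length(lp) > 1) stats::sd(lp) else 0,
       n = length(lp),
       correct_RCR = 1 / m,
       naive_RCR = naive,
       naive_RCR_note = if (is.na(naive))
         "naive mean of P/L undefined (a sample has L = 0)"
       else "statistically incorrect; for comparison only")
}

## Per-sample derived metrics from a pair of state-rate tables. Which steps
## feed which metric is protocol knowledge: in RP1 the coupling states are
## L = 1PM, P = 2c (cytochrome-c-saturated OXPHOS), E = 3U, the pathway
## states N_E = 4G, NS_E = 5S, S_E = rotenone step; RP2 contributes the FAO
## subtraction (1c minus +M.1) and the intra-assay E-P pair 6Gp/7U.
.sampleMetrics <- function(rp1 = NULL, rp2 = NULL) {
  out <- list()
  if (!is.null(rp1)) {
    v <- .rateVector(rp1)
    rot <- intersect(c("7Rot", "6Rot"), names(v))
    if (all(c("1PM", "2c", "3U") %in% names(v))) {
      ce <- suppressWarnings(
        couplingEfficiencies(v[["1PM"]], v[["2c"]], v[["3U"]]))
      out$pl_eff <- ce$pl_eff
      out$el_eff <- ce$el_eff
      out$ep_eff_N <- ce$ep_eff
      out$L_over_P <- ce$L_over_P
    }
    if (all(c("2D", "2c") %in% names(v))) {
      out$cytc_eff <- cytcControlEfficiency(v[["2D"]], v[["2c"]])$efficiency
    }
    if (all(c("4G", "5S") %in% names(v))) {
      out$nsn_eff <- nsNControlEfficiency(v[["4G"]], v[["5S"]])
    }
    if (length(rot) == 1 && all(c("4G", "5S") %in% names(v))) {
      ai <- additivityIndex(v[["4G"]], v[[rot]], v[["5S"]])
      out$additivity <- ai$A
      out$alpha <- ai$alpha
      out$beta <- ai$beta
      out$N_over_S <- ai$N_over_S
    }
  }
  if (!is.null(rp2)) {
    v2 <- .rateVector(rp2)
    if (all(c("6Gp", "7U") %in% names(v2)))
      out$ep_eff_FNSGp <- stepControlEfficiency(v2[["6Gp"]], v2[["7U"]])
    if (all(c("1c", "+M.1") %in% names(v2)))
      out$F_P <- faoCapacity(v2[["1c"]], v2[["+M.1"]])$F_P
    ## inter-assay E-P control efficiency: OXPHOS at full substrate input
    ## (FNS_P from RP2) against ET capacity of the comparable state in RP1
    if (!is.null(rp1)) {
      v1 <- .rateVector(rp1)
      e_ref <- intersect(c("6Oct", "5S"), names(v1))
      if ("5S" %in% names(v2) && length(e_ref) > 0)
        out$ep_eff_interassay <-
          stepControlEfficiency(v2[["5S"]], v1[[e_ref[1]]])
    }
  }
  out
}

#' Assemble bioenergetic profiles for a cohort
#'
#' Computes per-sample flux control ratios and derived efficiencies from
#' corrected, state-assigned rate tables, then summarizes per group both as
#' median with interquartile range (the profile convention) and as mean with
#' standard deviation (the efficiency-table convention). All group statistics
#' are computed on per-sample ratios, never as ratios of group means.
#'
#' @param samples named list; each element is either a single
#'   \linkS4class{StateRateTable} or a list with elements \code{rp1} and/or
#'   \code{rp2} for parallel runs of one sample.
#' @param grouping character vector (recycled names ok) assigning each
#'   sample to a group; defaults to one group.
#' @return An object of class \code{"BioenergeticProfile"}: a list with
#'   \code{fcr} (long data.frame sample/group/protocol/step/pathway/fcr),
#'   \code{metrics} (long data.frame sample/group/metric/value) and
#'   \code{summaries} (group/metric n, mean, sd, median, q1, q3).
#' @export
buildProfile <- function(samples, grouping = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  if (is.null(grouping)) grouping <- rep("all", length(samples))
  grouping <- rep_len(as.character(grouping), length(samples))

  fcr <- NULL
  metrics <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    nm <- names(samples)[i]
    if (is(s, "StateRateTable")) {
      s <- if (startsWith(toupper(s@protocol_id), "RP2")) list(rp2 = s)
           else list(rp1 = s)
    }
    for (tab in s[!vapply(s, is.null, logical(1))]) {
      f <- fluxControlRatios(tab)
      fcr <- rbind(fcr, data.frame(
        sample = nm, group = grouping[i], protocol = tab@protocol_id,
        step = names(f),
        pathway = tab@rows$pathway_state[match(names(f), tab@rows$step)],
        fcr = unname(f), stringsAsFactors = FALSE))
    }
    m <- .sampleMetrics(rp1 = s$rp1, rp2 = s$rp2)
    if (length(m))
      metrics <- rbind(metrics, data.frame(
        sample = nm, group = grouping[i], metric = names(m),
        value = unlist(m, use.names = FALSE), stringsAsFactors = FALSE))
  }

  summarize <- function(df, keys, valcol) {
    sp <- split(df, df[keys], drop = TRUE)
    do.call(rbind, lapply(sp, function(g) {
      x <- g[[valcol]]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      cbind(g[1, keys, drop = FALSE],
            data.frame(n = length(x), mean = mean(x),
                       sd = if (length(x) > 1) stats::sd(x) else 0,
                       median = q[2], q1 = q[1], q3 = q[3]))
    }))
  }
  summaries <- NULL
  if (!is.null(metrics))
    summaries <- summarize(metrics, c("group", "metric"), "value")
  fcr_summary <- NULL
  if (!is.null(fcr))
    fcr_summary <- summarize(fcr, c("group", "protocol", "step"), "fcr")
  structure(list(fcr = fcr, metrics = metrics, summaries = summaries,
                 fcr_summaries = fcr_summary,
                 n_samples = length(samples)),
            class = "BioenergeticProfile")
}

#' @export
print.BioenergeticProfile <- function(x, ...) {
  cat(sprintf("BioenergeticProfile: %d sample(s)\n", x$n_samples))
  if (!is.null(x$summaries)) {
    cat("Group summaries (per-sample ratios):\n")
    print(x$summaries, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot flux control ratio profiles
#'
#' Median FCR per group and protocol across the protocol's steps, one line
#' per group, on a common 0-based axis.
#'
#' @param profile a \code{"BioenergeticProfile"}.
#' @param protocol which protocol's profile to draw.
#' @export
plotProfile <- function(profile, protocol = "RP1") {
  fs <- profile$fcr_summaries
  fs <- fs[fs$protocol == protocol, , drop = FALSE]
  if (is.null(fs) || nrow(fs) == 0) stop("no FCRs for protocol ", protocol)
  steps <- unique(fs$step)
  groups <- unique(fs$group)
  graphics::plot(NULL, xlim = c(1, length(steps)),
                 ylim = c(0, max(fs$median) * 1.05),
                 xaxt = "n", xlab = "", ylab = "Flux control ratio",
                 main = paste("FCR profile,", protocol))
  graphics::axis(1, at = seq_along(steps), labels = steps, las = 2)
  for (gi in seq_along(groups)) {
    g <- fs[fs$group == groups[gi], ]
    graphics::lines(match(g$step, steps), g$median, type = "b", col = gi,
                    pch = 16)
  }
  graphics::legend("topright", legend = groups, col = seq_along(groups),
                   lty = 1, pch = 16, bty = "n")
  invisible(NULL)
}
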
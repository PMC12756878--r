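#' @include simulate.R regression.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Analyse one oxygraph run end to end
#'
#' read trace -> detect measurement intervals -> estimate flux -> read and
#' assign marks -> rox baseline correction -> normalization, with a QC
#' report. Warnings (negative corrected rates, cytochrome-c stimulation
#' above the damage threshold, non-steady steps) are reported, never fatal;
#' structural errors abort with a stage-named message.
#'
#' @param trace path to a trace file or an \linkS4class{OxygraphTrace}.
#' @param marks path to a marks file or a mark data.frame.
#' @param protocol protocol id or \linkS4class{ProtocolDefinition}.
#' @param background instrumental \code{\link{backgroundCalibration}}.
#' @param window_s slope window (s).
#' @param spike_pre_s,spike_post_s titration spike exclusion window.
#' @param aggregator mark aggregator.
#' @param normalize apply the trace's normalization metadata to the rates.
#' @param cytc_damage_threshold flag threshold for the cytochrome-c test.
#' @param out_dir if non-NULL, the state table (TSV + JSON sidecar) is
#'   written there.
#' @param dry_run validate the inputs and return the resolved plan without
#'   computing.
#' @return list with \code{table} (corrected \linkS4class{StateRateTable}),
#'   \code{volumetric_table}, \code{flux}, \code{trace}, \code{qc} (named
#'   list of flags) and \code{paths} (written files).
#' @export
analyzeRun <- function(trace, marks, protocol = "RP1",
                       background = backgroundCalibration(),
                       window_s = 40, spike_pre_s = 5, spike_post_s = 20,
                       aggregator = "mean", normalize = TRUE,
                       cytc_damage_threshold = 0.15, out_dir = NULL,
                       dry_run = FALSE) {
  proto <- .stage("protocol", {
    if (is(protocol, "ProtocolDefinition")) protocol
    else builtinProtocol(protocol)
  })
  if (dry_run) {
    plan <- list(
      trace = if (is.character(trace)) trace else "<in-memory trace>",
      marks = if (is.character(marks)) marks else "<in-memory marks>",
      protocol = proto@protocol_id,
      background = as.list(background),
      window_s = window_s,
      spike_window_s = c(pre = spike_pre_s, post = spike_post_s),
      aggregator = aggregator, normalize = normalize)
    if (is.character(trace) && !file.exists(trace))
      stop("stage 'trace': file not found: ", trace)
    if (is.character(marks) && !file.exists(marks))
      stop("stage 'marks': file not found: ", marks)
    return(list(plan = plan, dry_run = TRUE))
  }

  tr <- .stage("trace", {
    if (is(trace, "OxygraphTrace")) trace else readTrace(trace)
  })
  iv <- .stage("intervals", detectIntervals(
    tr, detect_reox = FALSE, spike_pre_s = spike_pre_s,
    spike_post_s = spike_post_s))
  fx <- .stage("flux", estimateFluxSeries(tr, calib = background,
                                          window_s = window_s,
                                          intervals = iv))
  mk <- .stage("marks", {
    if (is.character(marks)) readMarks(marks, proto)
    else validateMarks(marks, proto)
  })
  norm <- normalization(tr)
  tab <- .stage("states", assignStates(mk, proto, fx,
                                       aggregator = aggregator,
                                       norm_basis = norm$basis,
                                       norm_value = norm$value))
  tab <- .stage("corrections", withCallingHandlers(
    baselineCorrectRox(tab),
    warning = function(w) invokeRestart("muffleWarning")))

  qc <- list()
  rows <- tab@rows
  qc$rox_present <- tab@rox_corrected
  qc$negative_corrected <-
    rows$step[grepl("negative_corrected", rows$flags)]
  v <- .rateVector(tab)
  cyt_pre <- intersect(c("2D", "1Oct"), names(v))
  cyt_post <- intersect(c("2c", "1c"), names(v))
  if (length(cyt_pre) && length(cyt_post)) {
    ct <- cytcControlEfficiency(v[[cyt_pre[1]]], v[[cyt_post[1]]],
                                cytc_damage_threshold)
    qc$cytc_efficiency <- ct$efficiency
    qc$cytc_damaged <- ct$damaged
    if (ct$damaged)
      warning("cytochrome-c control efficiency ",
              round(ct$efficiency, 3), " exceeds the damage threshold (",
              cytc_damage_threshold, "): compromised outer membrane")
  }

  vol_tab <- tab
  if (normalize && norm$basis != "none")
    tab <- .stage("normalize", normalizeStateTable(tab))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, paste0(tab@run_id, "_states.tsv"))
    suppressWarnings(writeStateTable(tab, p))
    paths$state_table <- p
    paths$sidecar <- paste0(p, ".json")
  }
  list(table = tab, volumetric_table = vol_tab, flux = fx, trace = tr,
       qc = qc, paths = paths)
}

#' Cohort profile with technical-repeat agreement
#'
#' Builds the bioenergetic profile of a cohort of samples assayed with the
#' two reference protocols in parallel, pools the comparable-state pairs
#' into a repeat-agreement report, and, when groups are given, compares
#' groups by symmetric regression.
#'
#' @param samples named list; each element a list with \code{rp1} and/or
#'   \code{rp2} \linkS4class{StateRateTable}s (corrected).
#' @param grouping group label per sample.
#' @param cluster_pairs optional named list of data.frames (columns \code{x},
#'   \code{y}) for \code{\link{clusterCompare}}; defaults to per-group
#'   comparable-state pairs when at least two groups are present.
#' @return list with \code{profile}, \code{agreement},
#'   \code{comparable_pairs}, and \code{clusters} (NULL when ungrouped).
#' @export
profileCohort <- function(samples, grouping = NULL, cluster_pairs = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  if (is.null(grouping)) grouping <- rep("all", length(samples))
  grouping <- rep_len(as.character(grouping), length(samples))

  ## normalization bases must agree within each group
  for (g in unique(grouping)) {
    bases <- unlist(lapply(samples[grouping == g], function(s)
      vapply(s[!vapply(s, is.null, logical(1))],
             function(tb) tb@norm_basis, character(1))))
    if (length(unique(bases)) > 1)
      stop("inconsistent normalization bases within group '", g, "': ",
           paste(unique(bases), collapse = ", "))
  }

  profile <- buildProfile(samples, grouping)
  pairs <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!is.null(s$rp1) && !is.null(s$rp2)) {
      cp <- comparableStatePairs(s$rp1, s$rp2)
      cp <- cp[cp$class != "possibly_comparable", , drop = FALSE]
      if (nrow(cp))
        pairs <- rbind(pairs, cbind(sample = names(samples)[i],
                                    group = grouping[i], cp))
    }
  }
  agreement <- if (!is.null(pairs) && nrow(pairs) >= 3)
    repeatAgreement(pairs) else NULL

  clusters <- NULL
  if (is.null(cluster_pairs) && length(unique(grouping)) >= 2 &&
      !is.null(pairs)) {
    cluster_pairs <- lapply(split(pairs, pairs$group), function(p)
      data.frame(x = p$rate_rp1, y = p$rate_rp2))
    cluster_pairs <- Filter(function(p) nrow(p) >= 3, cluster_pairs)
  }
  if (!is.null(cluster_pairs) && length(cluster_pairs) >= 1)
    clusters <- clusterCompare(cluster_pairs)

  list(profile = profile, agreement = agreement,
       comparable_pairs = pairs, clusters = clusters)
}
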
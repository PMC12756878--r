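#' @include accessors.R
NULL

#' Column-mapping dialect for trace files
#'
#' The canonical dialect is comma-separated with header
#' \code{time_s,o2_uM[,event]}, decimal point and UTF-8, with run metadata in
#' leading \code{#} comment lines. Instrument exports with other column names
#' or separators are accommodated by overriding the mapping.
#'
#' @param time_col,o2_col,event_col column names holding time (s), O2 (uM)
#'   and the optional event label.
#' @param sep field separator.
#' @param dec decimal mark.
#' @return A named list understood by \code{\link{readTrace}}.
#' @export
traceDialect <- function(time_col = "time_s", o2_col = "o2_uM",
                         event_col = "event", sep = ",", dec = ".") {
  list(time_col = time_col, o2_col = o2_col, event_col = event_col,
       sep = sep, dec = dec)
}

.fmtNum <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                      trim = TRUE), character(1))
  out[is.na(x)] <- "NA"
  out
}

#' Read an oxygraph trace from a delimited text file
#'
#' Leading \code{#} comment lines of the form \code{# key: value} supply run
#' metadata (\code{run_id}, \code{chamber_volume_mL}, \code{temperature_C},
#' \code{normalization_basis}, \code{normalization_value}) and open-chamber
#' intervals (\code{# open_interval: t0,t1}, repeatable). Rows that fall
#' inside declared open intervals are retained in the trace; they are flagged
#' (masked) downstream when flux is estimated, never dropped.
#'
#' @param path file path.
#' @param dialect a \code{\link{traceDialect}}.
#' @return A validated \linkS4class{OxygraphTrace}.
#' @export
readTrace <- function(path, dialect = traceDialect()) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop("parse error: no header line in ", path)

  meta <- list()
  open_iv <- NULL
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "open_interval") {
      bounds <- as.numeric(strsplit(val, ",")[[1]])
      open_iv <- rbind(open_iv, bounds)
    } else meta[[key]] <- val
  }

  header <- strsplit(body[1], dialect$sep, fixed = TRUE)[[1]]
  header <- trimws(header)
  for (col in c(dialect$time_col, dialect$o2_col)) {
    hits <- sum(header == col)
    if (hits == 0L)
      stop("parse error: required column '", col, "' missing (found: ",
           paste(header, collapse = ", "), ")")
    if (hits > 1L)
      stop("parse error: duplicate column '", col, "'")
  }
  rows <- strsplit(body[-1], dialect$sep, fixed = TRUE)
  nfield <- length(header)
  cells <- vapply(rows, function(r) {
    length(r) <- nfield
    r
  }, character(nfield))
  cells <- matrix(cells, nrow = nfield)
  getcol <- function(name) {
    if (!name %in% header) return(NULL)
    trimws(cells[which(header == name)[1], ])
  }
  # malformed cells become NA here and are reported with their row below
  num <- function(x) suppressWarnings(as.numeric(chartr(dialect$dec, ".", x)))
  time_s <- num(getcol(dialect$time_col))
  o2 <- num(getcol(dialect$o2_col))
  if (anyNA(time_s))
    stop("parse error: non-numeric time at data row ", which(is.na(time_s))[1])
  if (anyNA(o2))
    stop("parse error: non-numeric O2 at data row ", which(is.na(o2))[1])

  ev_col <- getcol(dialect$event_col)
  events <- data.frame(time_s = numeric(0), label = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(ev_col)) {
    has_ev <- !is.na(ev_col) & nzchar(ev_col)
    events <- data.frame(time_s = time_s[has_ev], label = ev_col[has_ev],
                         stringsAsFactors = FALSE)
  }

  oxygraphTrace(
    time_s = time_s, o2_uM = o2,
    run_id = if (!is.null(meta$run_id)) meta$run_id else
      sub("\\.[^.]*$", "", basename(path)),
    chamber_volume_mL = if (!is.null(meta$chamber_volume_mL))
      as.numeric(meta$chamber_volume_mL) else 2,
    temperature_C = if (!is.null(meta$temperature_C))
      as.numeric(meta$temperature_C) else 37,
    norm_basis = if (!is.null(meta$normalization_basis))
      meta$normalization_basis else "none",
    norm_value = if (!is.null(meta$normalization_value))
      as.numeric(meta$normalization_value) else 1,
    events = events, open_intervals = open_iv)
}

#' Write an oxygraph trace in the canonical dialect
#'
#' @param trace an \linkS4class{OxygraphTrace}.
#' @param path output path.
#' @return \code{path}, invisibly. \code{writeTrace} followed by
#'   \code{\link{readTrace}} is the identity, and re-writing a trace read
#'   from a canonical file reproduces the file byte-identically.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "OxygraphTrace"))
  meta <- c(
    sprintf("# run_id: %s", trace@run_id),
    sprintf("# chamber_volume_mL: %s", .fmtNum(trace@chamber_volume_mL)),
    sprintf("# temperature_C: %s", .fmtNum(trace@temperature_C)),
    sprintf("# normalization_basis: %s", trace@norm_basis),
    sprintf("# normalization_value: %s", .fmtNum(trace@norm_value)))
  if (nrow(trace@open_intervals) > 0)
    meta <- c(meta, sprintf("# open_interval: %s,%s",
                            .fmtNum(trace@open_intervals[, 1]),
                            .fmtNum(trace@open_intervals[, 2])))
  ev <- character(length(trace@time_s))
  if (nrow(trace@events) > 0) {
    idx <- match(trace@events$time_s, trace@time_s)
    ok <- !is.na(idx)
    ev[idx[ok]] <- trace@events$label[ok]
  }
  body <- paste(.fmtNum(trace@time_s), .fmtNum(trace@o2_uM), ev, sep = ",")
  writeLines(c(meta, "time_s,o2_uM,event", body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a mark table and link it to a protocol
#'
#' Marks are analyst-defined windows \code{[t_start_s, t_end_s)} over which a
#' state's rate is read. The file is CSV with header
#' \code{label,t_start_s,t_end_s,role}; \code{role} defaults to
#' \code{"state"}. Labels must resolve against the protocol's steps (an
#' uncoupler titration mark such as \code{"3U2.5"} resolves to its
#' multi-titration step \code{"3U"}) or carry an \code{artifact-exclusion}
#' role. State marks must follow the protocol's titration order in time and
#' must not overlap.
#'
#' @param path file path.
#' @param protocol a \linkS4class{ProtocolDefinition}.
#' @return data.frame with columns \code{label}, \code{t_start_s},
#'   \code{t_end_s}, \code{role}, \code{step} (resolved protocol step),
#'   sorted by \code{t_start_s}.
#' @export
readMarks <- function(path, protocol) {
  stopifnot(is(protocol, "ProtocolDefinition"))
  if (!file.exists(path)) stop("marks file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty marks file: ", path)
    return(data.frame(label = character(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), role = character(0),
                      step = character(0), stringsAsFactors = FALSE))
  }
  if (!all(c("label", "t_start_s", "t_end_s") %in% names(df)))
    stop("marks file must have columns label,t_start_s,t_end_s[,role]")
  if (is.null(df$role)) df$role <- "state"
  df$role[is.na(df$role) | !nzchar(df$role)] <- "state"
  validateMarks(df, protocol)
}

#' Validate a mark table against a protocol
#'
#' @param marks data.frame with columns \code{label}, \code{t_start_s},
#'   \code{t_end_s}, \code{role}.
#' @param protocol a \linkS4class{ProtocolDefinition}.
#' @return The mark table sorted by \code{t_start_s} with a resolved
#'   \code{step} column.
#' @export
validateMarks <- function(marks, protocol) {
  if (any(marks$t_start_s >= marks$t_end_s))
    stop("marks must satisfy t_start_s < t_end_s")
  if (anyDuplicated(marks$label))
    stop("mark labels must be unique per run: ",
         marks$label[duplicated(marks$label)][1])
  marks$step <- NA_character_
  for (i in seq_len(nrow(marks))) {
    if (marks$role[i] == "artifact-exclusion") next
    s <- .resolveStepLabel(marks$label[i], protocol)
    if (is.na(s))
      stop("unknown mark label '", marks$label[i], "'; valid step labels: ",
           paste(protocol@steps$label, collapse = ", "))
    marks$step[i] <- s
  }
  marks <- marks[order(marks$t_start_s), , drop = FALSE]
  rownames(marks) <- NULL

  st <- marks[marks$role == "state" & !is.na(marks$step), , drop = FALSE]
  if (nrow(st) > 1) {
    if (any(st$t_start_s[-1] < st$t_end_s[-nrow(st)]))
      stop("state marks must not overlap")
    ord <- match(st$step, protocol@steps$label)
    if (any(diff(ord) < 0)) {
      i <- which(diff(ord) < 0)[1]
      stop(sprintf(
        "mark order violates protocol '%s': '%s' precedes '%s' in time",
        protocol@protocol_id, st$label[i], st$label[i + 1]))
    }
  }
  marks
}

#' Write a mark table
#'
#' @param marks data.frame as returned by \code{\link{readMarks}}.
#' @param path output path.
#' @export
writeMarks <- function(marks, path) {
  utils::write.csv(marks[, c("label", "t_start_s", "t_end_s", "role")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a state-rate table as TSV plus a JSON provenance sidecar
#'
#' The TSV holds one row per step (rates, dispersion, mean O2 at the mark);
#' the sidecar \code{<path>.json} captures run and protocol identifiers,
#' units, normalization, correction status, the parameters used and the
#' package version. If the residual oxygen consumption baseline has not been
#' applied the file is still written, with a warning that rates are totals.
#'
#' @param table a \linkS4class{StateRateTable}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeStateTable <- function(table, path) {
  stopifnot(is(table, "StateRateTable"))
  if (!table@rox_corrected)
    warning("rox absent; rates are totals")
  rows <- table@rows
  out <- rows
  for (col in c("rate_total", "rate_corrected", "sd", "o2_mean"))
    out[[col]] <- vapply(rows[[col]], function(v)
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                     trim = TRUE), character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    run_id = table@run_id,
    protocol_id = table@protocol_id,
    units = table@units,
    normalization = list(basis = table@norm_basis, value = table@norm_value),
    rox_corrected = table@rox_corrected,
    provenance = table@provenance,
    software = paste0("oxygraphR ",
                      as.character(utils::packageVersion("oxygraphR"))))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a state-rate table written by \code{\link{writeStateTable}}
#'
#' @param path TSV path (the JSON sidecar is looked up next to it).
#' @return A \linkS4class{StateRateTable}.
#' @export
readStateTable <- function(path) {
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  for (col in c("rate_total", "rate_corrected", "sd", "o2_mean"))
    rows[[col]] <- as.numeric(rows[[col]])
  rows$n <- as.integer(rows$n)
  rows$flags[is.na(rows$flags)] <- ""
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
          else list()
  new("StateRateTable",
      run_id = if (!is.null(side$run_id)) side$run_id else "run",
      protocol_id = if (!is.null(side$protocol_id)) side$protocol_id else "",
      rows = rows,
      units = if (!is.null(side$units)) side$units else "pmol.s-1.mL-1",
      norm_basis = if (!is.null(side$normalization$basis))
        side$normalization$basis else "none",
      norm_value = if (!is.null(side$normalization$value))
        as.numeric(side$normalization$value) else 1,
      rox_corrected = isTRUE(side$rox_corrected),
      provenance = if (!is.null(side$provenance)) as.list(side$provenance)
                   else list())
}
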
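# Plain-text formats: traces and session logs as TSV with a '#'-prefixed
# key-value header block (columns time_s, voltage_mv, current_na); events
# and annotations as TSV (time_s, kind, value). Chosen for diffability; no
# vendor/binary formats.

ANNOTATION_KINDS <- c("pressure_release", "suction", "current_change",
                      "note")
EVENT_KINDS <- c("touch", "zap", "reseal", "suction_break")

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

header_lines <- function(kv) {
  vapply(names(kv), function(k) {
    sprintf("#%s\t%s", k, as.character(kv[[k]]))
  }, character(1))
}

parse_header <- function(path) {
  lines <- readLines(path, n = 200L)
  hl <- lines[startsWith(lines, "#")]
  kv <- list()
  for (l in hl) {
    parts <- strsplit(sub("^#", "", l), "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) kv[[parts[1]]] <- parts[2]
  }
  kv
}

proto_to_kv <- function(proto) {
  if (is.null(proto)) return(list())
  if (inherits(proto, "step_protocol")) {
    list(protocol = "step", protocol_onset_s = proto$onset,
         protocol_duration_s = proto$duration,
         protocol_amplitude_na = proto$amplitude,
         protocol_tail_s = proto$tail)
  } else if (inherits(proto, "pulse_train")) {
    list(protocol = "pulse_train",
         pulse_frequency_hz = proto$frequency, pulse_duty = proto$duty,
         pulse_amplitude_na = proto$amplitude,
         pulse_start_s = proto$start,
         pulse_stop_s = if (is.finite(proto$stop)) proto$stop else "Inf")
  } else list()
}

kv_to_proto <- function(kv) {
  num <- function(k, default = NULL) {
    if (is.null(kv[[k]])) return(default)
    as.numeric(kv[[k]])
  }
  if (identical(kv$protocol, "step")) {
    step_protocol(onset = num("protocol_onset_s"),
                  duration = num("protocol_duration_s"),
                  amplitude = num("protocol_amplitude_na"),
                  tail = num("protocol_tail_s", 0))
  } else if (identical(kv$protocol, "pulse_train")) {
    pulse_train(frequency = num("pulse_frequency_hz"),
                duty = num("pulse_duty"),
                amplitude = num("pulse_amplitude_na"),
                start = num("pulse_start_s", 0),
                stop = num("pulse_stop_s", Inf))
  } else NULL
}

#' Write a trace or session log to TSV
#'
#' The file starts with a `#key<TAB>value` header block (format version,
#' sampling rate, units, protocol fields, tip-offset state) followed by a
#' column header `time_s voltage_mv current_na` and the samples.
#'
#' @param trace A `cc_trace` or `cc_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, c("cc_trace", "cc_session")))
  meta <- trace_meta(trace)
  kv <- c(
    list(version = 1,
         type = if (inherits(trace, "cc_session")) "session" else "trace",
         sampling_rate_hz = sampling_rate(trace),
         voltage_units = "mV", current_units = "nA"),
    proto_to_kv(trace_protocol(trace)),
    list(tip_offset_mv = meta$tip_offset_mv %||% 0,
         tip_offset_applied = tolower(as.character(
           isTRUE(meta$tip_offset_applied) ||
             is.null(meta$tip_offset_mv))))
  )
  for (k in c("filter_cutoff_hz", "depth_um", "species", "cell_id")) {
    if (!is.null(meta[[k]]) && !is.na(meta[[k]])) kv[[k]] <- meta[[k]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(kv), con)
  writeLines("time_s\tvoltage_mv\tcurrent_na", con)
  body <- paste(fmt_num(trace$time), fmt_num(trace$voltage),
                fmt_num(trace$current), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a trace or session log from TSV
#'
#' Validates the header (sampling rate and units are mandatory) and applies
#' the pipette tip-offset potential exactly once: if the header declares
#' `tip_offset_mv` with `tip_offset_applied false`, the offset is added to
#' the voltage column and the flag set, so a rewritten file is never
#' offset twice.
#'
#' @param path Input path.
#' @return A `cc_trace` or `cc_session` depending on the declared type.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  kv <- parse_header(path)
  if (is.null(kv$sampling_rate_hz)) {
    abort("header missing required field `sampling_rate_hz`")
  }
  if (is.null(kv$voltage_units) || is.null(kv$current_units)) {
    abort("header missing units (`voltage_units`, `current_units`)")
  }
  dat <- read.delim(path, comment.char = "#", sep = "\t",
                    check.names = FALSE)
  need <- c("time_s", "voltage_mv", "current_na")
  if (!all(need %in% names(dat))) {
    abort(sprintf("columns must be %s", paste(need, collapse = ", ")))
  }
  if (anyNA(dat[need])) abort("column length mismatch or missing values")
  rate <- as.numeric(kv$sampling_rate_hz)
  voltage <- dat$voltage_mv
  tip <- as.numeric(kv$tip_offset_mv %||% 0)
  applied <- identical(tolower(kv$tip_offset_applied %||% "true"), "true")
  if (!applied && tip != 0) {
    voltage <- voltage + tip
    applied <- TRUE
  }
  meta <- list(tip_offset_mv = tip, tip_offset_applied = applied)
  for (k in c("filter_cutoff_hz", "depth_um")) {
    if (!is.null(kv[[k]])) meta[[k]] <- as.numeric(kv[[k]])
  }
  for (k in c("species", "cell_id")) {
    if (!is.null(kv[[k]])) meta[[k]] <- kv[[k]]
  }
  proto <- kv_to_proto(kv)
  if (identical(kv$type, "session")) {
    new_cc_session(dat$time_s, voltage, dat$current_na, rate,
                   pulse = proto,
                   annotations = tibble(time = numeric(),
                                        kind = character(),
                                        value = numeric()),
                   truth_events = NULL, meta = meta)
  } else {
    new_cc_trace(dat$time_s, voltage, dat$current_na, rate,
                 protocol = proto, meta = meta)
  }
}

#' Write events or annotations to TSV
#'
#' @param events Tibble with columns `time`, `kind`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  check_event_kinds(events)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s\tkind\tvalue", con)
  if (nrow(events)) {
    writeLines(paste(fmt_num(events$time), events$kind,
                     ifelse(is.na(events$value), "NA",
                            fmt_num(events$value)),
                     sep = "\t"), con)
  }
  invisible(path)
}

check_event_kinds <- function(events) {
  ok <- c(EVENT_KINDS, ANNOTATION_KINDS)
  bad <- setdiff(unique(events$kind), ok)
  if (length(bad)) {
    abort(sprintf("unknown event kind(s): %s", paste(bad, collapse = ", ")))
  }
  zap_na <- events$kind == "zap" & !is.finite(events$value)
  if (any(zap_na)) abort("zap events must carry a zap voltage value")
  invisible(events)
}

#' Read events or annotations from TSV
#'
#' Unknown kinds are rejected; unsorted input is sorted by time with a
#' warning; duplicate timestamps are allowed.
#'
#' @param path Input path.
#' @return Tibble `time`, `kind`, `value`, ordered by time.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  dat <- read.delim(path, sep = "\t", check.names = FALSE,
                    colClasses = c("numeric", "character", "numeric"))
  out <- tibble(time = dat$time_s, kind = dat$kind, value = dat$value)
  check_event_kinds(out)
  if (is.unsorted(out$time)) {
    warn("events not time-ordered: sorting on read")
    out <- dplyr::arrange(out, .data$time)
  }
  out
}

#' Write cell records to CSV
#'
#' One row per cell (the flattened record produced by [cell_record()]).
#'
#' @param records Tibble of cell records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Read a flat key-value configuration file
#'
#' Parses `key = value` lines ('#' comments and blank lines ignored);
#' values that parse as numbers become numeric, `true`/`false` become
#' logical, everything else stays character.
#'
#' @param path Input path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(m) != 3) abort(sprintf("malformed config line: %s", l))
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
    else val
  }
  out
}
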
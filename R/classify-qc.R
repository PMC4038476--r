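# Neuron/glia classification, spike metrics, and recording-quality rules.

#' Detect current-evoked spikes in a sweep
#'
#' Threshold-crossing detector: a spike starts at an upward crossing of
#' `v_rest + threshold_mv`, with a refractory hold-off. The 50 mV amplitude
#' rule used for classification is applied downstream, on the measured
#' peaks.
#'
#' @param trace A `cc_trace`.
#' @param v_rest Resting potential (mV).
#' @param threshold_mv Detection threshold above rest (mV).
#' @param refractory_ms Hold-off after each detection (ms).
#' @param window Restrict detection to a time window `c(start, stop)` (s),
#'   e.g. the stimulus span; `NULL` for the whole sweep.
#' @return Tibble with one row per spike: `time`, `index`.
#' @export
detect_spikes <- function(trace, v_rest, threshold_mv = 20,
                          refractory_ms = 1, window = NULL) {
  v <- trace$voltage
  thr <- v_rest + threshold_mv
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  if (!is.null(window)) {
    up <- up[trace$time[up] >= window[1] & trace$time[up] < window[2]]
  }
  keep <- integer()
  last <- -Inf
  for (i in up) {
    if (trace$time[i] - last >= refractory_ms / 1000) {
      keep <- c(keep, i)
      last <- trace$time[i]
    }
  }
  tibble(time = trace$time[keep], index = keep)
}

#' Spike metrics: maximum depolarization rate and peak
#'
#' Each detected spike spans from its threshold crossing until the voltage
#' falls back below threshold (capped at `max_span_ms`); the maximum
#' finite-difference derivative and the absolute voltage at the spike
#' maximum are measured over that span, then averaged over spikes.
#'
#' @param trace A `cc_trace` containing at least one evoked spike.
#' @param protocol Step protocol (defaults to the attached one); detection
#'   is restricted to the stimulus span.
#' @param v_rest Resting potential (mV).
#' @param max_span_ms Cap on a single spike span (ms).
#' @return One-row tibble: `dvdt_max` (mV/ms), `v_peak` (mV), `n_spikes`.
#' @export
spike_metrics <- function(trace, protocol = trace_protocol(trace),
                          v_rest, max_span_ms = 20) {
  spikes <- detect_spikes(trace, v_rest,
                          window = c(protocol$onset,
                                     protocol$onset + protocol$duration))
  if (!nrow(spikes)) abort("no spikes detected during the step")
  dt_ms <- 1000 / sampling_rate(trace)
  cap <- max(2L, round(max_span_ms / dt_ms))
  thr <- v_rest + 20
  per <- purrr::map(spikes$index, function(i) {
    stop_i <- min(nrow(trace), i + cap)
    below <- which(trace$voltage[(i + 1):stop_i] < thr)
    if (length(below)) stop_i <- i + below[1]
    idx <- max(1L, i - round(1 / dt_ms)):stop_i
    v <- trace$voltage[idx]
    tibble(v_peak = max(v), dvdt_max = max(diff(v)) / dt_ms)
  }) |> dplyr::bind_rows()
  tibble(dvdt_max = mean(per$dvdt_max), v_peak = mean(per$v_peak),
         n_spikes = nrow(spikes))
}

#' Classify a recording as neuron, glia, or unclassified
#'
#' A cell is a neuron if any current-evoked action potential reaches at
#' least 50 mV in amplitude measured from the resting potential; a cell
#' with no spikes and a membrane time constant below 5 ms is a (putative)
#' glial cell; everything else is left unclassified.
#'
#' @param traces A `cc_trace` or list of sweeps covering the IV protocol
#'   (including suprathreshold steps).
#' @param passive A `cell_passive` from [aggregate_cell()] (supplies
#'   `tau0` and `v_rest`).
#' @param amp_mv Spike-amplitude criterion (mV from rest).
#' @param tau_ms Glial time-constant criterion (ms).
#' @return `"neuron"`, `"glia"`, or `"unclassified"`.
#' @export
classify_cell <- function(traces, passive, amp_mv = 50, tau_ms = 5) {
  if (inherits(traces, "cc_trace")) traces <- list(traces)
  v_rest <- passive$v_rest
  has_spike <- any(purrr::map_lgl(traces, function(tr) {
    proto <- attr(tr, "protocol")
    sp <- detect_spikes(tr, v_rest,
                        window = c(proto$onset,
                                   proto$onset + proto$duration))
    if (!nrow(sp)) return(FALSE)
    m <- spike_metrics(tr, proto, v_rest)
    (m$v_peak - v_rest) >= amp_mv
  }))
  if (has_spike) return("neuron")
  if (is.finite(passive$tau0) && passive$tau0 < tau_ms) return("glia")
  "unclassified"
}

#' Recording-quality flags
#'
#' Applies the recording-termination and exclusion rules: `high_Ra` when
#' the initial access resistance exceeds 50 MOhm; `Ra_drift` when any later
#' estimate exceeds 1.5 times the initial value; `Vrest_drift` when the
#' resting potential strays more than 20 mV from its initial value;
#' `excluded_Rin` for input resistances above 500 GOhm; `movement` when
#' passed in from upstream artifact detection. Flags are monotone: a later,
#' worse sample can add but never remove a flag.
#'
#' @param ra_series Tibble `time_s`, `ra_mohm` of access-resistance
#'   estimates (time-ordered), or `NULL`.
#' @param vrest_series Tibble `time_s`, `v_rest_mv`, or `NULL`.
#' @param r_in Input resistance (MOhm), or `NULL`.
#' @param movement Logical from upstream artifact detection.
#' @param high_ra_mohm,ra_drift_factor,vrest_drift_mv,excluded_rin_mohm
#'   Rule thresholds.
#' @return Character vector of flags (possibly empty).
#' @export
qc_evaluate <- function(ra_series = NULL, vrest_series = NULL, r_in = NULL,
                        movement = FALSE, high_ra_mohm = 50,
                        ra_drift_factor = 1.5, vrest_drift_mv = 20,
                        excluded_rin_mohm = 5e5) {
  flags <- character()
  if (!is.null(ra_series) && nrow(ra_series)) {
    ra <- ra_series$ra_mohm
    if (ra[1] > high_ra_mohm) flags <- c(flags, "high_Ra")
    if (any(ra > ra_drift_factor * ra[1])) flags <- c(flags, "Ra_drift")
  }
  if (!is.null(vrest_series) && nrow(vrest_series)) {
    v <- vrest_series$v_rest_mv
    if (any(abs(v - v[1]) > vrest_drift_mv)) {
      flags <- c(flags, "Vrest_drift")
    }
  }
  if (!is.null(r_in) && is.finite(r_in) && r_in > excluded_rin_mohm) {
    flags <- c(flags, "excluded_Rin")
  }
  if (isTRUE(movement)) flags <- c(flags, "movement")
  flags
}

#' Cortical depth corrected for electrode angle
#'
#' The along-trajectory depth overestimates true cortical depth when the
#' electrode enters at an angle; the correction `depth * cos(angle)` is
#' reported by this helper and never applied silently.
#'
#' @param depth_um Trajectory length (micrometers).
#' @param angle_deg Electrode angle off the perpendicular (degrees).
#' @return Corrected depth (micrometers).
#' @export
corrected_depth <- function(depth_um, angle_deg) {
  depth_um * cos(angle_deg * pi / 180)
}

#' Assemble a cell record row
#'
#' Flattens per-cell results into the one-row tibble used by the cohort
#' tables. The firing-pattern label (regular-spiking etc.) follows an
#' external taxonomy and is carried as supplied text, never computed.
#'
#' @param cell_id Identifier.
#' @param species Species label.
#' @param cell_class From [classify_cell()].
#' @param passive A `cell_passive` or `NULL`.
#' @param spikes One-row tibble from [spike_metrics()] or `NULL` (glia
#'   records carry no spike metrics).
#' @param endpoint One-row tibble from [classify_endpoint()] or `NULL`.
#' @param qc_flags Character vector from [qc_evaluate()].
#' @param duration_min Recording duration (minutes).
#' @param depth_um Recording depth (micrometers).
#' @param firing_label External firing-pattern label (free text).
#' @param ra_mean,dra_dt Access-resistance mean (MOhm) and trend
#'   (MOhm/min), e.g. from [ra_trend()].
#' @return One-row tibble.
#' @export
cell_record <- function(cell_id, species = NA_character_,
                        cell_class = NA_character_, passive = NULL,
                        spikes = NULL, endpoint = NULL,
                        qc_flags = character(), duration_min = NA_real_,
                        depth_um = NA_real_, firing_label = NA_character_,
                        ra_mean = NA_real_, dra_dt = NA_real_) {
  if (identical(cell_class, "glia") && !is.null(spikes)) {
    abort("glia records carry no spike metrics")
  }
  endpoint_name <- endpoint$endpoint %||% NA_character_
  v_zap <- endpoint$v_zap %||% NA_real_
  t_zap <- endpoint$t_zap %||% NA_real_
  tibble(
    cell_id = cell_id, species = species, cell_class = cell_class,
    firing_label = firing_label,
    v_rest = passive$v_rest %||% NA_real_,
    tau0 = passive$tau0 %||% NA_real_,
    r_in = passive$r_in %||% NA_real_,
    r_a_error = passive$r_a_error %||% NA_real_,
    ra_mean = ra_mean, dra_dt = dra_dt,
    spike_dvdt_max = spikes$dvdt_max %||% NA_real_,
    spike_v_peak = spikes$v_peak %||% NA_real_,
    endpoint = endpoint_name, v_zap = v_zap, t_zap = t_zap,
    qc_flags = paste(qc_flags, collapse = ";"),
    duration_min = duration_min, depth_um = depth_um
  )
}
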
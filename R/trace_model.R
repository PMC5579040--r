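# Enumerations used throughout the package.
.NEURON_TYPES <- c("AVP", "VIP")
.PHASES <- c("day", "night")
.BUFFERS <- c("bicarbonate", "HEPES")
.EVENT_KINDS <- c("puff_isoguvacine", "bath_VU", "bath_bumetanide")

.TRACE_COLUMNS <- c("slice_id", "roi_id", "time_s", "f436", "f500",
                    "exposure500_ms", "is_background")
.EFFECT_COLUMNS <- c("slice_id", "roi_id", "neuron_type", "phase", "buffer",
                     "drug", "baseline_r", "post_r", "delta_r")

.stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Experimental condition of a slice recording
#'
#' A condition bundles the neuron population imaged (AVP+ or VIP+ cells
#' carrying the chloride indicator), the circadian phase the slice was taken
#' at, and the extracellular buffer. Phase is always stored categorically:
#' use [phase_from_zt()] to map a zeitgeber time onto the day/night windows
#' used for entrainment (day = ZT 2-8, night = ZT 12-18).
#'
#' @param neuron_type `"AVP"` or `"VIP"`.
#' @param phase `"day"` or `"night"`.
#' @param buffer `"bicarbonate"` (default) or `"HEPES"`.
#' @return An object of class `cl_condition`.
#' @examples
#' condition("AVP", "day")
#' condition("VIP", phase_from_zt(14), buffer = "HEPES")
#' @export
condition <- function(neuron_type, phase, buffer = "bicarbonate") {
  neuron_type <- match.arg(neuron_type, .NEURON_TYPES)
  phase <- match.arg(phase, .PHASES)
  buffer <- match.arg(buffer, .BUFFERS)
  structure(list(neuron_type = neuron_type, phase = phase, buffer = buffer),
            class = "cl_condition")
}

#' @rdname condition
#' @param zt Zeitgeber time in hours (ZT 0 = lights on).
#' @export
phase_from_zt <- function(zt) {
  stopifnot(is.numeric(zt), length(zt) == 1L, is.finite(zt))
  if (zt >= 2 && zt <= 8) return("day")
  if (zt >= 12 && zt <= 18) return("night")
  .stop_validation("ZT %.2f falls outside the day (ZT 2-8) and night (ZT 12-18) windows", zt)
}

#' @export
format.cl_condition <- function(x, ...) {
  sprintf("%s+ %s (%s)", x$neuron_type, x$phase, x$buffer)
}

#' @export
print.cl_condition <- function(x, ...) {
  cat("<condition>", format(x), "\n")
  invisible(x)
}

#' Single-ROI two-channel fluorescence trace
#'
#' The raw unit of data: intensities integrated over one region of interest
#' (a neuronal soma, or a dim background region) at each acquisition time, for
#' the two excitation wavelengths (436 nm and 500 nm). Exposure metadata is
#' carried because the steady-state ratio depends on the 500 nm exposure.
#'
#' @param slice_id,roi_id Identifiers (character scalars).
#' @param time_s Strictly increasing acquisition times in seconds; the
#'   sampling interval must be constant within a trace.
#' @param f436,f500 Non-negative intensities (arbitrary units), one per time
#'   point: emission after 436 nm and 500 nm excitation respectively.
#' @param exposure500_ms Positive 500 nm exposure duration in milliseconds.
#' @param is_background `TRUE` for the background ROI.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(slice_id, roi_id, time_s, f436, f500, exposure500_ms,
                      is_background = FALSE) {
  tr <- structure(list(slice_id = as.character(slice_id),
                       roi_id = as.character(roi_id),
                       time_s = as.numeric(time_s),
                       f436 = as.numeric(f436),
                       f500 = as.numeric(f500),
                       exposure500_ms = as.numeric(exposure500_ms),
                       is_background = isTRUE(is_background)),
                  class = "roi_trace")
  validate_roi_trace(tr)
  tr
}

validate_roi_trace <- function(tr) {
  id <- sprintf("slice '%s' roi '%s'", tr$slice_id, tr$roi_id)
  n <- length(tr$time_s)
  if (n < 2L)
    .stop_validation("%s: trace needs at least 2 samples", id)
  if (length(tr$f436) != n || length(tr$f500) != n)
    .stop_validation("%s: f436/f500 length differs from time_s", id)
  dt <- diff(tr$time_s)
  if (any(dt <= 0))
    .stop_validation("%s: time_s not strictly increasing (first violation at row %d)",
                     id, which(dt <= 0)[1] + 1L)
  if (diff(range(dt)) > 1e-6 * max(dt))
    .stop_validation("%s: sampling interval not constant", id)
  if (any(tr$f436 < 0, na.rm = TRUE) || any(tr$f500 < 0, na.rm = TRUE))
    .stop_validation("%s: negative raw intensities", id)
  if (!is.finite(tr$exposure500_ms) || tr$exposure500_ms <= 0)
    .stop_validation("%s: exposure500_ms must be positive", id)
  invisible(tr)
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("<roi_trace> %s/%s: %d samples, dt = %gs, exposure %g ms%s\n",
              x$slice_id, x$roi_id, length(x$time_s),
              if (length(x$time_s) > 1) diff(x$time_s[1:2]) else NA,
              x$exposure500_ms,
              if (x$is_background) " [background]" else ""))
  invisible(x)
}

#' Slice recording: all traces and events from one brain slice
#'
#' @param slice_id Identifier.
#' @param condition A [condition()] object (may be `NULL` when the manifest is
#'   not yet joined).
#' @param traces List of [roi_trace()] objects sharing one time base; exactly
#'   one must be flagged as background.
#' @param events Data frame with columns `kind`, `onset_s`, `offset_s`
#'   (`NA` offset means the event persists to the end of the recording, the
#'   normal case for bath application).
#' @return An object of class `slice_recording`.
#' @export
slice_recording <- function(slice_id, condition = NULL, traces = list(),
                            events = empty_events()) {
  rec <- structure(list(slice_id = as.character(slice_id),
                        condition = condition,
                        traces = traces,
                        events = events),
                   class = "slice_recording")
  validate_slice_recording(rec)
  rec
}

#' @rdname slice_recording
#' @export
empty_events <- function() {
  data.frame(kind = character(), onset_s = numeric(), offset_s = numeric(),
             stringsAsFactors = FALSE)
}

validate_slice_recording <- function(rec) {
  if (!length(rec$traces))
    .stop_validation("slice '%s': no traces", rec$slice_id)
  for (tr in rec$traces) {
    validate_roi_trace(tr)
    if (!identical(tr$slice_id, rec$slice_id))
      .stop_validation("slice '%s': trace roi '%s' carries slice_id '%s'",
                       rec$slice_id, tr$roi_id, tr$slice_id)
  }
  nbg <- sum(vapply(rec$traces, function(t) t$is_background, logical(1)))
  if (nbg != 1L)
    .stop_validation("slice '%s': expected exactly 1 background ROI, found %d",
                     rec$slice_id, nbg)
  tb <- rec$traces[[1]]$time_s
  for (tr in rec$traces[-1]) {
    if (length(tr$time_s) != length(tb) || max(abs(tr$time_s - tb)) > 1e-9)
      .stop_validation("slice '%s': roi '%s' does not share the slice time base",
                       rec$slice_id, tr$roi_id)
  }
  ids <- vapply(rec$traces, function(t) t$roi_id, character(1))
  if (anyDuplicated(ids))
    .stop_validation("slice '%s': duplicated roi_id '%s'",
                     rec$slice_id, ids[duplicated(ids)][1])
  if (nrow(rec$events)) {
    bad <- !rec$events$kind %in% .EVENT_KINDS
    if (any(bad))
      .stop_validation("slice '%s': unknown event kind '%s'",
                       rec$slice_id, rec$events$kind[bad][1])
    rng <- range(tb)
    out <- rec$events$onset_s < rng[1] | rec$events$onset_s > rng[2]
    if (any(out))
      .stop_validation("slice '%s': event onset %.1f s outside recording",
                       rec$slice_id, rec$events$onset_s[out][1])
  }
  invisible(rec)
}

#' @export
print.slice_recording <- function(x, ...) {
  cat(sprintf("<slice_recording> '%s': %d ROIs, %d events%s\n",
              x$slice_id, length(x$traces), nrow(x$events),
              if (is.null(x$condition)) "" else paste0(", ", format(x$condition))))
  invisible(x)
}

#' Background trace of a slice recording
#' @param rec A [slice_recording()].
#' @return The background [roi_trace()].
#' @export
background_trace <- function(rec) {
  i <- which(vapply(rec$traces, function(t) t$is_background, logical(1)))
  rec$traces[[i]]
}

#' Signal (non-background) traces of a slice recording
#' @param rec A [slice_recording()].
#' @return List of [roi_trace()] objects.
#' @export
signal_traces <- function(rec) {
  keep <- !vapply(rec$traces, function(t) t$is_background, logical(1))
  rec$traces[keep]
}

# Lossless numeric formatting: %.17g survives text round trips bit-exactly.
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.write_csv_lossless <- function(df, path, numeric_cols) {
  for (cl in numeric_cols) df[[cl]] <- .fmt_num(df[[cl]])
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                       eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read ROI traces from a tidy CSV
#'
#' The interchange format is one row per ROI per time point with columns
#' `slice_id, roi_id, time_s, f436, f500, exposure500_ms, is_background`.
#' A JSON manifest (see [read_manifest()]) optionally supplies each slice's
#' condition and event list.
#'
#' @param path CSV file path.
#' @param manifest Optional manifest list as returned by [read_manifest()].
#' @return Named list of [slice_recording()] objects, keyed by `slice_id`.
#' @export
read_traces <- function(path, manifest = NULL) {
  if (!file.exists(path))
    stop(sprintf("trace file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRACE_COLUMNS, names(df))
  if (length(missing))
    .stop_validation("trace CSV '%s' is missing column(s): %s",
                     path, paste(missing, collapse = ", "))
  if (!nrow(df)) return(structure(list(), names = character()))
  key <- paste(df$slice_id, df$roi_id, .fmt_num(df$time_s), sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    .stop_validation("duplicated (slice, roi, time) row: slice '%s' roi '%s' t=%g",
                     d$slice_id, d$roi_id, d$time_s)
  }
  recs <- list()
  for (sid in unique(df$slice_id)) {
    sdf <- df[df$slice_id == sid, , drop = FALSE]
    traces <- lapply(unique(sdf$roi_id), function(rid) {
      rdf <- sdf[sdf$roi_id == rid, , drop = FALSE]
      if (length(unique(rdf$exposure500_ms)) != 1L)
        .stop_validation("slice '%s' roi '%s': exposure500_ms varies within trace",
                         sid, rid)
      if (length(unique(rdf$is_background)) != 1L)
        .stop_validation("slice '%s' roi '%s': is_background varies within trace",
                         sid, rid)
      roi_trace(sid, rid, rdf$time_s, rdf$f436, rdf$f500,
                rdf$exposure500_ms[1],
                is_background = .as_flag(rdf$is_background[1]))
    })
    cond <- NULL
    events <- empty_events()
    if (!is.null(manifest) && sid %in% names(manifest$slices)) {
      m <- manifest$slices[[sid]]
      cond <- condition(m$neuron_type, m$phase, m$buffer)
      events <- m$events
    }
    recs[[sid]] <- slice_recording(sid, cond, traces, events)
  }
  recs
}

.as_flag <- function(x) {
  if (is.logical(x)) return(isTRUE(x))
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write ROI traces to a tidy CSV
#'
#' Numeric values are written with 17 significant digits so that
#' `read_traces(write_traces(x))` reproduces every double bit-exactly and a
#' second write is byte-identical to the first.
#'
#' @param recordings List of [slice_recording()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(recordings, path) {
  rows <- lapply(recordings, function(rec) {
    do.call(rbind, lapply(rec$traces, function(tr) {
      data.frame(slice_id = tr$slice_id, roi_id = tr$roi_id,
                 time_s = tr$time_s, f436 = tr$f436, f500 = tr$f500,
                 exposure500_ms = tr$exposure500_ms,
                 is_background = tr$is_background,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.TRACE_COLUMNS))),
                    .TRACE_COLUMNS)
  rownames(df) <- NULL
  .write_csv_lossless(df, path, c("time_s", "f436", "f500", "exposure500_ms"))
}

#' Build one drug-effect record
#'
#' An effect record stores the per-ROI change in the chloride-proxy ratio for
#' one intervention, together with the slice and condition labels that drive
#' clustered inference downstream.
#'
#' @param slice_id,roi_id Identifiers.
#' @param condition A [condition()].
#' @param drug Event kind (one of the recognised event kinds).
#' @param baseline_r,post_r Window summaries of the corrected ratio.
#' @param low_confidence Flag set when a window had > 20\% missing samples.
#' @return One-row data frame with the effect schema.
#' @export
effect_record <- function(slice_id, roi_id, condition, drug,
                          baseline_r, post_r, low_confidence = FALSE) {
  drug <- match.arg(drug, .EVENT_KINDS)
  data.frame(slice_id = slice_id, roi_id = roi_id,
             neuron_type = condition$neuron_type, phase = condition$phase,
             buffer = condition$buffer, drug = drug,
             baseline_r = baseline_r, post_r = post_r,
             delta_r = post_r - baseline_r,
             low_confidence = low_confidence,
             stringsAsFactors = FALSE)
}

validate_effects <- function(effects) {
  missing <- setdiff(.EFFECT_COLUMNS, names(effects))
  if (length(missing))
    .stop_validation("effects table missing column(s): %s",
                     paste(missing, collapse = ", "))
  bad <- abs(effects$delta_r - (effects$post_r - effects$baseline_r)) > 1e-9
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    i <- which(bad)[1]
    .stop_validation("effect row %d (slice '%s' roi '%s'): delta_r != post_r - baseline_r",
                     i, effects$slice_id[i], effects$roi_id[i])
  }
  invisible(effects)
}

#' Write / read drug-effect tables
#'
#' @param effects Data frame of effect records (rows from [effect_record()]).
#' @param path CSV path.
#' @return `path` invisibly for the writer; the validated data frame for the
#'   reader.
#' @export
write_effects <- function(effects, path) {
  if (is.null(effects) || !nrow(effects)) {
    effects <- effect_record("s", "r", condition("AVP", "day"),
                             "bath_VU", 0, 0)[0, ]
  }
  validate_effects(effects)
  .write_csv_lossless(effects, path, c("baseline_r", "post_r", "delta_r"))
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  if (!file.exists(path))
    stop(sprintf("effects file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_effects(df)
  df
}

#' Read / write a dataset manifest
#'
#' The manifest is a JSON sidecar mapping `slice_id` to its condition and
#' event list, e.g.
#' `{"slices": {"s1": {"neuron_type": "AVP", "phase": "day",
#' "buffer": "bicarbonate", "events": [{"kind": "bath_VU", "onset_s": 600}]}}}`.
#'
#' @param path JSON file path.
#' @return A list with element `slices`; each slice entry has `neuron_type`,
#'   `phase`, `buffer` and an `events` data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest '%s' does not exist", path), call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$slices))
    .stop_validation("manifest '%s' has no 'slices' entry", path)
  m$slices <- lapply(m$slices, function(s) {
    ev <- empty_events()
    if (length(s$events)) {
      ev <- do.call(rbind, lapply(s$events, function(e) {
        data.frame(kind = e$kind, onset_s = as.numeric(e$onset_s),
                   offset_s = if (is.null(e$offset_s)) NA_real_ else as.numeric(e$offset_s),
                   stringsAsFactors = FALSE)
      }))
    }
    list(neuron_type = s$neuron_type, phase = s$phase,
         buffer = if (is.null(s$buffer)) "bicarbonate" else s$buffer,
         events = ev)
  })
  m
}

#' @rdname read_manifest
#' @param recordings Named list of [slice_recording()] objects.
#' @export
write_manifest <- function(recordings, path) {
  slices <- lapply(recordings, function(rec) {
    ev <- lapply(seq_len(nrow(rec$events)), function(i) {
      e <- list(kind = rec$events$kind[i], onset_s = rec$events$onset_s[i])
      if (!is.na(rec$events$offset_s[i])) e$offset_s <- rec$events$offset_s[i]
      e
    })
    list(neuron_type = rec$condition$neuron_type,
         phase = rec$condition$phase,
         buffer = rec$condition$buffer,
         events = ev)
  })
  jsonlite::write_json(list(slices = slices), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
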
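# Mode timelines: ordered half-open [start, end) segments of functional
# ventilation category per ICU stay. All times are hours since ICU admission.

new_timeline <- function(stay_id, segments, invasive) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "category", "provenance") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) && any(segments$end <= segments$start))
    stop("timeline segments must satisfy start < end")
  structure(list(stay_id = stay_id, segments = segments,
                 invasive = invasive),
            class = "vs_timeline")
}

#' @export
print.vs_timeline <- function(x, ...) {
  cat("<vs_timeline> stay", x$stay_id, "-", nrow(x$segments), "segments,",
      nrow(x$invasive), "invasive interval(s)\n")
  print(x$segments, ...)
  invisible(x)
}

# merge adjacent segments sharing a category; keeps the provenance of the
# first (boundary-defining) segment of each run
coalesce_segments <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  run <- cumsum(c(TRUE, seg$category[-1] != seg$category[-nrow(seg)] |
                    seg$start[-1] != seg$end[-nrow(seg)]))
  out <- data.frame(
    start = tapply(seg$start, run, min),
    end = tapply(seg$end, run, max),
    category = seg$category[!duplicated(run)],
    provenance = seg$provenance[!duplicated(run)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

invasive_from_events <- function(airway_events, stay_end) {
  ev <- airway_events[order(airway_events$time), , drop = FALSE]
  ints <- ev$time[ev$event == "intubation"]
  exts <- ev$time[ev$event == "extubation"]
  if (!length(ints)) stop("no intubation event for stay")
  starts <- ints
  ends <- vapply(ints, function(s) {
    nxt <- exts[exts > s]
    if (length(nxt)) min(nxt) else stay_end
  }, numeric(1))
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Build a mode timeline from raw mode logs
#'
#' Carries each logged functional category forward until the next log,
#' extubation, or stay end. Periods outside invasive ventilation are labeled
#' `NONINVASIVE_OR_NONE`. If the first log of an invasive interval falls
#' after the interval start, its category is extended back to the interval
#' start so the timeline is contiguous over invasive periods.
#'
#' @param records data.frame with columns `time` (hours since admission) and
#'   `raw_label`, for one stay.
#' @param airway_events data.frame with columns `time`, `event`
#'   (`"intubation"` / `"extubation"`), for the same stay.
#' @param dialect Mode dialect used by [map_raw_mode()].
#' @param stay_end Stay end in hours (discharge or death); used to close
#'   open intervals and the trailing non-invasive segment.
#' @param stay_id Identifier stored on the timeline.
#' @param strict Passed to [map_raw_mode()].
#' @return A `vs_timeline` object.
#' @export
build_timeline <- function(records, airway_events, dialect,
                           stay_end = NULL, stay_id = NA, strict = FALSE) {
  if (is.null(stay_end)) {
    stay_end <- max(c(records$time, airway_events$time), 0) + 1e-9
  }
  invasive <- invasive_from_events(airway_events, stay_end)
  records <- records[order(records$time), , drop = FALSE]
  cat_logged <- if (nrow(records))
    map_raw_mode(records$raw_label, dialect, strict = strict) else character(0)

  seg_list <- list()
  for (k in seq_len(nrow(invasive))) {
    s <- invasive$start[k]; e <- invasive$end[k]
    inside <- which(records$time >= s & records$time < e)
    if (!length(inside)) {
      stop(structure(
        class = c("vs_missing_mode_data", "error", "condition"),
        list(message = sprintf(
          "no mode record inside invasive interval [%g, %g) for stay %s",
          s, e, stay_id), call = sys.call(-1))))
    }
    tt <- records$time[inside]
    cc <- cat_logged[inside]
    starts <- c(s, tt[-1])
    ends <- c(tt[-1], e)
    seg_list[[length(seg_list) + 1L]] <- data.frame(
      start = starts, end = ends, category = cc, provenance = "logged",
      stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg_list)
  seg <- seg[seg$end > seg$start, , drop = FALSE]

  # fill non-invasive gaps over [0, stay_end)
  gaps <- list()
  cursor <- 0
  bounds <- invasive[order(invasive$start), , drop = FALSE]
  for (k in seq_len(nrow(bounds))) {
    if (bounds$start[k] > cursor)
      gaps[[length(gaps) + 1L]] <- c(cursor, bounds$start[k])
    cursor <- max(cursor, bounds$end[k])
  }
  if (stay_end > cursor)
    gaps[[length(gaps) + 1L]] <- c(cursor, stay_end)
  if (length(gaps)) {
    g <- do.call(rbind, gaps)
    seg <- rbind(seg, data.frame(start = g[, 1], end = g[, 2],
                                 category = "NONINVASIVE_OR_NONE",
                                 provenance = "logged",
                                 stringsAsFactors = FALSE))
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  # one segment per log record: combined/CPAP reassignment acts per record,
  # so re-logged identical categories are left uncoalesced here (the
  # persistence filter coalesces runs later)
  new_timeline(stay_id, seg, invasive)
}

nearest_value <- function(times, values, at, tolerance) {
  if (!length(times)) return(NA_real_)
  d <- abs(times - at)
  i <- which.min(d)
  if (d[i] <= tolerance + 1e-9) values[i] else NA_real_
}

#' Reassign combined-mode segments by spontaneous respiratory rate
#'
#' Assist-control ("combined") modes allow patient-triggered breaths besides
#' mandatory breaths, so they are ambiguous between controlled and assisted
#' ventilation. Each `COMBINED` segment is reassigned to `ASSISTED` when the
#' spontaneous respiratory rate nearest in time to the segment start (within
#' `tolerance`) exceeds `rr_threshold` breaths/min, indicating active
#' patient effort, and to `CONTROLLED` otherwise. When no spontaneous rate
#' is available within tolerance the segment is conservatively classified
#' `CONTROLLED` (this avoids fabricating switch attempts). The total (set)
#' respiratory rate is never used as a substitute.
#'
#' @param timeline A `vs_timeline`.
#' @param spont_rr data.frame with columns `time`, `value`: spontaneous
#'   respiratory rate measurements for the stay.
#' @param rr_threshold Breaths/min; strictly above means assisted. Default 10.
#' @param tolerance Hours; nearest-measurement tolerance. Default 1.
#' @return The timeline with `COMBINED` segments reassigned (provenance
#'   `combined_reassigned`); segment boundaries are unchanged.
#' @export
reassign_combined <- function(timeline, spont_rr, rr_threshold = 10,
                              tolerance = 1) {
  seg <- timeline$segments
  idx <- which(seg$category == "COMBINED")
  for (i in idx) {
    rr <- nearest_value(spont_rr$time, spont_rr$value, seg$start[i], tolerance)
    seg$category[i] <- if (!is.na(rr) && rr > rr_threshold)
      "ASSISTED" else "CONTROLLED"
    seg$provenance[i] <- "combined_reassigned"
  }
  new_timeline(timeline$stay_id, seg, timeline$invasive)
}

#' Reassign CPAP segments by invasive-ventilation status
#'
#' CPAP delivered through an invasive airway is a spontaneous-breathing mode
#' and becomes `ASSISTED`; CPAP outside invasive ventilation becomes
#' `NONINVASIVE_OR_NONE`. A segment straddling an extubation is split at the
#' boundary and each part reassigned per its side.
#'
#' @inheritParams reassign_combined
#' @return The timeline with CPAP segments reassigned (provenance
#'   `cpap_reassigned`).
#' @export
reassign_cpap <- function(timeline) {
  seg <- timeline$segments
  inv <- timeline$invasive
  out <- list()
  for (i in seq_len(nrow(seg))) {
    if (seg$category[i] != "CPAP") {
      out[[length(out) + 1L]] <- seg[i, ]
      next
    }
    # split at invasive boundaries intersecting the segment
    cuts <- sort(unique(c(seg$start[i], seg$end[i],
                          inv$start[inv$start > seg$start[i] & inv$start < seg$end[i]],
                          inv$end[inv$end > seg$start[i] & inv$end < seg$end[i]])))
    for (k in seq_len(length(cuts) - 1L)) {
      s <- cuts[k]; e <- cuts[k + 1L]
      mid <- (s + e) / 2
      inside <- any(mid >= inv$start & mid < inv$end)
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e,
        category = if (inside) "ASSISTED" else "NONINVASIVE_OR_NONE",
        provenance = "cpap_reassigned", stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, out)
  new_timeline(timeline$stay_id, seg, timeline$invasive)
}

# left-to-right blip merging of one run sequence (single invasive interval);
# seg holds coalesced CONTROLLED/ASSISTED runs
merge_blips <- function(seg, min_duration) {
  repeat {
    seg <- coalesce_segments(seg)
    if (nrow(seg) < 2) return(seg)
    dur <- seg$end - seg$start
    # first interior/trailing run shorter than the minimum persistence
    cand <- which(dur < min_duration - 1e-9 & seq_len(nrow(seg)) > 1L)
    if (!length(cand)) return(seg)
    i <- cand[1L]
    seg$end[i - 1L] <- seg$end[i]
    seg <- seg[-i, , drop = FALSE]
  }
}

#' Filter out non-persistent mode transitions
#'
#' A transition to a new mode category counts only if the patient stays in
#' the new category for at least `min_duration` hours (inclusive). Shorter
#' runs -- e.g. an abrupt mode change to facilitate a procedure -- are merged
#' left-to-right into the surrounding category, re-checking after each
#' merge. The first run of each invasive interval is the starting mode, not
#' a transition, and is kept regardless of duration. The filter is
#' idempotent and never changes total covered time.
#'
#' @param timeline A `vs_timeline` whose invasive segments are already
#'   reassigned to `CONTROLLED` / `ASSISTED`.
#' @param min_duration Minimum persistence in hours. Default 1.
#' @return The filtered `vs_timeline`.
#' @export
persistence_filter <- function(timeline, min_duration = 1) {
  seg <- timeline$segments
  inv <- timeline$invasive
  out <- list()
  for (i in seq_len(nrow(seg))) {
    mid <- (seg$start[i] + seg$end[i]) / 2
    k <- which(mid >= inv$start & mid < inv$end)
    group <- if (length(k)) paste0("inv", k[1]) else "out"
    out[[length(out) + 1L]] <- cbind(seg[i, ], group = group)
  }
  seg <- do.call(rbind, out)
  pieces <- lapply(split(seg, seg$group), function(d) {
    d$group <- NULL
    if (d$category[1] %in% c("CONTROLLED", "ASSISTED"))
      merge_blips(d, min_duration) else coalesce_segments(d)
  })
  seg <- do.call(rbind, pieces)
  seg <- seg[order(seg$start), , drop = FALSE]
  new_timeline(timeline$stay_id, seg, timeline$invasive)
}

#' Export a timeline's segments as a data.frame
#'
#' @param timeline A `vs_timeline`.
#' @return data.frame with `stay_id`, `start`, `end`, `category`,
#'   `provenance`.
#' @export
timeline_segments <- function(timeline) {
  cbind(stay_id = timeline$stay_id, timeline$segments)
}
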
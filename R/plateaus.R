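#' Detect plateaus in a voltage trace
#'
#' Plateau segments are maximal intervals with `V >= threshold` lasting at
#' least `min_duration` ms. Crossing times are refined by linear
#' interpolation between samples, so measured durations are not quantized to
#' the output step. A segment still above threshold at the end of the trace
#' is flagged open-ended (its `t_off` is the trace end).
#'
#' @param trace an `exp2_trace` (or data frame with columns `t`, `V`).
#' @param threshold detection threshold, mV. The default -30 mV sits midway
#'   between rest (about -65 mV) and the plateau level (near +40 mV) and is
#'   robust to subthreshold EPSP stubs.
#' @param min_duration minimal segment length, ms.
#' @return an `exp2_segments` data frame with columns `t_on`, `t_off`,
#'   `duration`, `V_peak`, `open_ended`.
#' @export
detect_plateaus <- function(trace, threshold = -30, min_duration = 5) {
  t <- trace$t
  V <- trace$V
  n <- length(V)
  above <- V >= threshold
  if (!any(above)) return(empty_segments())
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  seg <- lapply(seq_along(starts), function(k) {
    i <- starts[k]; j <- ends[k]
    t_on <- if (i == 1L) t[1] else
      t[i - 1] + (threshold - V[i - 1]) / (V[i] - V[i - 1]) * (t[i] - t[i - 1])
    open <- j == n
    t_off <- if (open) t[n] else
      t[j] + (threshold - V[j]) / (V[j + 1] - V[j]) * (t[j + 1] - t[j])
    c(t_on = t_on, t_off = t_off, V_peak = max(V[i:j]), open = open)
  })
  seg <- as.data.frame(do.call(rbind, seg))
  out <- data.frame(t_on = seg$t_on, t_off = seg$t_off,
                    duration = seg$t_off - seg$t_on,
                    V_peak = seg$V_peak,
                    open_ended = as.logical(seg$open))
  out <- out[out$duration >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exp2_segments", "data.frame")
  out
}

empty_segments <- function() {
  out <- data.frame(t_on = numeric(), t_off = numeric(), duration = numeric(),
                    V_peak = numeric(), open_ended = logical())
  class(out) <- c("exp2_segments", "data.frame")
  out
}

#' Mean duration of closed plateaus
#'
#' Arithmetic mean of the durations of closed (not open-ended) segments.
#' Open-ended segments are excluded: they indicate a failure of rhythmicity
#' and drive the regime label instead of the duration statistics.
#'
#' @param segments an `exp2_segments` data frame.
#' @return a list with `mean` (ms; 0 when no closed segment exists), `n`,
#'   and `empty` (flag).
#' @export
mean_plateau_duration <- function(segments) {
  d <- segments$duration[!segments$open_ended]
  if (!length(d)) return(list(mean = 0, n = 0L, empty = TRUE))
  list(mean = mean(d), n = length(d), empty = FALSE)
}

#' Regime classification thresholds
#'
#' @param detect_threshold plateau detection threshold, mV.
#' @param min_duration minimal plateau length, ms.
#' @param amplitude_min minimal peak V (mV) for a full-amplitude plateau.
#' @param command_window_ms a segment ending within this window after a
#'   scheduled IPSP counts as terminated by command.
#' @param band_separation minimal separation of the two voltage bands of a
#'   two-level plateau, mV.
#' @param band_dwell_ms minimal dwell per band, ms.
#' @param activity_margin V must exceed rest by this much (mV) to count as
#'   activity for the low-amplitude label.
#' @return a list of thresholds.
#' @export
regime_thresholds <- function(detect_threshold = -30, min_duration = 5,
                              amplitude_min = 20, command_window_ms = 25,
                              band_separation = 20, band_dwell_ms = 50,
                              activity_margin = 10) {
  as.list(environment())
}

#' Classify the dynamical regime of a trace
#'
#' Labels a reference-protocol trace as one of `"unending"` (an open-ended
#' plateau spanning at least two stimulus periods: complete failure of
#' rhythmicity), `"two_level"` (a plateau dwelling in two sustained voltage
#' bands before final repolarization), `"physiological"` (full-amplitude
#' plateaus terminated on command by scheduled IPSPs), `"low_amplitude"`
#' (activity above rest that never reaches full plateau amplitude), or
#' `"quiescent"`.
#'
#' @param trace an `exp2_trace`.
#' @param schedule the `exp2_schedule` the trace was simulated under.
#' @param thresholds a [regime_thresholds()] list.
#' @return a single regime label (character).
#' @export
classify_regime <- function(trace, schedule, thresholds = regime_thresholds()) {
  th <- thresholds
  segs <- detect_plateaus(trace, th$detect_threshold, th$min_duration)
  ipsp_t <- schedule$t[schedule$kind == "IPSP"]
  epsp_t <- schedule$t[schedule$kind == "EPSP"]
  period <- if (length(epsp_t) >= 2L) min(diff(sort(epsp_t))) else
    attr(schedule, "t_total")

  if (any(segs$open_ended & segs$duration >= 2 * period)) return("unending")

  if (nrow(segs)) {
    closed <- segs[!segs$open_ended, , drop = FALSE]
    for (i in seq_len(nrow(closed))) {
      bands <- plateau_levels(trace, closed[i, ],
                              band_dwell_ms = th$band_dwell_ms,
                              band_separation = th$band_separation)
      if (!is.na(bands$upper) && !is.na(bands$lower)) return("two_level")
    }
    if (nrow(closed)) {
      commanded <- vapply(closed$t_off, function(toff)
        any(ipsp_t <= toff & toff <= ipsp_t + th$command_window_ms), TRUE)
      if (mean(commanded) >= 0.5 &&
          median(closed$V_peak) >= th$amplitude_min) return("physiological")
    }
  }

  # anything left with activity above rest (sub-threshold spikes, short or
  # low plateaus, erratic non-commanded activity) is the low-amplitude
  # continuum; truly flat traces are quiescent
  rest_V <- trace$V[1]
  if (max(trace$V) > rest_V + th$activity_margin) return("low_amplitude")
  "quiescent"
}

#' Voltage bands of a (possibly two-level) plateau
#'
#' Builds a dwell-time histogram of V within the segment (2 mV bins) and
#' finds local modes with at least `band_dwell_ms` of dwell. When two modes
#' at least `band_separation` mV apart exist, the segment is a two-level
#' plateau; the returned `upper` and `lower` are dwell-weighted mean
#' voltages within +/- 3 mV of the two extreme qualifying modes.
#'
#' @param trace an `exp2_trace`.
#' @param segment one row of [detect_plateaus()] output.
#' @param band_dwell_ms minimal dwell per band, ms.
#' @param band_separation minimal mode separation, mV.
#' @return list with `upper`, `lower` (mV; `NA` when no two-band structure).
#' @export
plateau_levels <- function(trace, segment, band_dwell_ms = 50,
                           band_separation = 20) {
  dt <- attr(trace, "dt_out")
  if (is.null(dt)) dt <- stats::median(diff(trace$t))
  m <- trace$t >= segment$t_on & trace$t <= segment$t_off
  v <- trace$V[m]
  if (!length(v)) return(list(upper = NA_real_, lower = NA_real_))
  breaks <- seq(floor(min(v)) - 2, ceiling(max(v)) + 2, by = 2)
  hcount <- tabulate(findInterval(v, breaks), nbins = length(breaks) - 1L)
  dwell <- hcount * dt
  is_mode <- vapply(seq_along(dwell), function(i) {
    lo <- max(1L, i - 2L); hi <- min(length(dwell), i + 2L)
    dwell[i] >= band_dwell_ms && dwell[i] == max(dwell[lo:hi]) && dwell[i] > 0
  }, TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  modes <- centers[is_mode]
  if (length(modes) < 2L || diff(range(modes)) < band_separation)
    return(list(upper = NA_real_, lower = NA_real_))
  band_mean <- function(mode) mean(v[abs(v - mode) <= 3])
  list(upper = band_mean(max(modes)), lower = band_mean(min(modes)))
}

#' Wedge hyperpolarization depth of a plateau
#'
#' With slow K-current inactivation, plateaus develop a transient "wedge"
#' hyperpolarization after the initial peak, caused by the overlap of
#' activation and still-decaying inactivation gating. The depth is measured
#' as the difference between the initial local maximum of V (within the
#' first `peak_window_ms` of the segment) and the subsequent local minimum
#' preceding recovery. A plateau whose V merely relaxes monotonically (no
#' recovery after the minimum beyond `recover_min` mV) has depth 0.
#'
#' A wedge is recognized in two forms: a dip followed by recovery of at
#' least `recover_min` mV (the usual case), or -- when inactivation is so
#' slow that the wedge drives the cell onto a sustained lower level and no
#' recovery occurs -- a fast drop of at least `deep_drop_min` mV to a flat
#' level. The slow L-type-driven relaxation of a healthy plateau (a few mV,
#' no recovery, never flat-after-fast-fall by 20 mV) is thereby excluded.
#'
#' @param trace an `exp2_trace`.
#' @param segment one row of [detect_plateaus()] output.
#' @param peak_window_ms window for the initial peak, ms.
#' @param search_window_ms window after the peak searched for the wedge
#'   minimum, ms.
#' @param recover_min minimal post-minimum recovery (mV) for a recovering
#'   wedge to count; guards against counting the slow L-type relaxation.
#' @param deep_drop_min minimal drop (mV) for a non-recovering wedge onto a
#'   sustained lower level.
#' @return wedge depth, mV (>= 0).
#' @export
wedge_depth <- function(trace, segment, peak_window_ms = 50,
                        search_window_ms = 150, recover_min = 1,
                        deep_drop_min = 20) {
  m <- trace$t >= segment$t_on & trace$t <= segment$t_off
  tt <- trace$t[m]; v <- trace$V[m]
  if (length(v) < 5L) return(0)
  # initial peak: the first local maximum inside the peak window (the
  # upstroke peak, possibly blunted by slow inactivation), found as the
  # running maximum at the moment V first falls 0.5 mV below it
  win <- which(tt <= segment$t_on + peak_window_ms)
  i_peak <- win[1]
  for (i in win) {
    if (v[i] > v[i_peak]) i_peak <- i
    if (v[i_peak] - v[i] >= 0.5) break
  }
  idx <- which(seq_along(v) > i_peak & tt <= tt[i_peak] + search_window_ms)
  if (!length(idx)) return(0)
  # first local minimum after the peak: walk forward tracking the running
  # minimum until V recovers recover_min above it (so the later slow L-type
  # relaxation cannot mask a small early wedge)
  i_min <- idx[1]
  recovered <- FALSE
  for (i in idx) {
    if (v[i] < v[i_min]) i_min <- i
    if (v[i] - v[i_min] >= recover_min) { recovered <- TRUE; break }
  }
  if (recovered) return(max(0, v[i_peak] - v[i_min]))
  # no recovery: count only a deep fast drop onto a flat lower level
  i_min <- idx[which.min(v[idx])]
  depth <- max(0, v[i_peak] - v[i_min])
  later <- which(seq_along(v) > i_min)
  flat_win <- later[tt[later] <= tt[i_min] + 50]
  flat <- length(flat_win) > 3L && diff(range(v[flat_win])) < 2
  if (flat && depth >= deep_drop_min) depth else 0
}

#' Tabulate plateau segments with shape features
#'
#' Convenience table combining [detect_plateaus()] output with
#' [wedge_depth()], commanded-termination flags and the trace regime.
#'
#' @param trace an `exp2_trace`.
#' @param schedule the schedule the trace was simulated under.
#' @param thresholds a [regime_thresholds()] list.
#' @return data frame with one row per segment: `t_on`, `t_off`, `duration`,
#'   `V_peak`, `wedge_depth`, `commanded`, `open_ended`, `regime`.
#' @export
segments_table <- function(trace, schedule, thresholds = regime_thresholds()) {
  th <- thresholds
  segs <- detect_plateaus(trace, th$detect_threshold, th$min_duration)
  regime <- classify_regime(trace, schedule, th)
  ipsp_t <- schedule$t[schedule$kind == "IPSP"]
  if (!nrow(segs)) {
    out <- cbind(as.data.frame(segs),
                 wedge_depth = numeric(), commanded = logical(),
                 regime = character())
    return(out)
  }
  segs$wedge_depth <- vapply(seq_len(nrow(segs)), function(i)
    wedge_depth(trace, segs[i, ]), 0)
  segs$commanded <- vapply(segs$t_off, function(toff)
    any(ipsp_t <= toff & toff <= ipsp_t + th$command_window_ms), TRUE)
  segs$regime <- regime
  as.data.frame(segs)
}
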
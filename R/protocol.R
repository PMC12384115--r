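#' Five-segment breathing protocol
#'
#' The 150 s trial protocol: 30 s normal breathing, a breath hold (~5 s
#' inhalation then ~25 s hold), 30 s normal breathing, 30 s of deep breathing,
#' and a final 30 s of normal breathing. Segments are contiguous half-open
#' intervals `[start, end)` on a time axis starting at 0.
#'
#' @param normal_s Duration of each normal-breathing segment, s.
#' @param inhale_lead_s Inhalation lead within the breath-hold segment, s.
#' @param hold_s Breath-hold duration after the inhalation, s.
#' @param deep_s Deep-breathing duration, s.
#' @return Object of class `breathing_protocol`: a tibble with columns
#'   `label`, `start_s`, `end_s` plus an `inhale_lead_s` attribute.
#' @examples
#' breathing_protocol()
#' @export
breathing_protocol <- function(normal_s = 30, inhale_lead_s = 5, hold_s = 25,
                               deep_s = 30) {
  if (any(c(normal_s, inhale_lead_s, hold_s, deep_s) <= 0)) {
    stop("all protocol durations must be positive", call. = FALSE)
  }
  bh <- inhale_lead_s + hold_s
  durations <- c(normal_s, bh, normal_s, deep_s, normal_s)
  labels <- c("normal1", "breath_hold", "normal2", "deep_breathing", "normal3")
  ends <- cumsum(durations)
  out <- tibble(
    label = labels,
    start_s = c(0, head(ends, -1)),
    end_s = ends
  )
  attr(out, "inhale_lead_s") <- inhale_lead_s
  class(out) <- c("breathing_protocol", class(out))
  out
}

#' Total protocol duration in seconds
#' @param protocol A [breathing_protocol()].
#' @return Scalar duration, s.
#' @export
protocol_duration <- function(protocol) {
  max(protocol$end_s)
}

#' Segment label for each time point
#'
#' Assigns each sample time to its protocol segment using half-open
#' `[start, end)` intervals; times at or beyond the protocol end get `NA`.
#'
#' @param time_s Numeric vector of times, s.
#' @param protocol A [breathing_protocol()].
#' @return Factor of segment labels, levels in protocol order.
#' @export
segment_of <- function(time_s, protocol) {
  idx <- findInterval(time_s, c(protocol$start_s, max(protocol$end_s)),
                      rightmost.closed = FALSE)
  idx[time_s < 0 | time_s >= max(protocol$end_s)] <- NA_integer_
  factor(protocol$label[idx], levels = protocol$label)
}

#' Per-segment sample masks for a trace
#'
#' @param trace Data frame with a `time_s` column covering the full protocol.
#' @param protocol A [breathing_protocol()].
#' @return Named list of logical masks (one per segment) that tile the trace.
#' @export
segment_masks <- function(trace, protocol) {
  t <- trace$time_s
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  if (max(t) + dt < protocol_duration(protocol) - 1e-9) {
    stop(sprintf("trace ends at %.2f s but the protocol runs to %.2f s",
                 max(t) + dt, protocol_duration(protocol)), call. = FALSE)
  }
  seg <- segment_of(t, protocol)
  masks <- lapply(protocol$label, function(lb) !is.na(seg) & seg == lb)
  names(masks) <- protocol$label
  masks
}

#' Sample time grid for one trial
#' @param protocol A [breathing_protocol()].
#' @param sampling_rate_hz Sampling rate, Hz.
#' @return Numeric vector of sample times starting at 0, s.
#' @export
protocol_time_grid <- function(protocol, sampling_rate_hz = 2.24) {
  n <- floor(protocol_duration(protocol) * sampling_rate_hz)
  (seq_len(n) - 1) / sampling_rate_hz
}
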
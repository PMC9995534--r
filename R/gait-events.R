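#' Detect heel-strike events from marker trajectories
#'
#' A heel strike is taken as a local maximum of a heel marker's AP
#' position relative to the AP position of the posterior-hip midpoint
#' (the foot is maximally forward relative to the pelvis at contact).
#' Candidate maxima from the two feet are merged in time and forced to
#' alternate: of two consecutive same-foot candidates the more forward
#' one is kept. Event detection can be bypassed entirely by supplying an
#' externally produced event table to the downstream functions.
#'
#' @param trial a [gait_trial()].
#' @param min_amplitude minimum peak-to-peak excursion (mm) of the
#'   heel-relative-to-hip signal below which the trial is considered
#'   motionless and no events are returned.
#' @return An object of class `gait_events`: data.frame with columns
#'   `foot`, `time`, `index` (sample index), ordered by time with
#'   alternating feet.
#' @export
detect_heel_strikes <- function(trial, min_amplitude = 1) {
  stopifnot(inherits(trial, "gait_trial"))
  hip_ap <- (trial$markers$hip_l_ap + trial$markers$hip_r_ap) / 2
  cand <- list()
  for (f in c("left", "right")) {
    sig <- trial$markers[[paste0("heel_", substr(f, 1, 1), "_ap")]] - hip_ap
    if (diff(range(sig)) < min_amplitude) next
    n <- length(sig)
    i <- 2:(n - 1L)
    is_max <- sig[i] > sig[i - 1L] & sig[i] >= sig[i + 1L]
    pk <- i[is_max]
    if (length(pk))
      cand[[f]] <- data.frame(foot = f, time = trial$time[pk], index = pk,
                              height = sig[pk], stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, cand)
  if (is.null(ev) || !all(c("left", "right") %in% ev$foot) ||
      min(table(ev$foot)) < 2L)
    stop("no gait events: no alternating heel-strike pattern detected",
         call. = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  # enforce alternation: among consecutive same-foot candidates keep the
  # most forward one
  keep <- rep(TRUE, nrow(ev))
  last_kept <- 1L
  for (j in seq_len(nrow(ev))[-1]) {
    if (ev$foot[j] == ev$foot[last_kept]) {
      if (ev$height[j] > ev$height[last_kept]) {
        keep[last_kept] <- FALSE
        last_kept <- j
      } else keep[j] <- FALSE
    } else last_kept <- j
  }
  ev <- ev[keep, c("foot", "time", "index")]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Single-stance intervals implied by alternating heel strikes
#'
#' The single-stance interval of the foot striking at event *i* runs from
#' that strike to the next contralateral strike (no toe-off events are
#' available, so early double support is included; the interval always
#' lies between consecutive contralateral events). The last event has no
#' complete interval and gets `NA`.
#'
#' @param events a `gait_events` table.
#' @return data.frame: foot, start, end (s); `end` is `NA` for the final event.
#' @export
single_stance_intervals <- function(events) {
  n <- nrow(events)
  end <- c(events$time[-1], NA_real_)
  # guard: only a contralateral follow-up closes the interval
  same <- c(events$foot[-1] == events$foot[-n], FALSE)
  end[same] <- NA_real_
  data.frame(foot = events$foot, start = events$time, end = end,
             stringsAsFactors = FALSE)
}

interp_at <- function(time, values, at) {
  if (any(at < time[1] | at > time[length(time)]))
    stop("event time outside trial range", call. = FALSE)
  approx(time, values, xout = at)$y
}
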
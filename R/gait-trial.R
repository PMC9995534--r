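#' Construct a gait trial
#'
#' A time-indexed set of marker trajectories for one subject and condition:
#' left/right heel and left/right posterior-hip markers, each with a
#' mediolateral (ML) and anteroposterior (AP) coordinate in mm, plus the ML
#' center-of-pressure trace. The midpoint of the two posterior-hip markers
#' serves as the body center-of-mass (CoM) proxy throughout. ML sign
#' convention: positive is toward the slow-belt (right) side.
#'
#' @param time strictly increasing time vector (s).
#' @param heel_l_ml,heel_l_ap,heel_r_ml,heel_r_ap heel trajectories (mm).
#' @param hip_l_ml,hip_l_ap,hip_r_ml,hip_r_ap posterior-hip trajectories (mm).
#' @param cop_ml ML center-of-pressure trace (mm), or `NULL` if absent.
#' @param condition condition label, e.g. `"baseline_slow"`, `"split"`.
#' @param belt_speed_slow,belt_speed_fast belt speeds (m/s).
#' @param fast_foot which foot walks on the fast belt (`"left"` here).
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(time, heel_l_ml, heel_l_ap, heel_r_ml, heel_r_ap,
                       hip_l_ml, hip_l_ap, hip_r_ml, hip_r_ap,
                       cop_ml = NULL, condition = "split",
                       belt_speed_slow = 0.7, belt_speed_fast = 1.4,
                       fast_foot = "left") {
  n <- length(time)
  traces <- list(heel_l_ml = heel_l_ml, heel_l_ap = heel_l_ap,
                 heel_r_ml = heel_r_ml, heel_r_ap = heel_r_ap,
                 hip_l_ml = hip_l_ml, hip_l_ap = hip_l_ap,
                 hip_r_ml = hip_r_ml, hip_r_ap = hip_r_ap)
  lens <- vapply(traces, length, integer(1))
  if (any(lens != n))
    stop("all trajectories must have the same length as `time`", call. = FALSE)
  if (!is.null(cop_ml) && length(cop_ml) != n)
    stop("`cop_ml` must have the same length as `time`", call. = FALSE)
  if (n < 2L || any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  structure(list(time = time, markers = as.data.frame(traces),
                 cop_ml = cop_ml, condition = condition,
                 belt_speed_slow = belt_speed_slow,
                 belt_speed_fast = belt_speed_fast,
                 fast_foot = fast_foot),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial: condition '%s', %.1f s at %.0f Hz, CoP %s\n",
              x$condition, diff(range(x$time)),
              1 / stats::median(diff(x$time)),
              if (is.null(x$cop_ml)) "absent" else "present"))
  invisible(x)
}

#' Read / write gait trials as wide CSV
#'
#' The wide layout has one row per sample and one column per marker-axis
#' (`time`, `heel_l_ml`, ..., `cop_ml`); condition and belt speeds travel
#' in commented header lines.
#'
#' @param trial a `gait_trial`.
#' @param path CSV file path.
#' @return `write_gait_trial_csv()` returns the path invisibly;
#'   `read_gait_trial_csv()` returns a `gait_trial`.
#' @export
write_gait_trial_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition=%s belt_slow=%g belt_fast=%g fast_foot=%s",
                     trial$condition, trial$belt_speed_slow,
                     trial$belt_speed_fast, trial$fast_foot), con)
  df <- cbind(time = trial$time, trial$markers)
  if (!is.null(trial$cop_ml)) df$cop_ml <- trial$cop_ml
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_trial_csv
#' @export
read_gait_trial_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- list(condition = "split", belt_slow = 0.7, belt_fast = 1.4,
               fast_foot = "left")
  if (startsWith(hdr, "#")) {
    kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L) meta[[p[1]]] <- p[2]
    }
  }
  df <- read.csv(path, comment.char = "#")
  gait_trial(time = df$time,
             heel_l_ml = df$heel_l_ml, heel_l_ap = df$heel_l_ap,
             heel_r_ml = df$heel_r_ml, heel_r_ap = df$heel_r_ap,
             hip_l_ml = df$hip_l_ml, hip_l_ap = df$hip_l_ap,
             hip_r_ml = df$hip_r_ml, hip_r_ap = df$hip_r_ap,
             cop_ml = if ("cop_ml" %in% names(df)) df$cop_ml else NULL,
             condition = meta$condition,
             belt_speed_slow = as.numeric(meta$belt_slow),
             belt_speed_fast = as.numeric(meta$belt_fast),
             fast_foot = meta$fast_foot)
}
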
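#' Build a dynamic-PET frame schedule from duration blocks
#'
#' Dynamic brain PET acquisitions are rebinned into frames of increasing
#' duration. A schedule is specified as a list of blocks, each a pair
#' `(duration_s, n_frames)`, and expanded into contiguous frames starting
#' at injection time (t = 0).
#'
#' @param blocks A list of length-2 numeric vectors `c(duration_s, count)`,
#'   or a 2-column matrix/data.frame with durations in the first column and
#'   repeat counts in the second. Durations are in seconds.
#' @return A `frame_schedule` data frame with columns `frame_start`,
#'   `frame_end`, `frame_mid` and `frame_duration`, all in seconds.
#' @examples
#' # A 90-min protocol: 10 s x 6, 20 s x 3, 1 min x 6, 3 min x 4, 5 min x 14
#' sched <- build_frame_schedule(list(
#'   c(10, 6), c(20, 3), c(60, 6), c(180, 4), c(300, 14)
#' ))
#' nrow(sched)                     # 33 frames
#' max(sched$frame_end) / 60       # 90 minutes
#' @export
build_frame_schedule <- function(blocks) {
  if (is.matrix(blocks) || is.data.frame(blocks)) {
    blocks <- lapply(seq_len(nrow(blocks)), function(i) as.numeric(blocks[i, 1:2]))
  }
  if (!is.list(blocks) || length(blocks) == 0L) {
    stop("`blocks` must be a non-empty list of (duration, count) pairs")
  }
  durations <- vapply(blocks, function(b) as.numeric(b[[1]]), numeric(1))
  counts <- vapply(blocks, function(b) as.numeric(b[[2]]), numeric(1))
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all frame durations must be finite and > 0")
  }
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("all repeat counts must be integers >= 1")
  }
  frame_duration <- rep(durations, times = counts)
  frame_end <- cumsum(frame_duration)
  frame_start <- c(0, frame_end[-length(frame_end)])
  out <- data.frame(
    frame_start = frame_start,
    frame_end = frame_end,
    frame_mid = (frame_start + frame_end) / 2,
    frame_duration = frame_duration
  )
  class(out) <- c("frame_schedule", "data.frame")
  validate_frame_schedule(out)
  out
}

validate_frame_schedule <- function(x) {
  stopifnot(
    is.data.frame(x),
    all(c("frame_start", "frame_end", "frame_mid", "frame_duration") %in% names(x))
  )
  if (nrow(x) == 0L) stop("frame schedule has no frames")
  if (x$frame_start[1] != 0) stop("first frame must start at t = 0")
  if (any(x$frame_duration <= 0)) stop("frame durations must be > 0")
  if (nrow(x) > 1L &&
      any(abs(x$frame_end[-nrow(x)] - x$frame_start[-1]) > 1e-9)) {
    stop("frames must be contiguous: end[i] == start[i + 1]")
  }
  if (any(diff(x$frame_mid) <= 0)) stop("frame mid-times must be strictly increasing")
  invisible(x)
}

#' The default 90-minute, 33-frame acquisition schedule
#'
#' Convenience constructor for the dynamic schedule used throughout the
#' package defaults: 10 s x 6, 20 s x 3, 1 min x 6, 3 min x 4 and
#' 5 min x 14, spanning 5400 s.
#'
#' @return A `frame_schedule` with 33 frames.
#' @export
default_frame_schedule <- function() {
  build_frame_schedule(list(c(10, 6), c(20, 3), c(60, 6), c(180, 4), c(300, 14)))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, 0-%g s (%.1f min)\n",
              nrow(x), max(x$frame_end), max(x$frame_end) / 60))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more frames\n", nrow(x) - 6L))
  invisible(x)
}

#' Per-frame weights for nonlinear least-squares fitting
#'
#' Frame weights control the relative influence of frames in weighted NLS
#' fits. `uniform` gives every frame equal weight; `duration` weights
#' proportionally to frame length (longer frames accumulate more counts);
#' `duration_decay` additionally down-weights late frames for physical
#' decay, `w_i` proportional to `dt_i * exp(-lambda * t_mid_i)` with
#' `lambda = log(2) / half_life`. Weights are normalised to mean 1 so that
#' weighted residual sums stay on the scale of the unweighted fit.
#'
#' @param schedule A `frame_schedule` (or a TAC, whose schedule is used).
#' @param scheme One of `"uniform"`, `"duration"`, `"duration_decay"`.
#' @param half_life Isotope half-life in seconds; required for
#'   `duration_decay`. For carbon-11 use `20.4 * 60`.
#' @return Numeric vector of nonnegative weights with mean 1.
#' @export
frame_weights <- function(schedule,
                          scheme = c("duration", "uniform", "duration_decay"),
                          half_life = 20.4 * 60) {
  if (inherits(schedule, "tac")) schedule <- schedule$schedule
  validate_frame_schedule(schedule)
  scheme <- match.arg(scheme)
  w <- switch(scheme,
    uniform = rep(1, nrow(schedule)),
    duration = schedule$frame_duration,
    duration_decay = {
      if (!is.numeric(half_life) || half_life <= 0) {
        stop("`half_life` must be a positive number of seconds")
      }
      lambda <- log(2) / half_life
      schedule$frame_duration * exp(-lambda * schedule$frame_mid)
    }
  )
  w / mean(w)
}
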
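#' Parametrization schedule container
#'
#' Maps every trajectory frame to the LVC anchor that serves it.
#'
#' @param anchor_times anchor times (fs), strictly increasing
#' @param assignment per-frame anchor index (1-based into `anchor_times`)
#' @param times per-frame times (fs)
#' @param mode "fixed", "bisection" or "rmsd-adaptive"
#' @param threshold RMSD threshold (angstrom) for adaptive mode
#' @return object of class `param_schedule`
#' @export
param_schedule <- function(anchor_times, assignment, times,
                           mode = c("fixed", "bisection", "rmsd-adaptive"),
                           threshold = NA_real_) {
  mode <- match.arg(mode)
  anchor_times <- as.numeric(anchor_times)
  if (is.unsorted(anchor_times, strictly = TRUE))
    .stopf("anchor times must be strictly increasing")
  assignment <- as.integer(assignment)
  if (length(assignment) != length(times))
    .stopf("assignment and times differ in length")
  if (any(assignment < 1L) || any(assignment > length(anchor_times)))
    .stopf("assignment indices out of range")
  structure(list(anchor_times = anchor_times, assignment = assignment,
                 times = as.numeric(times), mode = mode,
                 threshold = threshold),
            class = "param_schedule")
}

#' @export
print.param_schedule <- function(x, ...) {
  cat(sprintf("Parametrization schedule (%s): %d anchors over %d frames\n",
              x$mode, length(x$anchor_times), length(x$times)))
  cat("  anchors (fs):", paste(format(x$anchor_times), collapse = ", "), "\n")
  if (!is.na(x$threshold)) cat(sprintf("  RMSD threshold: %g A\n", x$threshold))
  invisible(x)
}

## nearest anchor in time; ties broken toward the earlier anchor
.assign_nearest <- function(times, anchor_times) {
  vapply(times, function(t) {
    d <- abs(anchor_times - t)
    which(d <= min(d) + 1e-12)[1]
  }, 1L)
}

#' Fixed-interval parametrization schedule
#'
#' Anchors at t0, t0 + interval, ... up to t_end; every frame is assigned
#' to its nearest anchor in time (an anchor predicts both forward and
#' backward), ties going to the earlier anchor.
#'
#' @param t0,t_end window limits (fs)
#' @param interval anchor spacing (fs, > 0)
#' @param times frame times (fs); defaults to the 1 fs grid over the window
#' @return a [param_schedule()]
#' @export
fixed_schedule <- function(t0, t_end, interval, times = NULL) {
  if (t_end < t0) .stopf("empty window: t_end < t0")
  if (interval <= 0) .stopf("interval must be positive")
  if (is.null(times)) times <- seq(t0, t_end, by = 1)
  anchors <- seq(t0, t_end, by = interval)
  param_schedule(anchors, .assign_nearest(times, anchors), times,
                 mode = "fixed")
}

#' Bisection-refined parametrization schedule
#'
#' Depth 0 anchors the two window ends; every further depth adds the
#' midpoint of each current interval (rounded onto the frame grid), so the
#' maximum anchor spacing roughly halves per increment.
#'
#' @param t0,t_end window limits (fs)
#' @param depth number of bisection passes (>= 0)
#' @param times frame times (fs); defaults to the 1 fs grid
#' @return a [param_schedule()]
#' @export
bisection_schedule <- function(t0, t_end, depth = 0L, times = NULL) {
  if (t_end <= t0) .stopf("empty window: t_end <= t0")
  if (depth < 0) .stopf("depth must be >= 0")
  if (is.null(times)) times <- seq(t0, t_end, by = 1)
  snap <- function(t) times[which.min(abs(times - t))]
  anchors <- c(t0, t_end)
  for (i in seq_len(depth)) {
    mids <- vapply(seq_len(length(anchors) - 1L), function(j)
      snap((anchors[j] + anchors[j + 1L]) / 2), 0)
    anchors <- sort(unique(c(anchors, mids)))
  }
  param_schedule(anchors, .assign_nearest(times, anchors), times,
                 mode = "bisection")
}

#' RMSD-threshold adaptive parametrization schedule
#'
#' Walks the trajectory from the first frame (the first anchor).  Each time
#' the Kabsch RMSD to the current reference geometry first reaches the
#' threshold counts as a crossing.  Because an LVC model predicts backward
#' as well as forward, reparametrization is needed only at every other
#' crossing: at odd crossings only the RMSD reference geometry moves to the
#' crossing frame; at even crossings a new anchor is created there and
#' becomes both the reference and the active model.  Frames are assigned to
#' their nearest anchor in time.
#'
#' @param frames list of [traj_frame()] in strictly increasing time order
#' @param threshold RMSD threshold (angstrom, > 0); reached means
#'   `rmsd >= threshold` up to a 1e-9 relative tolerance
#' @param rmsd_fn function(frame, reference_frame) -> RMSD; defaults to
#'   [kabsch_rmsd()] with the given mask
#' @param mask optional site subset for the default RMSD
#' @return a [param_schedule()]
#' @export
adaptive_schedule <- function(frames, threshold, rmsd_fn = NULL, mask = NULL) {
  if (threshold <= 0) .stopf("threshold must be positive")
  times <- vapply(frames, `[[`, 0, "time")
  if (any(diff(times) <= 0)) .stopf("frame times must be strictly increasing")
  if (is.null(rmsd_fn))
    rmsd_fn <- function(a, b) kabsch_rmsd(a, b, mask = mask)
  anchors <- times[1]
  ref <- frames[[1]]
  crossings <- 0L
  for (i in seq_along(frames)[-1]) {
    r <- rmsd_fn(frames[[i]], ref)
    if (r >= threshold * (1 - 1e-9)) {
      crossings <- crossings + 1L
      ref <- frames[[i]]
      if (crossings %% 2L == 0L) anchors <- c(anchors, times[i])
    }
  }
  param_schedule(anchors, .assign_nearest(times, anchors), times,
                 mode = "rmsd-adaptive", threshold = threshold)
}

#' Serialize / read a schedule as JSON
#'
#' @param schedule a [param_schedule()]
#' @param path file path
#' @return writer: `path` invisibly; reader: a [param_schedule()]
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(
    list(mode = schedule$mode, threshold = schedule$threshold,
         anchor_times = schedule$anchor_times, times = schedule$times,
         assignment = schedule$assignment),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  param_schedule(obj$anchor_times, obj$assignment, obj$times,
                 mode = obj$mode,
                 threshold = obj$threshold %||% NA_real_)
}
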
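# Per-animal locomotion measures: instantaneous speed, filtered median
# speed, path lengths, head-swinging index.
#
# All measures are step-based. A step joins two consecutive frames and is
# usable only when both endpoint frames are valid; steps touching a tracking
# gap are excised, never interpolated — bridging a gap would fabricate path
# length and bias the head-swinging index.

# Internal per-step table shared by kinematics and pirouette detection.
step_table <- function(track) {
  stopifnot(inherits(track, "worm_track"))
  fr <- track$frames
  if (nrow(fr) < 2) stop("insufficient data: track has fewer than 2 frames")
  m <- nrow(fr) - 1L
  dx <- diff(fr$cx); dy <- diff(fr$cy)
  dhx <- diff(fr$hx); dhy <- diff(fr$hy)
  dur <- diff(fr$time)
  valid <- fr$valid[-(m + 1L)] & fr$valid[-1L]
  disp <- sqrt(dx^2 + dy^2)
  hdisp <- sqrt(dhx^2 + dhy^2)
  data.frame(t0 = fr$time[-(m + 1L)], t1 = fr$time[-1L], dur = dur,
             dx = dx, dy = dy, disp = disp, hdisp = hdisp,
             speed = disp / dur, valid = valid)
}

n_valid_frames <- function(track) sum(track$frames$valid)

#' Instantaneous speed series
#'
#' Frame-to-frame centroid displacement divided by the actual inter-frame
#' interval, one value per step. Steps touching an invalid (gap) frame are
#' flagged `step_valid = FALSE` and carry no usable speed.
#'
#' @param track A [worm_track()] with at least 2 valid frames.
#' @return A data frame of class `speed_series` with columns `t0`, `t1`,
#'   `speed` (mm/s) and `step_valid`; one row per inter-frame step.
#' @export
instantaneous_speeds <- function(track) {
  if (n_valid_frames(track) < 2) {
    stop("insufficient data: fewer than 2 valid frames")
  }
  st <- step_table(track)
  out <- data.frame(t0 = st$t0, t1 = st$t1, speed = st$speed,
                    step_valid = st$valid)
  out$speed[!out$step_valid] <- NA_real_
  attr(out, "animal_id") <- track$animal_id
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Filtered median speed
#'
#' Median of the instantaneous speeds over valid steps, after excluding
#' immobility (steps slower than `immobility_threshold`; 0.2 mm/s, i.e.
#' 0.02 cm/s, by default — exclusion is strict `<`, so a step at exactly the
#' threshold is kept). If no step survives the filter the animal is flagged
#' immobile rather than given a median of zero.
#'
#' @param series A [instantaneous_speeds()] result.
#' @param immobility_threshold Immobility cutoff, mm/s.
#' @return The median speed in mm/s, or `NA` carrying attribute
#'   `immobile = TRUE` when every valid step is below the cutoff.
#' @export
median_speed <- function(series, immobility_threshold = 0.2) {
  stopifnot(inherits(series, "speed_series"))
  if (nrow(series) == 0 || !any(series$step_valid)) {
    stop("insufficient data: no valid steps in speed series")
  }
  keep <- series$step_valid & series$speed >= immobility_threshold
  if (!any(keep)) {
    return(structure(NA_real_, immobile = TRUE))
  }
  stats::median(series$speed[keep])
}

#' Path length of the centroid or head track
#'
#' Summed Euclidean step distance over steps whose both endpoint frames are
#' valid. Steps spanning a gap contribute nothing: the gap is excised, not
#' bridged.
#'
#' @param track A [worm_track()] with at least 2 valid frames.
#' @param which `"centroid"` or `"head"`.
#' @return Path length in mm.
#' @export
track_length <- function(track, which = c("centroid", "head")) {
  which <- match.arg(which)
  if (n_valid_frames(track) < 2) {
    stop("insufficient data: fewer than 2 valid frames")
  }
  st <- step_table(track)
  d <- if (which == "centroid") st$disp else st$hdisp
  sum(d[st$valid])
}

#' Head-swinging index
#'
#' Head-track length divided by centroid-track length, computed over the
#' identical step-validity mask for numerator and denominator. Values above
#' 1 quantify the extra path traced by lateral head oscillation
#' (klinotaxis-style head-swinging); a head rigidly leading a straight-moving
#' centroid gives exactly 1.
#'
#' @param track A [worm_track()] with at least 2 valid frames.
#' @return Dimensionless index (> 0). Signals an error of class
#'   `nematrack_undefined_index` when the centroid track length is zero, so
#'   callers can flag (not silently drop) the animal.
#' @export
head_swinging_index <- function(track) {
  if (n_valid_frames(track) < 2) {
    stop("insufficient data: fewer than 2 valid frames")
  }
  st <- step_table(track)
  cl <- sum(st$disp[st$valid])
  hl <- sum(st$hdisp[st$valid])
  if (!(cl > 0)) {
    stop(structure(class = c("nematrack_undefined_index", "error",
                             "condition"),
                   list(message = sprintf(
                     "head-swinging index undefined for '%s': centroid track length is zero",
                     track$animal_id), call = sys.call(-1))))
  }
  hl / cl
}

#' Moving-average track smoother
#'
#' Optional centred moving average applied independently to each run of
#' consecutive valid frames (gaps are respected, not bridged; runs shorter
#' than the window are averaged over what is available). Positional jitter
#' inflates both path lengths, so smoothing can be useful on noisy data —
#' but it also erodes genuine head oscillation, which is why no analysis
#' applies it by default.
#'
#' @param track A [worm_track()].
#' @param window Odd window length in frames (default 5).
#' @return A new `worm_track` with smoothed coordinates; the applied window
#'   is recorded in attribute `"smoothed"`.
#' @export
smooth_track <- function(track, window = 5) {
  stopifnot(inherits(track, "worm_track"))
  if (window < 1 || window %% 2 != 1) stop("window must be a positive odd integer")
  half <- (window - 1) / 2
  fr <- track$frames
  runs <- rle(fr$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  smooth_run <- function(v, s, e) {
    idx <- s:e
    n <- length(idx)
    out <- v[idx]
    if (n > 1) {
      cs <- c(0, cumsum(v[idx]))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    out
  }
  for (r in which(runs$values)) {
    s <- starts[r]; e <- ends[r]
    for (col in c("cx", "cy", "hx", "hy")) {
      fr[[col]][s:e] <- smooth_run(fr[[col]], s, e)
    }
  }
  out <- track
  out$frames <- fr
  attr(out, "smoothed") <- window
  message(sprintf("track '%s': applied moving-average smoothing, window = %d frames",
                  track$animal_id, window))
  out
}

#' Per-animal kinematic summary table
#'
#' Runs the whole per-animal kinematics pipeline over a list of tracks:
#' instantaneous speeds, immobility-filtered median speed, centroid and head
#' path lengths, head-swinging index, and the per-animal outlier flag
#' (median speed above `max_speed` — 0.5 mm/s by default, the speed ceiling
#' above which plate trackers lose the animal and data are discarded).
#' Animals whose head-swinging index is undefined are flagged via `NA`, not
#' dropped.
#'
#' @param tracks A `worm_track` or list of them.
#' @param immobility_threshold Passed to [median_speed()] (mm/s).
#' @param max_speed Outlier cutoff on the per-animal median speed (mm/s).
#' @return A data frame of class `kinematic_summary`, one row per animal:
#'   `animal_id, species, stage, condition, median_speed, immobile,
#'   centroid_track_length, head_track_length, head_swinging_index,
#'   n_valid_steps, excluded_as_outlier`.
#' @export
summarize_kinematics <- function(tracks, immobility_threshold = 0.2,
                                 max_speed = 0.5) {
  if (inherits(tracks, "worm_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    sp <- instantaneous_speeds(tr)
    ms <- median_speed(sp, immobility_threshold)
    immobile <- isTRUE(attr(ms, "immobile"))
    hsi <- tryCatch(head_swinging_index(tr),
                    nematrack_undefined_index = function(e) NA_real_)
    data.frame(animal_id = tr$animal_id, species = tr$species,
               stage = tr$stage, condition = tr$condition,
               median_speed = as.numeric(ms), immobile = immobile,
               centroid_track_length = track_length(tr, "centroid"),
               head_track_length = track_length(tr, "head"),
               head_swinging_index = hsi,
               n_valid_steps = sum(sp$step_valid),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$excluded_as_outlier <- !is.na(out$median_speed) &
    out$median_speed > max_speed
  rownames(out) <- NULL
  class(out) <- c("kinematic_summary", "data.frame")
  out
}

#' Partition animals by the tracker speed ceiling
#'
#' Splits a kinematic summary into animals kept and animals excluded as
#' outliers: individuals whose median speed is strictly above `max_speed`
#' (500 um/s by default) are removed, because trajectories that fast cannot
#' be tracked reliably. A median speed of exactly `max_speed` is kept
#' ("up to" the ceiling is trackable).
#'
#' @param summaries A [summarize_kinematics()] table.
#' @param max_speed Cutoff on the per-animal median speed, mm/s.
#' @return A list with elements `kept` and `excluded`; exclusions are
#'   reported via `message()` with the animal ids.
#' @export
apply_outlier_filter <- function(summaries, max_speed = 0.5) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0) {
    return(list(kept = summaries, excluded = summaries))
  }
  out <- !is.na(summaries$median_speed) & summaries$median_speed > max_speed
  if (any(out)) {
    message(sprintf("excluding %d animal(s) with median speed > %.3g mm/s: %s",
                    sum(out), max_speed,
                    paste(summaries$animal_id[out], collapse = ", ")))
  }
  list(kept = summaries[!out, , drop = FALSE],
       excluded = summaries[out, , drop = FALSE])
}
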
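# Pirouette (sharp-reorientation) detection from centroid trajectories.
#
# A pirouette is operationalised as a cumulative turning angle exceeding
# 120 degrees within a 3-s window, with a concurrent speed drop of >= 40%
# relative to the animal's 2-s pre-event baseline. Detection uses the
# centroid only: lateral head oscillation must not enter the turning signal.

# Wrap angles (degrees) into (-180, 180].
wrap_deg <- function(x) {
  w <- x %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

#' Per-step heading and turn-increment series
#'
#' Step headings are taken from the atan2 of the centroid displacement.
#' Steps whose displacement falls below `min_step` are masked: at jitter
#' scale the direction of motion is numerically meaningless and would
#' generate spurious turning. Turn increments are wrapped successive heading
#' differences, masked whenever either contributing heading is masked.
#'
#' @param track A [worm_track()] with at least 3 valid frames.
#' @param min_step Minimum step displacement (mm) for a defined heading.
#' @return A data frame of class `heading_series` with one row per step:
#'   `t0, t1, heading` (degrees in (-180, 180], `NA` when masked), `defined`
#'   (heading usable), `turn` (signed increment vs the previous step,
#'   degrees, `NA` when masked).
#' @export
heading_series <- function(track, min_step = 0.01) {
  if (n_valid_frames(track) < 3) {
    stop("insufficient data: fewer than 3 valid frames")
  }
  st <- step_table(track)
  m <- nrow(st)
  defined <- st$valid & is.finite(st$disp) & st$disp >= min_step
  heading <- rep(NA_real_, m)
  heading[defined] <- atan2(st$dy[defined], st$dx[defined]) * 180 / pi
  turn <- rep(NA_real_, m)
  if (m >= 2) {
    ok <- defined[-1] & defined[-m]
    turn[-1][ok] <- wrap_deg(heading[-1][ok] - heading[-m][ok])
  }
  out <- data.frame(t0 = st$t0, t1 = st$t1, heading = heading,
                    defined = defined, turn = turn)
  attr(out, "animal_id") <- track$animal_id
  attr(out, "min_step") <- min_step
  class(out) <- c("heading_series", "data.frame")
  out
}

#' Detect pirouette events
#'
#' Scans every sub-interval of contiguous usable steps whose duration is at
#' most `window`. A candidate fires when the cumulative turning angle over
#' the sub-interval exceeds `angle_threshold` in magnitude AND the
#' time-weighted mean speed over the sub-interval is at most
#' `(1 - drop_threshold)` times the mean speed over the `baseline` seconds
#' immediately preceding the sub-interval start. Overlapping or abutting
#' candidates — and candidates separated by less than `merge_gap` seconds —
#' describe a single behavioural event and are merged; the reported event
#' takes the bounds and statistics of the merged cluster's
#' maximal-`|net_turn|` candidate (ties broken by the larger speed drop,
#' then the earlier start), which prevents one omega-turn from being counted
#' twice.
#'
#' "Cumulative turning angle" is, by default, the magnitude of the net
#' signed sum of wrapped heading increments (`mode = "net"`): a sum of
#' absolute increments would fire on vigorous oscillation without any
#' reorientation. The sum-of-absolutes reading is available as
#' `mode = "absolute"` for comparison; results should state which mode was
#' used.
#'
#' Candidates whose baseline interval has fewer than `min_baseline_frac` of
#' its steps valid (e.g. at the very start of a track, or across a long gap)
#' are skipped, not errors.
#'
#' @param track A [worm_track()] holding at least `baseline + window`
#'   seconds of valid data.
#' @param window Maximum event duration, s.
#' @param angle_threshold Turning-angle threshold, degrees.
#' @param drop_threshold Required fractional speed drop vs baseline.
#' @param baseline Pre-event baseline duration, s (anchored immediately
#'   before the candidate window start).
#' @param min_step Heading displacement floor (mm), see [heading_series()].
#' @param min_duration Minimum candidate duration, s. Windows shorter than
#'   this are never considered: a pirouette is an extended reorientation
#'   manoeuvre, whereas an apparent near-instant heading flip at plate-camera
#'   resolution is positional jitter. The default (0.8 s) is well below any
#'   plausible reorientation time yet long enough that jitter cannot sustain
#'   both the turning and the speed-drop criterion across the window.
#' @param mode `"net"` (default) or `"absolute"` cumulative turning.
#' @param merge_gap Events closer than this (s) are merged.
#' @param min_baseline_frac Minimum fraction of valid baseline steps.
#' @return A data frame of class `pirouette_events`, one row per event,
#'   sorted by `t_start`: `t_start, t_end, net_turn` (signed degrees),
#'   `baseline_speed, event_speed` (mm/s), `speed_drop` (fraction) and
#'   `n_candidates` merged into the event. Attributes record the animal id
#'   and the detection settings.
#' @export
detect_pirouettes <- function(track, window = 3, angle_threshold = 120,
                              drop_threshold = 0.40, baseline = 2,
                              min_step = 0.01, min_duration = 0.8,
                              mode = c("net", "absolute"),
                              merge_gap = 1, min_baseline_frac = 0.5) {
  mode <- match.arg(mode)
  st <- step_table(track)
  if (sum(st$dur[st$valid]) < baseline + window) {
    stop(sprintf("insufficient data: track '%s' holds < %.3g s of valid data",
                 track$animal_id, baseline + window))
  }
  hs <- heading_series(track, min_step = min_step)
  m <- nrow(st)

  # Runs of steps with defined headings; a candidate window must lie inside
  # one run so that every turn increment it needs is defined.
  r <- rle(hs$defined)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  run_id[!hs$defined] <- NA_integer_

  inc <- hs$turn
  inc[is.na(inc)] <- 0
  if (mode == "absolute") inc <- abs(inc)
  cuminc <- c(0, cumsum(inc))               # cuminc[s+1] = sum inc[1..s]
  cumsp <- c(0, cumsum(ifelse(st$valid, st$speed * st$dur, 0)))

  # Vectorised baseline over [t0 - baseline, t0): mean speed over valid
  # steps starting in that interval.
  vs <- c(0, cumsum(ifelse(st$valid, st$speed * st$dur, 0)))
  vt <- c(0, cumsum(ifelse(st$valid, st$dur, 0)))
  vn <- c(0, cumsum(as.numeric(st$valid)))
  lo <- findInterval(st$t0 - baseline - 1e-9, st$t0) + 1L
  i_all <- seq_len(m)
  nb_valid <- vn[i_all] - vn[lo]            # valid steps in [lo, i-1]
  nb_time <- vt[i_all] - vt[lo]
  nb_speedsum <- vs[i_all] - vs[lo]
  n_expected <- max(1, round(baseline / track$nominal_dt))
  base_ok <- i_all > 1 & nb_valid >= min_baseline_frac * n_expected &
    nb_valid >= 1 & nb_time > 0
  base_speed <- ifelse(base_ok, nb_speedsum / pmax(nb_time, 1e-300), NA_real_)

  pos_dur <- st$dur[st$dur > 0]
  k_max <- if (length(pos_dur) > 0) min(m, ceiling(window / min(pos_dur)) + 1L) else 1L

  cand <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    i <- seq_len(m - k + 1L)
    j <- i + k - 1L
    ok <- !is.na(run_id[i]) & !is.na(run_id[j]) & run_id[i] == run_id[j]
    dur_ij <- st$t1[j] - st$t0[i]
    ok <- ok & dur_ij <= window + 1e-9 & dur_ij >= min_duration - 1e-9
    if (!any(ok)) next
    net <- cuminc[j + 1L] - cuminc[i + 1L]  # sum of increments i+1..j
    evspd <- (cumsp[j + 1L] - cumsp[i]) / dur_ij
    sel <- ok & abs(net) > angle_threshold & base_ok[i] &
      evspd <= (1 - drop_threshold) * base_speed[i] + 1e-12
    if (any(sel)) {
      cand[[k]] <- data.frame(i = i[sel], j = j[sel], net = net[sel],
                              event_speed = evspd[sel],
                              baseline_speed = base_speed[i[sel]])
    }
  }
  cand <- do.call(rbind, cand)

  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      net_turn = numeric(0), baseline_speed = numeric(0),
                      event_speed = numeric(0), speed_drop = numeric(0),
                      n_candidates = integer(0))
  events <- if (is.null(cand) || nrow(cand) == 0) {
    empty
  } else {
    cand$t_start <- st$t0[cand$i]
    cand$t_end <- st$t1[cand$j]
    cand <- cand[order(cand$t_start, cand$t_end), , drop = FALSE]
    cluster <- integer(nrow(cand))
    cur_end <- -Inf
    cid <- 0L
    for (q in seq_len(nrow(cand))) {
      if (cand$t_start[q] - cur_end >= merge_gap) {
        cid <- cid + 1L
        cur_end <- cand$t_end[q]
      } else {
        cur_end <- max(cur_end, cand$t_end[q])
      }
      cluster[q] <- cid
    }
    rows <- lapply(split(seq_len(nrow(cand)), cluster), function(qs) {
      drop_q <- 1 - cand$event_speed[qs] / cand$baseline_speed[qs]
      # round |net| so float noise cannot decide ties between candidates
      # whose turning content is identical
      best <- qs[order(-round(abs(cand$net[qs]), 9), -drop_q,
                       cand$t_start[qs])[1]]
      data.frame(t_start = cand$t_start[best], t_end = cand$t_end[best],
                 net_turn = cand$net[best],
                 baseline_speed = cand$baseline_speed[best],
                 event_speed = cand$event_speed[best],
                 speed_drop = 1 - cand$event_speed[best] /
                   cand$baseline_speed[best],
                 n_candidates = length(qs))
    })
    out <- do.call(rbind, rows)
    out[order(out$t_start), , drop = FALSE]
  }
  rownames(events) <- NULL
  attr(events, "animal_id") <- track$animal_id
  attr(events, "settings") <- list(window = window,
                                   angle_threshold = angle_threshold,
                                   drop_threshold = drop_threshold,
                                   baseline = baseline, min_step = min_step,
                                   min_duration = min_duration,
                                   mode = mode, merge_gap = merge_gap,
                                   min_baseline_frac = min_baseline_frac)
  class(events) <- c("pirouette_events", "data.frame")
  events
}

#' @export
print.pirouette_events <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<pirouette_events> %s: %d event(s) [%s cumulative turning, >%g deg in %g s, >=%g%% speed drop]\n",
              attr(x, "animal_id"), nrow(x), s$mode, s$angle_threshold,
              s$window, 100 * s$drop_threshold))
  if (nrow(x) > 0) print.data.frame(x, ...)
  invisible(x)
}

#' Per-animal pirouette rate
#'
#' Events per minute of observed (valid-step) time: the denominator is the
#' total time spanned by valid steps, so tracking gaps do not deflate the
#' rate.
#'
#' @param track The [worm_track()] the events came from.
#' @param events A [detect_pirouettes()] result for the same track; when
#'   `NULL`, detection is run with `...` passed through.
#' @param ... Detection settings forwarded to [detect_pirouettes()].
#' @return A one-row data frame: `animal_id, species, condition, n_events,
#'   observed_minutes, rate`.
#' @export
pirouette_rate <- function(track, events = NULL, ...) {
  stopifnot(inherits(track, "worm_track"))
  if (is.null(events)) events <- detect_pirouettes(track, ...)
  st <- step_table(track)
  minutes <- sum(st$dur[st$valid]) / 60
  if (minutes <= 0) stop("insufficient data: no valid observation time")
  data.frame(animal_id = track$animal_id, species = track$species,
             condition = track$condition, n_events = nrow(events),
             observed_minutes = minutes, rate = nrow(events) / minutes,
             stringsAsFactors = FALSE)
}

#' Per-animal behaviour table for a track ensemble
#'
#' Convenience wrapper running the full per-animal pipeline — kinematic
#' summary plus pirouette detection and rate — over a list of tracks,
#' returning one tidy row per animal ready for [compare_conditions()].
#' Tracks too short for detection get `NA` event fields (with a warning).
#'
#' @param tracks A list of [worm_track()] objects.
#' @param immobility_threshold,max_speed Passed to [summarize_kinematics()].
#' @param ... Detection settings forwarded to [detect_pirouettes()].
#' @return A data frame with the kinematic summary columns plus `n_events,
#'   observed_minutes, pirouette_rate`.
#' @export
summarize_behavior <- function(tracks, immobility_threshold = 0.2,
                               max_speed = 0.5, ...) {
  if (inherits(tracks, "worm_track")) tracks <- list(tracks)
  kin <- summarize_kinematics(tracks,
                              immobility_threshold = immobility_threshold,
                              max_speed = max_speed)
  pir <- lapply(tracks, function(tr) {
    tryCatch(pirouette_rate(tr, ...),
             error = function(e) {
               warning(sprintf("track '%s': %s", tr$animal_id,
                               conditionMessage(e)))
               data.frame(animal_id = tr$animal_id, species = tr$species,
                          condition = tr$condition, n_events = NA_integer_,
                          observed_minutes = NA_real_, rate = NA_real_,
                          stringsAsFactors = FALSE)
             })
  })
  pir <- do.call(rbind, pir)
  kin$n_events <- pir$n_events[match(kin$animal_id, pir$animal_id)]
  kin$observed_minutes <- pir$observed_minutes[match(kin$animal_id,
                                                     pir$animal_id)]
  kin$pirouette_rate <- pir$rate[match(kin$animal_id, pir$animal_id)]
  kin
}
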
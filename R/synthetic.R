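# Correlated-random-walk simulator for worm tracks and multinomial plate
# endpoints. The generator provides ground truth for parameter-recovery
# tests; the ground-truth metadata rides on the track object but is never
# consulted by the analysis functions.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generative parameters for a synthetic worm
#'
#' Describes one species' locomotion as a correlated random walk: a
#' lognormal AR(1) crawling speed, heading that integrates Gaussian turning
#' noise, occasional pirouette reorientations injected as a Poisson process,
#' and a head tip that leads the centroid and oscillates laterally.
#'
#' @param name Label attached to tracks generated from these parameters.
#' @param mean_speed Mean crawling speed, mm/s.
#' @param speed_cv Coefficient of variation of the lognormal speed process
#'   (0 gives constant speed).
#' @param speed_ar1 Lag-1 autocorrelation of log speed, in `[0, 1)`.
#' @param heading_diffusion Baseline turning-noise variance, degrees^2 per
#'   second.
#' @param head_offset Distance the head tip leads the centroid along the
#'   heading, mm.
#' @param head_amp Lateral head-oscillation amplitude, mm.
#' @param head_freq Head-oscillation frequency, Hz.
#' @param pirouette_rate Pirouette event rate, events per minute.
#' @param pirouette_turn Mean net reorientation per pirouette, degrees. The
#'   realised magnitude is Gaussian with 10% relative sd, truncated below at
#'   130 degrees so injected events sit clearly above the 120-degree
#'   detection threshold rather than straddling it.
#' @param pirouette_duration Duration of one pirouette, seconds.
#' @param pirouette_speed_factor Speed multiplier during a pirouette, in
#'   `[0, 1)`.
#' @param gap_prob Per-frame probability of a tracking dropout.
#' @param noise_sd Isotropic positional jitter sd added to centroid and head,
#'   mm.
#' @return An object of class `species_params`.
#' @seealso [species_preset()], [simulate_track()]
#' @export
species_params <- function(name = "custom",
                           mean_speed = 0.3, speed_cv = 0.25, speed_ar1 = 0.8,
                           heading_diffusion = 60,
                           head_offset = 0.5, head_amp = 0.08, head_freq = 0.4,
                           pirouette_rate = 1, pirouette_turn = 160,
                           pirouette_duration = 1,
                           pirouette_speed_factor = 0.45,
                           gap_prob = 0.01, noise_sd = 0.005) {
  p <- list(name = as.character(name), mean_speed = mean_speed,
            speed_cv = speed_cv, speed_ar1 = speed_ar1,
            heading_diffusion = heading_diffusion, head_offset = head_offset,
            head_amp = head_amp, head_freq = head_freq,
            pirouette_rate = pirouette_rate, pirouette_turn = pirouette_turn,
            pirouette_duration = pirouette_duration,
            pirouette_speed_factor = pirouette_speed_factor,
            gap_prob = gap_prob, noise_sd = noise_sd)
  nonneg <- c("mean_speed", "speed_cv", "heading_diffusion", "head_offset",
              "head_amp", "head_freq", "pirouette_rate", "pirouette_turn",
              "pirouette_duration")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || p[[f]] < 0) {
      stop(sprintf("'%s' must be a single non-negative number", f))
    }
  }
  if (p$speed_ar1 < 0 || p$speed_ar1 >= 1) stop("speed_ar1 must be in [0, 1)")
  if (p$pirouette_speed_factor < 0 || p$pirouette_speed_factor >= 1) {
    stop("pirouette_speed_factor must be in [0, 1)")
  }
  if (p$gap_prob < 0 || p$gap_prob >= 1) stop("gap_prob must be in [0, 1)")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(p, class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s\n", x$name))
  cat(sprintf("  speed: %.3g mm/s (cv %.2g, ar1 %.2g); heading diffusion %.3g deg^2/s\n",
              x$mean_speed, x$speed_cv, x$speed_ar1, x$heading_diffusion))
  cat(sprintf("  head: offset %.3g mm, amp %.3g mm at %.3g Hz\n",
              x$head_offset, x$head_amp, x$head_freq))
  cat(sprintf("  pirouettes: %.3g /min, %.3g deg over %.3g s, speed x%.2g\n",
              x$pirouette_rate, x$pirouette_turn, x$pirouette_duration,
              x$pirouette_speed_factor))
  cat(sprintf("  gap_prob %.3g, noise_sd %.3g mm\n", x$gap_prob, x$noise_sd))
  invisible(x)
}

#' Shipped species presets
#'
#' Two parameter sets encoding the qualitative species contrast the package
#' is built around: the "elegans"-like worm crawls faster, swings its head
#' little, and pirouettes regularly; the "inopinata"-like worm crawls more
#' slowly, shows large-amplitude higher-frequency head-swinging, and
#' pirouettes only very rarely. Absolute values are chosen to be realistic
#' for adult worms on agar plates; only the ordinal relations between the two
#' presets are asserted by the validation suite.
#'
#' @param name `"elegans"` or `"inopinata"`.
#' @return A [species_params()] object.
#' @export
species_preset <- function(name = c("elegans", "inopinata")) {
  name <- match.arg(name)
  switch(name,
    elegans = species_params(
      name = "elegans", mean_speed = 0.30, speed_cv = 0.25, speed_ar1 = 0.8,
      heading_diffusion = 60, head_offset = 0.5,
      head_amp = 0.08, head_freq = 0.4,
      pirouette_rate = 1.0, pirouette_turn = 160, pirouette_duration = 1,
      pirouette_speed_factor = 0.45, gap_prob = 0.01, noise_sd = 0.005),
    inopinata = species_params(
      name = "inopinata", mean_speed = 0.15, speed_cv = 0.25, speed_ar1 = 0.8,
      heading_diffusion = 60, head_offset = 0.5,
      head_amp = 0.15, head_freq = 0.6,
      pirouette_rate = 0.05, pirouette_turn = 160, pirouette_duration = 1,
      pirouette_speed_factor = 0.45, gap_prob = 0.01, noise_sd = 0.005))
}

#' Simulate one worm track
#'
#' Generates a correlated random walk: the heading integrates Gaussian
#' turning noise with variance `heading_diffusion * dt` per step, plus
#' pirouette reorientations at Poisson rate `pirouette_rate` — each adds a
#' net signed turn of random sign and truncated-Gaussian magnitude around
#' `pirouette_turn`, spread uniformly over `pirouette_duration`, while the
#' speed is multiplied by `pirouette_speed_factor`. Step speed follows a
#' lognormal AR(1) with mean `mean_speed`. The head tip equals the centroid
#' plus `head_offset` along the heading plus a lateral sinusoid of amplitude
#' `head_amp` and frequency `head_freq` with random phase. Independent
#' Gaussian jitter of sd `noise_sd` is added to both positions, and frames
#' drop out independently with probability `gap_prob`.
#'
#' The realised event schedule, together with the generating parameters, is
#' attached as ground-truth metadata (`$truth`) for recovery tests; no
#' analysis function reads it.
#'
#' @param params A [species_params()] object.
#' @param duration Track duration, seconds (at least `2 * dt`).
#' @param dt Frame interval, seconds (default 0.1 s, i.e. 10 fps — typical
#'   for plate-scale worm tracking).
#' @param seed Integer seed fixing the full realisation.
#' @param animal_id,condition Metadata for the resulting track.
#' @return A [worm_track()] with `species = params$name`.
#' @export
simulate_track <- function(params, duration = 600, dt = 0.1, seed = 1,
                           animal_id = paste0(params$name, "_1"),
                           condition = "control") {
  stopifnot(inherits(params, "species_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (!is.numeric(duration) || duration < 2 * dt) {
    stop("duration must be at least 2 * dt")
  }
  n <- round(duration / dt)        # number of steps; n + 1 frames
  times <- seq(0, by = dt, length.out = n + 1)

  with_seed(seed, {
    # lognormal AR(1) step speeds with mean mean_speed
    if (params$speed_cv > 0 && params$mean_speed > 0) {
      sigma <- sqrt(log(1 + params$speed_cv^2))
      mu <- log(params$mean_speed) - sigma^2 / 2
      phi <- params$speed_ar1
      e <- stats::rnorm(n)
      z <- numeric(n)
      z[1] <- sigma * e[1]
      if (n > 1) {
        innov_sd <- sigma * sqrt(1 - phi^2)
        for (i in 2:n) z[i] <- phi * z[i - 1] + innov_sd * e[i]
      }
      speed <- exp(mu + z)
    } else {
      speed <- rep(params$mean_speed, n)
    }

    # pirouette schedule: homogeneous Poisson process on [0, duration)
    lambda <- params$pirouette_rate / 60
    n_ev <- stats::rpois(1, lambda * duration)
    ev_start <- sort(stats::runif(n_ev, 0, duration))
    ev_sign <- sample(c(-1, 1), n_ev, replace = TRUE)
    if (n_ev > 0) {
      mag_sd <- 0.1 * params$pirouette_turn
      p_lo <- min(stats::pnorm(130, params$pirouette_turn, mag_sd), 1 - 1e-12)
      ev_mag <- stats::qnorm(stats::runif(n_ev, p_lo, 1),
                             params$pirouette_turn, mag_sd)
    } else {
      ev_mag <- numeric(0)
    }

    dtheta <- stats::rnorm(n, 0, sqrt(params$heading_diffusion * dt))
    spd_mult <- rep(1, n)
    ev_end <- pmin(ev_start + params$pirouette_duration, duration)
    if (n_ev > 0) {
      t0s <- times[seq_len(n)]
      t1s <- times[seq_len(n) + 1]
      for (k in seq_len(n_ev)) {
        idx <- which(t0s < ev_end[k] & t1s > ev_start[k])
        if (length(idx) == 0) next
        dtheta[idx] <- dtheta[idx] + ev_sign[k] * ev_mag[k] / length(idx)
        spd_mult[idx] <- spd_mult[idx] * params$pirouette_speed_factor
      }
    }
    speed <- speed * spd_mult

    theta <- stats::runif(1, 0, 360) + cumsum(dtheta)   # heading per step, deg
    rad <- theta * pi / 180
    cx <- c(0, cumsum(speed * dt * cos(rad)))
    cy <- c(0, cumsum(speed * dt * sin(rad)))

    # head tip: lead along heading + lateral sinusoid; per-frame heading is
    # the outgoing step's heading (final frame reuses the last step)
    rad_f <- c(rad, rad[n])
    phase <- stats::runif(1, 0, 2 * pi)
    lat <- params$head_amp * sin(2 * pi * params$head_freq * times + phase)
    hx <- cx + params$head_offset * cos(rad_f) - lat * sin(rad_f)
    hy <- cy + params$head_offset * sin(rad_f) + lat * cos(rad_f)

    if (params$noise_sd > 0) {
      cx <- cx + stats::rnorm(n + 1, 0, params$noise_sd)
      cy <- cy + stats::rnorm(n + 1, 0, params$noise_sd)
      hx <- hx + stats::rnorm(n + 1, 0, params$noise_sd)
      hy <- hy + stats::rnorm(n + 1, 0, params$noise_sd)
    }
    valid <- if (params$gap_prob > 0) {
      stats::runif(n + 1) >= params$gap_prob
    } else rep(TRUE, n + 1)

    frames <- data.frame(time = times, cx = cx, cy = cy, hx = hx, hy = hy,
                         valid = valid)
    worm_track(frames, animal_id = animal_id, species = params$name,
               stage = "adult", condition = condition, nominal_dt = dt,
               truth = list(event_start = ev_start, event_end = ev_end,
                            event_turn = ev_sign * ev_mag, n_events = n_ev,
                            mean_speed = params$mean_speed,
                            head_amp = params$head_amp, seed = seed))
  })
}

#' Multinomial model of plate endpoint counts
#'
#' @param p_control,p_odorant,p_central Probabilities that one worm ends the
#'   assay in the control, odorant, or central zone; must sum to 1 within
#'   1e-12.
#' @param n_worms Number of worms per plate (default 10, the usual load of an
#'   adult plate assay).
#' @return An object of class `endpoint_model`.
#' @export
endpoint_model <- function(p_control, p_odorant, p_central = 0,
                           n_worms = 10) {
  p <- c(p_control, p_odorant, p_central)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1")
  if (n_worms < 1 || n_worms != round(n_worms)) {
    stop("n_worms must be a positive integer")
  }
  structure(list(p_control = p_control, p_odorant = p_odorant,
                 p_central = p_central, n_worms = as.integer(n_worms)),
            class = "endpoint_model")
}

#' Simulate one assay plate
#'
#' Draws `(count_control, count_odorant, count_central)` from a single
#' multinomial with `n_worms` trials, so counts always conserve the plate
#' load exactly.
#'
#' @param model An [endpoint_model()].
#' @param seed Integer seed.
#' @param plate_id,species,stage,odorant,dilution,odorant_side Metadata for
#'   the resulting plate row.
#' @return A one-row `plate_assay_table` data frame.
#' @export
simulate_plate <- function(model, seed = 1, plate_id = "plate1",
                           species = "synthetic", stage = "adult",
                           odorant = "ET", dilution = "1:1000",
                           odorant_side = "left") {
  stopifnot(inherits(model, "endpoint_model"))
  counts <- with_seed(seed, {
    stats::rmultinom(1, model$n_worms,
                     c(model$p_control, model$p_odorant, model$p_central))
  })
  as_plate_assays(data.frame(
    plate_id = plate_id, species = species, stage = stage, odorant = odorant,
    dilution = dilution, odorant_side = odorant_side,
    count_control = counts[1], count_odorant = counts[2],
    count_central = counts[3], stringsAsFactors = FALSE))
}

#' Simulate an ensemble of assay plates
#'
#' Convenience wrapper around [simulate_plate()]; plate `i` uses seed
#' `seed + i` so the ensemble is reproducible independent of generation
#' order. Odorant sides alternate across plates, mirroring the bench
#' practice of alternating odorant position to cancel spatial bias.
#'
#' @inheritParams simulate_plate
#' @param n_plates Number of plates.
#' @return A `plate_assay_table` with `n_plates` rows.
#' @export
simulate_plates <- function(model, n_plates, seed = 1, species = "synthetic",
                            stage = "adult", odorant = "ET",
                            dilution = "1:1000") {
  rows <- lapply(seq_len(n_plates), function(i) {
    simulate_plate(model, seed = seed + i,
                   plate_id = sprintf("P%04d", i), species = species,
                   stage = stage, odorant = odorant, dilution = dilution,
                   odorant_side = if (i %% 2 == 1) "left" else "right")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a balanced two-species tracking study
#'
#' Generates `n_per_group` tracks under each preset, with per-track RNG
#' streams derived from the root seed by counter offset (track `i` of the
#' ensemble uses `seed + i`), so any subset of the ensemble is reproducible.
#' Each track carries its own ground truth (true mean speed, realised event
#' times, head amplitude) for recovery tests.
#'
#' @param preset_a,preset_b [species_params()] for the two groups.
#' @param n_per_group Tracks per group (>= 1).
#' @param duration,dt Passed to [simulate_track()].
#' @param seed Root integer seed.
#' @param condition Condition label applied to every track.
#' @return A list of `2 * n_per_group` [worm_track()] objects, group A first.
#' @export
make_two_species_study <- function(preset_a = species_preset("inopinata"),
                                   preset_b = species_preset("elegans"),
                                   n_per_group = 20, duration = 600,
                                   dt = 0.1, seed = 1,
                                   condition = "odorant") {
  stopifnot(n_per_group >= 1)
  sim_group <- function(preset, offset) {
    lapply(seq_len(n_per_group), function(i) {
      simulate_track(preset, duration = duration, dt = dt,
                     seed = seed + offset + i,
                     animal_id = sprintf("%s_%02d", preset$name, i),
                     condition = condition)
    })
  }
  c(sim_group(preset_a, 0L), sim_group(preset_b, n_per_group))
}
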
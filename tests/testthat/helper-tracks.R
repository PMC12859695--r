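# Hand-built track fixtures (constructed in code; no data files).

# Track from explicit coordinate vectors; head defaults to the centroid.
make_path_track <- function(cx, cy, hx = cx, hy = cy, dt = 1,
                            valid = TRUE, id = "hand", ...) {
  n <- length(cx)
  frames <- data.frame(time = (seq_len(n) - 1) * dt, cx = cx, cy = cy,
                       hx = hx, hy = hy, valid = rep(valid, length.out = n))
  worm_track(frames, animal_id = id, nominal_dt = dt, ...)
}

# Straight eastward track whose consecutive step speeds are given (mm/s).
make_speed_track <- function(speeds, dt = 1, ...) {
  make_path_track(cx = c(0, cumsum(speeds * dt)),
                  cy = rep(0, length(speeds) + 1), dt = dt, ...)
}

# Deterministic track with one embedded reorientation: cruise east at
# `v_run` for `run_s` seconds, turn by `turn_deg` (spread evenly) at
# `v_turn` for `turn_s` seconds, then cruise `run_s` more on the new
# heading. dt = 0.1 s.
make_turn_track <- function(v_run = 0.3, v_turn = 0.1, turn_deg = 150,
                            run_s = 10, turn_s = 2, dt = 0.1, ...) {
  n_run <- round(run_s / dt)
  n_turn <- round(turn_s / dt)
  dtheta <- c(rep(0, n_run), rep(turn_deg / n_turn, n_turn), rep(0, n_run))
  speed <- c(rep(v_run, n_run), rep(v_turn, n_turn), rep(v_run, n_run))
  theta <- cumsum(dtheta) * pi / 180
  make_path_track(cx = c(0, cumsum(speed * dt * cos(theta))),
                  cy = c(0, cumsum(speed * dt * sin(theta))),
                  dt = dt, ...)
}

# Straight centroid with a sinusoidal head: x from 0 to `len` in steps of
# `dx`, head displaced laterally by amp * sin(2 pi x / period).
make_sinusoid_track <- function(len = 10, dx = 0.01, amp = 1, period = 5,
                                dt = 0.1, ...) {
  x <- seq(0, len, by = dx)
  make_path_track(cx = x, cy = rep(0, length(x)), hx = x,
                  hy = amp * sin(2 * pi * x / period), dt = dt, ...)
}

# Rigid-motion helper: rotate (deg) then translate all coordinates.
transform_track <- function(track, angle_deg = 0, shift = c(0, 0),
                            scale = 1, reflect = FALSE) {
  a <- angle_deg * pi / 180
  fr <- track$frames
  xf <- function(x, y) {
    if (reflect) y <- -y
    list(x = scale * (cos(a) * x - sin(a) * y) + shift[1],
         y = scale * (sin(a) * x + cos(a) * y) + shift[2])
  }
  c1 <- xf(fr$cx, fr$cy); h1 <- xf(fr$hx, fr$hy)
  fr$cx <- c1$x; fr$cy <- c1$y; fr$hx <- h1$x; fr$hy <- h1$y
  out <- track
  out$frames <- fr
  out
}

# Random species parameters spanning the generator's realistic range.
random_species_params <- function() {
  species_params(
    name = "rand", mean_speed = stats::runif(1, 0.1, 0.45),
    speed_cv = stats::runif(1, 0, 0.3), speed_ar1 = stats::runif(1, 0, 0.9),
    heading_diffusion = stats::runif(1, 10, 150),
    head_amp = stats::runif(1, 0, 0.2), head_freq = stats::runif(1, 0.2, 0.8),
    pirouette_rate = stats::runif(1, 0, 3), pirouette_turn = 160,
    pirouette_duration = stats::runif(1, 0.6, 1.5),
    pirouette_speed_factor = stats::runif(1, 0.2, 0.5),
    gap_prob = stats::runif(1, 0, 0.05), noise_sd = stats::runif(1, 0, 0.01))
}
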
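# Invariance and recovery properties over generated cases.

test_that("speeds and lengths are invariant under rigid motion", {
  set.seed(41)
  for (rep in 1:5) {
    tr <- simulate_track(random_species_params(), duration = 30, dt = 0.1,
                         seed = 600 + rep)
    moved <- transform_track(tr, angle_deg = runif(1, 0, 360),
                             shift = runif(2, -20, 20))
    expect_equal(instantaneous_speeds(moved)$speed,
                 instantaneous_speeds(tr)$speed, tolerance = 1e-9)
    expect_equal(track_length(moved, "centroid"),
                 track_length(tr, "centroid"), tolerance = 1e-9)
    expect_equal(track_length(moved, "head"), track_length(tr, "head"),
                 tolerance = 1e-9)
  }
})

test_that("time rescaling halves speeds but preserves lengths and the index", {
  tr <- simulate_track(species_preset("inopinata"), duration = 30, dt = 0.1,
                       seed = 55)
  slow <- tr
  slow$frames$time <- tr$frames$time * 2
  slow$nominal_dt <- tr$nominal_dt * 2
  sp <- instantaneous_speeds(tr); sp2 <- instantaneous_speeds(slow)
  ok <- sp$step_valid
  expect_equal(sp2$speed[ok], sp$speed[ok] / 2, tolerance = 1e-12)
  expect_equal(track_length(slow, "head"), track_length(tr, "head"))
  expect_equal(head_swinging_index(slow), head_swinging_index(tr))
})

test_that("the head-swinging index is scale-invariant", {
  tr <- simulate_track(species_preset("inopinata"), duration = 30, dt = 0.1,
                       seed = 56)
  scaled <- transform_track(tr, scale = 3.7)
  expect_equal(head_swinging_index(scaled), head_swinging_index(tr),
               tolerance = 1e-12)
})

test_that("median speed recovers the generating mean on clean tracks", {
  p <- species_params(name = "rec", mean_speed = 0.3, speed_cv = 0.15,
                      speed_ar1 = 0.5, heading_diffusion = 60,
                      head_amp = 0.05, head_freq = 0.4, pirouette_rate = 0,
                      gap_prob = 0, noise_sd = 0)
  for (s in 1:5) {
    tr <- simulate_track(p, duration = 120, dt = 0.1, seed = s)
    ms <- median_speed(instantaneous_speeds(tr))
    expect_lt(abs(ms / p$mean_speed - 1), 0.05)
  }
})

test_that("head-swinging index increases with the generating head amplitude", {
  base <- species_params(name = "straight", mean_speed = 0.3, speed_cv = 0,
                         heading_diffusion = 0, head_amp = 0,
                         head_freq = 0.5, pirouette_rate = 0, gap_prob = 0,
                         noise_sd = 0)
  hsi <- vapply(c(0, 0.2, 0.5, 1.0), function(a) {
    p <- base; p$head_amp <- a
    head_swinging_index(simulate_track(p, duration = 60, dt = 0.1, seed = 13))
  }, numeric(1))
  expect_true(all(diff(hsi) > 0))
  expect_equal(hsi[1], 1, tolerance = 1e-6)
})

test_that("group medians order with the generating parameters", {
  tracks <- make_two_species_study(n_per_group = 8, duration = 600,
                                   dt = 0.1, seed = 17)
  beh <- summarize_behavior(tracks)
  med <- function(v) tapply(beh[[v]], beh$species, stats::median)
  expect_lt(med("median_speed")[["inopinata"]],
            med("median_speed")[["elegans"]])
  expect_gt(med("head_swinging_index")[["inopinata"]],
            med("head_swinging_index")[["elegans"]])
  expect_lt(med("pirouette_rate")[["inopinata"]],
            med("pirouette_rate")[["elegans"]])
})

test_that("identical presets give a uniform-ish Wilcoxon null", {
  # same generator for both groups: the rank test should not reject at
  # much more than the nominal rate across replicate studies
  p <- species_preset("elegans")
  set.seed(71)
  pvals <- vapply(1:40, function(r) {
    a <- vapply(1:5, function(i) {
      median_speed(instantaneous_speeds(
        simulate_track(p, 60, 0.1, seed = 5000 + 10 * r + i)))
    }, numeric(1))
    b <- vapply(6:10, function(i) {
      median_speed(instantaneous_speeds(
        simulate_track(p, 60, 0.1, seed = 5000 + 10 * r + i)))
    }, numeric(1))
    wilcoxon_rank_sum(a, b)$p_value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)       # not systematically tiny
})
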
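test_that("track files parse through the reference dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,time_s,centroid_x_mm,centroid_y_mm,head_x_mm,head_y_mm",
               "w1,0.0,0,0,0.5,0",
               "w1,0.1,0.05,0,0.55,0",
               "w1,0.2,0.10,0,0.60,0"), f)
  tracks <- read_tracks(f)
  expect_length(tracks, 1)
  tr <- tracks[[1]]
  expect_s3_class(tr, "worm_track")
  expect_identical(tr$animal_id, "w1")
  expect_equal(nrow(tr$frames), 3)
  expect_true(all(tr$frames$valid))
  expect_equal(tr$frames$cx, c(0, 0.05, 0.10))
})

test_that("missing coordinates become gap frames, not dropped rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,time_s,centroid_x_mm,centroid_y_mm,head_x_mm,head_y_mm",
               "w1,0.0,0,0,0.5,0",
               "w1,0.1,0.05,0,,0",
               "w1,0.2,0.10,0,0.60,0"), f)
  tr <- read_tracks(f)[[1]]
  expect_equal(nrow(tr$frames), 3)
  expect_equal(tr$frames$valid, c(TRUE, FALSE, TRUE))
})

test_that("unit conversion is applied and closed across declarations", {
  base <- c("track_id,time_s,cx,cy,hx,hy")
  vals_mm <- c("w1,0,0,0,0.5,0", "w1,0.1,0.5,0,1,0")
  write_variant <- function(vals) {
    f <- tempfile(fileext = ".csv")
    writeLines(c(base, vals), f)
    f
  }
  dial <- function(u) track_dialect(centroid_x = "cx", centroid_y = "cy",
                                    head_x = "hx", head_y = "hy", units = u)
  t_mm <- read_tracks(write_variant(vals_mm), dial("mm"))[[1]]
  t_um <- read_tracks(write_variant(c("w1,0,0,0,500,0", "w1,0.1,500,0,1000,0")),
                      dial("um"))[[1]]
  t_cm <- read_tracks(write_variant(c("w1,0,0,0,0.05,0", "w1,0.1,0.05,0,0.1,0")),
                      dial("cm"))[[1]]
  expect_equal(t_um$frames, t_mm$frames)
  expect_equal(t_cm$frames, t_mm$frames)
  expect_equal(t_um$frames$cx[2], 0.5)   # 500 um = 0.5 mm
})

test_that("unmappable columns and non-monotone times are rejected with context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,time_s,centroid_x_mm,centroid_y_mm,head_x_mm",
               "w1,0,0,0,0.5"), f)
  expect_error(read_tracks(f), "head_y_mm")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,time_s,centroid_x_mm,centroid_y_mm,head_x_mm,head_y_mm",
               "w1,0.2,0,0,0.5,0",
               "w1,0.1,1,0,1.5,0",
               "w1,0.1,2,0,2.5,0"), g)
  expect_error(read_tracks(g), "non-monotone time in track 'w1' at row")
})

test_that("frame-index time columns convert through the dialect dt", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,centroid_x_mm,centroid_y_mm,head_x_mm,head_y_mm",
               "w1,0,0,0,0.5,0", "w1,1,0.05,0,0.55,0"), f)
  tr <- read_tracks(f, track_dialect(time = "frame", dt = 0.1))[[1]]
  expect_equal(tr$frames$time, c(0, 0.1))
  expect_equal(tr$nominal_dt, 0.1)
})

test_that("track write/read round trip preserves frames including gaps", {
  p <- species_preset("elegans")
  tr <- simulate_track(p, duration = 10, dt = 0.1, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, f)
  back <- read_tracks(f, nominal_dt = 0.1)[[1]]
  expect_equal(back$frames$valid, tr$frames$valid)
  ok <- tr$frames$valid
  expect_equal(back$frames$cx[ok], tr$frames$cx[ok], tolerance = 1e-12)
  expect_equal(back$frames$hy[ok], tr$frames$hy[ok], tolerance = 1e-12)
})

test_that("plate-count tables are validated on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,species,stage,odorant,dilution,odorant_side,count_control,count_odorant,count_central",
               "P1,inopinata,adult,TT,1:1000,left,2,8,1"), f)
  plates <- read_plate_counts(f)
  expect_s3_class(plates, "plate_assay_table")
  expect_equal(plates$count_odorant, 8L)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,species,stage,odorant,dilution,odorant_side,count_control,count_odorant,count_central",
               "P1,inopinata,adult,TT,1:1000,left,-1,8,1"), g)
  expect_error(read_plate_counts(g), "non-negative")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,species,stage,odorant,dilution,odorant_side,count_control,count_odorant,count_central",
               "P1,inopinata,adult,XX,1:1000,left,2,8,1"), h)
  expect_error(read_plate_counts(h), "TT, BT, IA, BZ, PZ, DC, ET")
})

test_that("result tables round-trip through write_results", {
  res <- data.frame(plate_id = c("P1", "P2"), ci = c(0.6123456789, -0.25),
                    n_scored = c(10L, 8L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(res, f)
  lines <- readLines(f)
  expect_length(lines, 3)            # header + 2 rows
  back <- utils::read.csv(f)
  expect_equal(back$plate_id, res$plate_id)
  expect_equal(back$ci, signif(res$ci, 6))
  expect_equal(back$n_scored, res$n_scored)

  write_results(res[0, ], f)
  expect_length(readLines(f), 1)     # header only
})

test_that("plate geometry rejects a band wider than the plate", {
  expect_error(plate_geometry(50, 25), "narrower")
  g <- plate_geometry()
  expect_equal(g$diameter, 50)
  expect_equal(g$central_band_halfwidth, 5)
})
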
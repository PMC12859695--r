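# Data model and delimited-text I/O for worm tracks and plate counts.
# Internal units are fixed: millimetres and seconds. Tracker exports in cm or
# micrometres are converted once, at read time.

.unit_to_mm <- c(mm = 1, cm = 10, um = 1e-3)

#' Allowed odorant labels
#'
#' The seven odorant codes used in plate-count tables: 2,4,5-trimethylthiazole
#' (TT), 2-butanone (BT), isoamyl alcohol (IA), benzaldehyde (BZ), pyrazine
#' (PZ), diacetyl (DC), and the ethanol-only control (ET).
#'
#' @return Character vector of valid odorant labels.
#' @export
odorant_labels <- function() {
  c("TT", "BT", "IA", "BZ", "PZ", "DC", "ET")
}

#' Construct a worm track
#'
#' A `worm_track` holds one animal's time-stamped centroid and head-tip
#' positions. Tracking gaps are kept in-band as `valid = FALSE` frames (rather
#' than splitting the track) so that downstream per-animal aggregation sees a
#' single logical track; all kinematic computations skip invalid frames.
#'
#' @param frames Data frame with columns `time` (s, strictly increasing),
#'   `cx`, `cy` (centroid, mm), `hx`, `hy` (head tip, mm) and logical `valid`.
#'   Rows with any missing coordinate are forced to `valid = FALSE`.
#' @param animal_id Identifier for the animal.
#' @param species,stage,condition Metadata labels (e.g. `"elegans"`,
#'   `"adult"`, `"odorant"`).
#' @param nominal_dt Nominal inter-frame interval in seconds; defaults to the
#'   median observed interval. A warning is raised if the median observed
#'   interval deviates from `nominal_dt` by more than 10%.
#' @param truth Optional list of generator ground truth (used by the
#'   simulator; ignored by every analysis function).
#' @return An object of class `worm_track`.
#' @seealso [read_tracks()], [simulate_track()]
#' @export
worm_track <- function(frames, animal_id = "worm", species = "synthetic",
                       stage = "adult", condition = "control",
                       nominal_dt = NULL, truth = NULL) {
  stopifnot(is.data.frame(frames))
  need <- c("time", "cx", "cy", "hx", "hy", "valid")
  miss <- setdiff(need, names(frames))
  if (length(miss) > 0) {
    stop("frames is missing column(s): ", paste(miss, collapse = ", "))
  }
  frames <- frames[need]
  if (nrow(frames) >= 2 && any(diff(frames$time) <= 0)) {
    bad <- which(diff(frames$time) <= 0)[1] + 1L
    stop(sprintf("non-monotone time in track '%s' at row %d",
                 as.character(animal_id), bad))
  }
  frames$valid <- as.logical(frames$valid) &
    stats::complete.cases(frames[c("cx", "cy", "hx", "hy")])
  if (is.null(nominal_dt)) {
    if (nrow(frames) < 2) stop("nominal_dt must be given for a 1-frame track")
    nominal_dt <- stats::median(diff(frames$time))
  }
  if (!is.numeric(nominal_dt) || length(nominal_dt) != 1 || nominal_dt <= 0) {
    stop("nominal_dt must be a single positive number")
  }
  if (nrow(frames) >= 2) {
    obs <- stats::median(diff(frames$time))
    if (abs(obs - nominal_dt) > 0.1 * nominal_dt) {
      warning(sprintf(
        "track '%s': median observed frame interval (%.4g s) deviates >10%% from nominal_dt (%.4g s)",
        as.character(animal_id), obs, nominal_dt))
    }
  }
  rownames(frames) <- NULL
  structure(
    list(animal_id = as.character(animal_id),
         species = as.character(species),
         stage = as.character(stage),
         condition = as.character(condition),
         frames = frames,
         nominal_dt = nominal_dt,
         truth = truth),
    class = "worm_track")
}

#' @export
print.worm_track <- function(x, ...) {
  nv <- sum(x$frames$valid)
  cat(sprintf("<worm_track> %s (%s, %s, %s)\n", x$animal_id, x$species,
              x$stage, x$condition))
  cat(sprintf("  %d frames (%d valid), %.1f s at nominal dt = %.3g s\n",
              nrow(x$frames), nv,
              diff(range(x$frames$time)), x$nominal_dt))
  if (!is.null(x$truth)) cat("  carries simulator ground-truth metadata\n")
  invisible(x)
}

#' Plot a worm track
#'
#' Draws the centroid trajectory (green) and head-tip trajectory (red) of the
#' valid frames, with equal axis scaling, in the style of published
#' single-animal track panels.
#'
#' @param x A `worm_track`.
#' @param ... Passed on to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.worm_track <- function(x, ...) {
  fr <- x$frames[x$frames$valid, ]
  if (nrow(fr) < 2) stop("too few valid frames to plot")
  rng_x <- range(c(fr$cx, fr$hx))
  rng_y <- range(c(fr$cy, fr$hy))
  graphics::plot(NA, xlim = rng_x, ylim = rng_y, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%s (%s)", x$animal_id, x$species), ...)
  graphics::lines(fr$hx, fr$hy, col = "red")
  graphics::lines(fr$cx, fr$cy, col = "darkgreen")
  invisible(x)
}

#' Describe the column layout of a track file
#'
#' Tracker exports differ in column naming and units; a dialect maps file
#' columns onto the internal track fields. The default is the reference
#' dialect written by [write_tracks()] and by the simulator helpers.
#'
#' @param track_id,time,centroid_x,centroid_y,head_x,head_y Column names in
#'   the file.
#' @param units Coordinate units in the file: `"mm"`, `"cm"` or `"um"`
#'   (micrometres; `"µm"` is accepted as an alias). Converted to mm on
#'   read.
#' @param dt If the time column holds frame indices rather than seconds, the
#'   frame interval in seconds used to convert them; `NULL` (default) means
#'   the time column is already in seconds.
#' @param species,stage,condition Optional names of metadata columns in the
#'   file; when `NULL` the defaults passed to [read_tracks()] are used.
#' @return An object of class `track_dialect`.
#' @export
track_dialect <- function(track_id = "track_id", time = "time_s",
                          centroid_x = "centroid_x_mm",
                          centroid_y = "centroid_y_mm",
                          head_x = "head_x_mm", head_y = "head_y_mm",
                          units = "mm", dt = NULL,
                          species = NULL, stage = NULL, condition = NULL) {
  units <- as.character(units)
  if (identical(units, "µm")) units <- "um"
  units <- match.arg(units, c("mm", "cm", "um"))
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0)) {
    stop("dt must be NULL or a positive number of seconds")
  }
  structure(list(track_id = track_id, time = time,
                 centroid_x = centroid_x, centroid_y = centroid_y,
                 head_x = head_x, head_y = head_y,
                 units = units, dt = dt,
                 species = species, stage = stage, condition = condition),
            class = "track_dialect")
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read worm tracks from a delimited text file
#'
#' Reads a CSV/TSV track table (separator auto-detected from the header
#' line), maps columns through `dialect`, converts coordinates to millimetres
#' and times to seconds, and splits rows into one [worm_track()] per track
#' id. Rows with any missing coordinate become `valid = FALSE` gap frames.
#'
#' @param path Path to the file.
#' @param dialect A [track_dialect()] describing column names and units.
#' @param species,stage,condition Metadata defaults applied to every track
#'   when the file carries no metadata columns.
#' @param nominal_dt Nominal frame interval in seconds; defaults to
#'   `dialect$dt` if set, else the per-track median observed interval.
#' @return A list of `worm_track` objects, one per track id, frames sorted
#'   by time.
#' @export
read_tracks <- function(path, dialect = track_dialect(),
                        species = "synthetic", stage = "adult",
                        condition = "control", nominal_dt = NULL) {
  stopifnot(inherits(dialect, "track_dialect"))
  raw <- utils::read.csv(path, sep = .detect_sep(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  fields <- c(track_id = dialect$track_id, time = dialect$time,
              cx = dialect$centroid_x, cy = dialect$centroid_y,
              hx = dialect$head_x, hy = dialect$head_y)
  missing_cols <- fields[!(fields %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop(sprintf("cannot map track file '%s': no column '%s' for field '%s'",
                 path, missing_cols[1], names(missing_cols)[1]))
  }
  f <- .unit_to_mm[[dialect$units]]
  tab <- data.frame(track_id = as.character(raw[[fields[["track_id"]]]]),
                    time = as.numeric(raw[[fields[["time"]]]]),
                    cx = as.numeric(raw[[fields[["cx"]]]]) * f,
                    cy = as.numeric(raw[[fields[["cy"]]]]) * f,
                    hx = as.numeric(raw[[fields[["hx"]]]]) * f,
                    hy = as.numeric(raw[[fields[["hy"]]]]) * f,
                    stringsAsFactors = FALSE)
  if (!is.null(dialect$dt)) tab$time <- tab$time * dialect$dt
  meta_col <- function(col, default) {
    if (!is.null(col)) {
      if (!(col %in% names(raw))) {
        stop(sprintf("metadata column '%s' not found in '%s'", col, path))
      }
      as.character(raw[[col]])
    } else rep(default, nrow(raw))
  }
  tab$species <- meta_col(dialect$species, species)
  tab$stage <- meta_col(dialect$stage, stage)
  tab$condition <- meta_col(dialect$condition, condition)
  if (is.null(nominal_dt)) nominal_dt <- dialect$dt

  ids <- unique(tab$track_id)
  lapply(ids, function(id) {
    rows <- tab[tab$track_id == id, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    frames <- data.frame(time = rows$time, cx = rows$cx, cy = rows$cy,
                         hx = rows$hx, hy = rows$hy, valid = TRUE)
    worm_track(frames, animal_id = id,
               species = rows$species[1], stage = rows$stage[1],
               condition = rows$condition[1], nominal_dt = nominal_dt)
  })
}

#' Write worm tracks in the reference dialect
#'
#' Companion to [read_tracks()]: writes one CSV row per frame with the
#' reference column names (`track_id, time_s, centroid_x_mm, ...`). Invalid
#' (gap) frames are written with empty coordinate cells, which read back as
#' `valid = FALSE`.
#'
#' @param tracks A `worm_track` or list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "worm_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    fr <- tr$frames
    fr[!fr$valid, c("cx", "cy", "hx", "hy")] <- NA_real_
    data.frame(track_id = tr$animal_id, time_s = fr$time,
               centroid_x_mm = fr$cx, centroid_y_mm = fr$cy,
               head_x_mm = fr$hx, head_y_mm = fr$hy)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plate-count table
#'
#' One row per assay plate with endpoint counts in the control (A), odorant
#' (B) and central exclusion (C) zones. Counts must be non-negative integers
#' and odorant labels must come from [odorant_labels()].
#'
#' @param path Path to a CSV with columns `plate_id, species, stage, odorant,
#'   dilution, odorant_side, count_control, count_odorant, count_central`.
#' @return A data frame of class `plate_assay_table`.
#' @export
read_plate_counts <- function(path) {
  raw <- utils::read.csv(path, sep = .detect_sep(path),
                         stringsAsFactors = FALSE)
  need <- c("plate_id", "species", "stage", "odorant", "dilution",
            "odorant_side", "count_control", "count_odorant", "count_central")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("plate-count file is missing column(s): ", paste(miss, collapse = ", "))
  }
  as_plate_assays(raw[need])
}

#' Validate a data frame of plate assays
#'
#' @param df Data frame with the nine plate-count columns (see
#'   [read_plate_counts()]).
#' @return The validated data frame with class `plate_assay_table`.
#' @export
as_plate_assays <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("count_control", "count_odorant", "count_central")) {
    v <- df[[col]]
    if (is.null(v)) stop("missing column: ", col)
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop(sprintf("column '%s' must contain non-negative integers", col))
    }
    df[[col]] <- as.integer(v)
  }
  bad <- setdiff(unique(as.character(df$odorant)), odorant_labels())
  if (length(bad) > 0) {
    stop(sprintf("unknown odorant label(s) %s; allowed labels are: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(odorant_labels(), collapse = ", ")))
  }
  side <- as.character(df$odorant_side)
  if (!all(side %in% c("left", "right"))) {
    stop("odorant_side must be 'left' or 'right'")
  }
  class(df) <- unique(c("plate_assay_table", class(df)))
  df
}

#' Write an analysis result table
#'
#' Writes any homogeneous result table (per-plate chemotaxis indices,
#' per-animal kinematics, statistical comparisons) as CSV with a header and a
#' stable column order. Numeric columns are rendered at 6 significant digits
#' so that a read/write round trip reproduces typed fields to that precision.
#'
#' @param records Data frame of result rows (may have zero rows, giving a
#'   header-only file).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- as.data.frame(records)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(z) signif(z, 6))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Plate geometry for zone assignment
#'
#' Plate-centric Cartesian geometry of the two-point assay: origin at the
#' plate centre, x axis along the axis joining the two scoring spots, and a
#' central exclusion band (default 1 cm wide, i.e. halfwidth 5 mm) straddling
#' the midline.
#'
#' @param diameter Plate diameter in mm (default 50, a 5-cm plate).
#' @param central_band_halfwidth Half the width of the central exclusion
#'   band, mm (default 5).
#' @return An object of class `plate_geometry`.
#' @export
plate_geometry <- function(diameter = 50, central_band_halfwidth = 5) {
  stopifnot(is.numeric(diameter), diameter > 0,
            is.numeric(central_band_halfwidth), central_band_halfwidth >= 0)
  if (2 * central_band_halfwidth >= diameter) {
    stop("central band must be narrower than the plate diameter")
  }
  structure(list(diameter = diameter,
                 central_band_halfwidth = central_band_halfwidth),
            class = "plate_geometry")
}
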
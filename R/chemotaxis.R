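# Chemotaxis-index scoring of two-point plate assays.
#
# CI = (B - A) / (A + B), with A the control-zone count, B the odorant-zone
# count; worms in the central exclusion band (C) are reported but never
# enter the index. The per-plate CI is the statistical unit.

#' Per-plate chemotaxis index
#'
#' Computes `ci = (count_odorant - count_control) / (count_odorant +
#' count_control)` for every plate. Plates with no worm in either scoring
#' zone cannot be scored: they get `ci = NA`, `scorable = FALSE`, and a
#' logged notice, and should be excluded from downstream statistics.
#'
#' @param assays A `plate_assay_table` (see [read_plate_counts()],
#'   [as_plate_assays()], [simulate_plates()]).
#' @return A data frame of class `chemotaxis_result`: plate metadata plus
#'   `ci` (in `[-1, 1]`), `n_scored` (A + B), `n_excluded_central` and
#'   `scorable`.
#' @export
chemotaxis_index <- function(assays) {
  assays <- as_plate_assays(assays)
  n_scored <- assays$count_control + assays$count_odorant
  scorable <- n_scored > 0
  ci <- ifelse(scorable,
               (assays$count_odorant - assays$count_control) / n_scored,
               NA_real_)
  if (any(!scorable)) {
    message(sprintf("plate(s) unscorable (no worm in either scoring zone): %s",
                    paste(assays$plate_id[!scorable], collapse = ", ")))
  }
  out <- data.frame(plate_id = assays$plate_id, species = assays$species,
                    stage = assays$stage, odorant = assays$odorant,
                    dilution = assays$dilution, ci = ci,
                    n_scored = as.integer(n_scored),
                    n_excluded_central = assays$count_central,
                    scorable = scorable, stringsAsFactors = FALSE)
  class(out) <- c("chemotaxis_result", "data.frame")
  out
}

#' Pooled-count chemotaxis index
#'
#' Secondary summary pooling counts over all plates of a table before
#' computing a single index; the per-plate CI from [chemotaxis_index()]
#' remains the unit of analysis.
#'
#' @param assays A `plate_assay_table`.
#' @return A single pooled CI value.
#' @export
pooled_chemotaxis_index <- function(assays) {
  assays <- as_plate_assays(assays)
  a <- sum(assays$count_control)
  b <- sum(assays$count_odorant)
  if (a + b == 0) stop("no scored worms across plates")
  (b - a) / (a + b)
}

#' Assign tracked final positions to scoring zones
#'
#' Converts per-worm endpoint positions into plate counts. The midline is
#' perpendicular to the axis joining the two scoring spots (the x axis in
#' plate-centred coordinates): positions within `central_band_halfwidth` of
#' the midline fall in the central exclusion zone C; the remaining worms are
#' counted as odorant (zone B) on the side given by `odorant_side` and as
#' control (zone A) on the opposite side. Counts are side-normalised — B is
#' always the odorant zone regardless of the physical left/right assignment
#' — so alternating the odorant position across trials needs no special
#' handling downstream. Positions outside the plate radius are excluded
#' with a warning.
#'
#' @param final_positions Two-column matrix or data frame of endpoint
#'   positions (mm, plate-centred; column 1 = x along the A-B axis).
#' @param geometry A [plate_geometry()].
#' @param odorant_side `"left"` (odorant at negative x) or `"right"`.
#' @param plate_id,species,stage,odorant,dilution Metadata for the resulting
#'   plate row.
#' @return A one-row `plate_assay_table`, with attribute `n_outside` giving
#'   the number of excluded out-of-plate positions.
#' @export
assign_zones <- function(final_positions, geometry = plate_geometry(),
                         odorant_side = c("left", "right"),
                         plate_id = "plate1", species = "synthetic",
                         stage = "adult", odorant = "ET",
                         dilution = "1:1000") {
  odorant_side <- match.arg(odorant_side)
  stopifnot(inherits(geometry, "plate_geometry"))
  pos <- as.matrix(final_positions)
  if (ncol(pos) != 2) stop("final_positions must have two columns (x, y)")
  radius <- geometry$diameter / 2
  inside <- sqrt(pos[, 1]^2 + pos[, 2]^2) <= radius + 1e-9
  if (any(!inside)) {
    warning(sprintf("%d position(s) outside the plate radius excluded",
                    sum(!inside)))
    pos <- pos[inside, , drop = FALSE]
  }
  x <- pos[, 1]
  hw <- geometry$central_band_halfwidth
  central <- abs(x) <= hw
  odor_sign <- if (odorant_side == "left") -1 else 1
  odorant_zone <- !central & sign(x) == odor_sign
  control_zone <- !central & !odorant_zone
  out <- as_plate_assays(data.frame(
    plate_id = plate_id, species = species, stage = stage, odorant = odorant,
    dilution = dilution, odorant_side = odorant_side,
    count_control = sum(control_zone), count_odorant = sum(odorant_zone),
    count_central = sum(central), stringsAsFactors = FALSE))
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Group summaries of per-plate chemotaxis indices
#'
#' Summarises scorable plates per (species, stage, odorant, dilution) group:
#' number of plates, median CI, quartiles and range — the quantities shown
#' by the usual per-plate boxplots. Groups with no scorable plate are
#' omitted with a logged notice.
#'
#' @param results A [chemotaxis_index()] table.
#' @return A data frame with one row per group: `species, stage, odorant,
#'   dilution, n_plates, median_ci, q1, q3, min_ci, max_ci`.
#' @export
summarize_by_condition <- function(results) {
  stopifnot(is.data.frame(results))
  res <- results[results$scorable & !is.na(results$ci), , drop = FALSE]
  dropped <- unique(results[!(results$plate_id %in% res$plate_id),
                            c("species", "stage", "odorant", "dilution")])
  key <- interaction(res$species, res$stage, res$odorant, res$dilution,
                     drop = TRUE)
  if (nrow(res) == 0) {
    message("no scorable plates in any group")
    return(data.frame(species = character(0), stage = character(0),
                      odorant = character(0), dilution = character(0),
                      n_plates = integer(0), median_ci = numeric(0),
                      q1 = numeric(0), q3 = numeric(0),
                      min_ci = numeric(0), max_ci = numeric(0)))
  }
  rows <- lapply(split(res, key), function(g) {
    q <- stats::quantile(g$ci, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(species = g$species[1], stage = g$stage[1],
               odorant = g$odorant[1], dilution = g$dilution[1],
               n_plates = nrow(g), median_ci = q[2], q1 = q[1], q3 = q[3],
               min_ci = min(g$ci), max_ci = max(g$ci),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(dropped) > 0 && nrow(merge(dropped, out,
      by = c("species", "stage", "odorant", "dilution"))) < nrow(dropped)) {
    message("group(s) with no scorable plate omitted from the summary")
  }
  out
}
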
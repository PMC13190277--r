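#' @title AIS morphometry and lesion volumetry
#' @description
#' AIS boundaries from Ankyrin-G fluorescence line profiles using the
#' 0.33-of-maximum criterion (first upward and last downward crossing of the
#' threshold, linearly interpolated), distance from the soma, per-stratum
#' aggregation, lesion volume from serial section areas, and 2D/3D polyline
#' path-length comparison.
#' @name ais-morphometry
NULL

#' Construct a fluorescence line profile
#'
#' Intensity versus arc length along a traced axon. Arc length must be
#' strictly increasing; intensities are non-negative arbitrary units.
#'
#' @param arc_length_um Arc-length samples, µm.
#' @param intensity Intensity samples (same length).
#' @param source Provenance label (`"tabular"`, `"image+polyline"`,
#'   `"synthetic"`).
#' @return An object of class `fluorescence_profile`.
#' @export
fluorescence_profile <- function(arc_length_um, intensity,
                                 source = "tabular") {
  arc_length_um <- as.numeric(arc_length_um)
  intensity <- as.numeric(intensity)
  if (length(arc_length_um) != length(intensity) || !length(intensity))
    stop("arc_length and intensity must have equal positive length",
         call. = FALSE)
  if (any(diff(arc_length_um) <= 0))
    stop("arc_length must be strictly increasing", call. = FALSE)
  if (any(intensity < 0) || anyNA(intensity))
    stop("intensity must be non-negative and finite", call. = FALSE)
  structure(list(arc_length_um = arc_length_um, intensity = intensity,
                 source = source),
            class = "fluorescence_profile")
}

#' @export
print.fluorescence_profile <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_profile> %d samples over %.2f um (%s), max intensity %g\n",
    length(x$intensity), diff(range(x$arc_length_um)), x$source,
    max(x$intensity)))
  invisible(x)
}

#' Sample a fluorescence profile from an image along a polyline
#'
#' Reads intensities by bilinear interpolation at a fixed arc-length spacing
#' along a traced polyline, averaging across a perpendicular width. Intended
#' for single-channel maximum-projection TIFFs; the tracing itself is manual
#' input.
#'
#' @param image Numeric matrix (rows = y, columns = x) or path to a
#'   single-channel TIFF.
#' @param polyline_um Two-column matrix of ordered (x, y) coordinates in µm.
#' @param pixel_size_um Image pixel size, µm.
#' @param spacing_um Arc-length sampling interval, µm.
#' @param width_um Perpendicular averaging width, µm (0 = centre line only).
#' @return A [fluorescence_profile()] with `source = "image+polyline"`.
#' @export
sample_profile_from_image <- function(image, polyline_um, pixel_size_um = 0.1,
                                      spacing_um = 0.1, width_um = 0) {
  if (is.character(image)) {
    image <- tiff::readTIFF(image)
    if (length(dim(image)) == 3) image <- image[, , 1]
  }
  stopifnot(is.matrix(image))
  polyline_um <- as.matrix(polyline_um)
  if (nrow(polyline_um) < 2)
    stop("polyline needs at least two points", call. = FALSE)
  seg <- diff(polyline_um)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = spacing_um)
  ix <- findInterval(s, cum, rightmost.closed = TRUE)
  ix <- pmin(ix, nrow(seg))
  f <- (s - cum[ix]) / seg_len[ix]
  pts <- polyline_um[ix, , drop = FALSE] + seg[ix, , drop = FALSE] * f
  tang <- seg[ix, , drop = FALSE] / seg_len[ix]
  norm <- cbind(-tang[, 2], tang[, 1])
  offsets <- if (width_um > 0)
    seq(-width_um / 2, width_um / 2, by = pixel_size_um / 2) else 0

  bilinear <- function(x_um, y_um) {
    # image[row, col]: row = y, col = x; pixel centres at (i-0.5)*pixel
    x <- x_um / pixel_size_um + 0.5
    y <- y_um / pixel_size_um + 0.5
    if (any(x < 1 | x > ncol(image) | y < 1 | y > nrow(image)))
      stop("polyline (with width) outside image bounds", call. = FALSE)
    x0 <- pmin(floor(x), ncol(image) - 1); y0 <- pmin(floor(y), nrow(image) - 1)
    fx <- x - x0; fy <- y - y0
    image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      image[cbind(y0 + 1, x0 + 1)] * fx * fy
  }
  vals <- rowMeans(sapply(offsets, function(o)
    bilinear(pts[, 1] + o * norm[, 1], pts[, 2] + o * norm[, 2])))
  fluorescence_profile(s, vals, source = "image+polyline")
}

moving_average <- function(y, k) {
  if (k <= 1) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  half <- (k - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (k - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect AIS boundaries by the fraction-of-maximum rule
#'
#' After optional moving-average smoothing and baseline subtraction (median
#' of the flanking samples at each end of the trace), the AIS start is the
#' first upward crossing and the end the last downward crossing of
#' `threshold_fraction` times the maximum, linearly interpolated between
#' samples. Threshold excursions between the first rise and last fall are
#' bridged (the rule reads literally "first and last point"). The result is
#' invariant to positive scaling of the intensities.
#'
#' @param profile A [fluorescence_profile()].
#' @param threshold_fraction Fraction of the (baseline-subtracted) maximum
#'   (default 0.33).
#' @param smooth_window_um Moving-average window, µm (0 disables smoothing).
#' @param baseline_flank_fraction Fraction of samples at each end used for
#'   the median baseline estimate (0 disables baseline subtraction).
#' @return An `ais_bounds` object: `start_um`, `end_um`, `length_um`,
#'   `max_intensity` (baseline-subtracted), `threshold_fraction`,
#'   `no_ais` flag. When the profile never exceeds the threshold, `no_ais`
#'   is `TRUE` and the boundaries are `NA`.
#' @export
detect_ais_bounds <- function(profile, threshold_fraction = 0.33,
                              smooth_window_um = 1,
                              baseline_flank_fraction = 0.1) {
  stopifnot(inherits(profile, "fluorescence_profile"))
  x <- profile$arc_length_um
  y <- profile$intensity
  dx <- stats::median(diff(x))
  if (smooth_window_um > 0) {
    k <- max(1L, round(smooth_window_um / dx))
    y <- moving_average(y, k)
  }
  base <- 0
  if (baseline_flank_fraction > 0) {
    nf <- max(1L, floor(baseline_flank_fraction * length(y)))
    base <- stats::median(c(y[seq_len(nf)], y[seq.int(length(y) - nf + 1,
                                                      length(y))]))
  }
  y <- y - base
  ymax <- max(y)
  if (ymax <= 0)
    return(structure(list(start_um = NA_real_, end_um = NA_real_,
                          length_um = NA_real_, max_intensity = ymax,
                          threshold_fraction = threshold_fraction,
                          no_ais = TRUE), class = "ais_bounds"))
  level <- threshold_fraction * ymax
  above <- y >= level
  if (!any(above))
    return(structure(list(start_um = NA_real_, end_um = NA_real_,
                          length_um = NA_real_, max_intensity = ymax,
                          threshold_fraction = threshold_fraction,
                          no_ais = TRUE), class = "ais_bounds"))
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  start_um <- if (i1 == 1) x[1] else {
    f <- (level - y[i1 - 1]) / (y[i1] - y[i1 - 1])
    x[i1 - 1] + f * (x[i1] - x[i1 - 1])
  }
  end_um <- if (i2 == length(y)) x[length(x)] else {
    f <- (y[i2] - level) / (y[i2] - y[i2 + 1])
    x[i2] + f * (x[i2 + 1] - x[i2])
  }
  structure(list(start_um = start_um, end_um = end_um,
                 length_um = end_um - start_um, max_intensity = ymax,
                 threshold_fraction = threshold_fraction, no_ais = FALSE),
            class = "ais_bounds")
}

#' @export
print.ais_bounds <- function(x, ...) {
  if (isTRUE(x$no_ais)) cat("<ais_bounds> no AIS detected\n")
  else cat(sprintf("<ais_bounds> [%.2f, %.2f] um, length %.2f um (%.2f of max)\n",
                   x$start_um, x$end_um, x$length_um, x$threshold_fraction))
  invisible(x)
}

#' AIS distance from the soma
#'
#' Distance between the end of the soma (eGFP signal) and the AIS start
#' (Ankyrin-G signal) along the trace. Negative distances (AIS overlapping
#' the soma label) are returned with an `overlap = TRUE` attribute.
#'
#' @param soma_end_um Position of the soma end on the trace, µm.
#' @param ais_start_um AIS start position, µm.
#' @return Distance in µm.
#' @export
distance_from_soma <- function(soma_end_um, ais_start_um) {
  d <- ais_start_um - soma_end_um
  if (is.finite(d) && d < 0) return(structure(d, overlap = TRUE))
  d
}

#' Aggregate per-cell measures to one value per stratum
#'
#' Arithmetic mean and count per animal x hemisphere x layer stratum (the
#' unit of analysis for the group models). Strata below `min_n` cells are
#' flagged; empty strata are absent from the output.
#'
#' @param dat Data frame with columns `animal_id`, `hemisphere`, `layer`
#'   and `value` (plus any grouping columns to carry through, e.g. `group`,
#'   `sex`).
#' @param value_col Name of the measurement column (default `"value"`).
#' @param min_n Minimal cell count per stratum before flagging.
#' @return A tibble with one row per stratum: the carried design columns,
#'   `mean_value`, `n_cells`, `below_min_n`.
#' @export
aggregate_per_stratum <- function(dat, value_col = "value", min_n = 1) {
  stopifnot(all(c("animal_id", "hemisphere", "layer", value_col) %in%
                  names(dat)))
  keys <- c("animal_id", "hemisphere", "layer")
  carry <- intersect(c("group", "sex"), names(dat))
  sp <- split(dat, interaction(dat[keys], drop = TRUE, lex.order = TRUE))
  rows <- lapply(sp, function(g) {
    out <- g[1, c(keys, carry), drop = FALSE]
    out$mean_value <- mean(g[[value_col]])
    out$n_cells <- nrow(g)
    out$below_min_n <- nrow(g) < min_n
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Construct a lesion section series
#'
#' Per-section lesion areas from a systematically sampled series: every
#' `series_factor`-th section of thickness `thickness_um` is measured.
#'
#' @param section_areas_um2 Traced lesion areas, µm² (>= 0).
#' @param thickness_um Section thickness, µm (default 30).
#' @param series_factor Integer sampling factor (default 3).
#' @return An object of class `lesion_series`.
#' @export
lesion_series <- function(section_areas_um2, thickness_um = 30,
                          series_factor = 3) {
  if (any(section_areas_um2 < 0)) stop("areas must be non-negative",
                                       call. = FALSE)
  if (thickness_um <= 0) stop("thickness must be positive", call. = FALSE)
  if (series_factor < 1 || series_factor != round(series_factor))
    stop("series_factor must be a positive integer", call. = FALSE)
  structure(list(section_areas_um2 = as.numeric(section_areas_um2),
                 thickness_um = thickness_um,
                 series_factor = as.integer(series_factor)),
            class = "lesion_series")
}

#' Lesion volume from a section series
#'
#' `sum(area_i * thickness) * series_factor / 1e9`: each traced area times
#' the section thickness, summed, scaled by the series sampling factor, and
#' converted from µm³ to mm³.
#'
#' @param series A [lesion_series()].
#' @return Lesion volume in mm³.
#' @examples
#' lesion_volume(lesion_series(1e6))   # 0.09 mm^3
#' @export
lesion_volume <- function(series) {
  stopifnot(inherits(series, "lesion_series"))
  sum(series$section_areas_um2 * series$thickness_um) *
    series$series_factor / 1e9
}

#' Compare 3D and 2D-projected path lengths of a traced polyline
#'
#' Arc length of a 3D path and of its XY (maximum-projection) shadow. For
#' pure polyline geometry the 3D length is always at least the 2D length.
#'
#' @param path3d_um Matrix with three columns (x, y, z) in µm.
#' @return List with `length3d_um` and `length2d_um`.
#' @export
compare_projection_length <- function(path3d_um) {
  path3d_um <- as.matrix(path3d_um)
  stopifnot(ncol(path3d_um) == 3, nrow(path3d_um) >= 2)
  seg <- diff(path3d_um)
  list(length3d_um = sum(sqrt(rowSums(seg^2))),
       length2d_um = sum(sqrt(rowSums(seg[, 1:2, drop = FALSE]^2))))
}
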
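# Rim topology: rim-band geometry, foci distance classification, rim
# occupancy and rim intensity profiles.

#' Rim geometry of a segmented nucleus
#'
#' Builds the rim reference for one nucleus: the ordered boundary contour
#' and the rim band (all nucleus pixels within `rim_width_um` of the
#' boundary).
#'
#' @param mask Binary nucleus mask.
#' @param pixel_size_um Pixel size (um/px).
#' @param rim_width_um Rim band width (um), default 0.5.
#' @param nucleus Nucleus label carried through to outputs.
#' @return An object of class `rim_geometry`: list with `nucleus`, `mask`,
#'   `contour` (0-based px, columns x/y), `rim_band` (binary matrix),
#'   `rim_width_um`, `pixel_size_um`.
#' @export
rim_geometry <- function(mask, pixel_size_um, rim_width_um = 0.5,
                         nucleus = 1L) {
  check_mask(mask)
  check_number(rim_width_um, "rim_width_um", 0, strict_min = TRUE)
  dist_in <- inside_distance(mask) * pixel_size_um
  band <- matrix(as.numeric(mask > 0 & dist_in <= rim_width_um),
                 nrow(mask), ncol(mask))
  structure(
    list(nucleus = nucleus, mask = as_binary(mask),
         contour = mask_contour(mask), rim_band = band,
         rim_width_um = rim_width_um, pixel_size_um = pixel_size_um),
    class = "rim_geometry"
  )
}

# Rim reference point set (0-based px): the lamina-channel intensity ridge
# when a rim channel is available, else the mask boundary contour. The
# ridge is found per contour sample by scanning inward (towards the
# centroid) over twice the rim width and taking the intensity maximum.
rim_reference_points <- function(rim, rim_channel = NULL) {
  if (is.null(rim_channel)) return(rim$contour)
  check_image(rim_channel)
  px <- rim$pixel_size_um
  ct <- rim$contour
  coords <- mask_coords(rim$mask)
  cx <- mean(coords[, 1]); cy <- mean(coords[, 2])
  depth_px <- 2 * rim$rim_width_um / px
  steps <- seq(0, depth_px, by = 0.5)
  t(apply(ct, 1L, function(p) {
    d <- c(cx, cy) - p
    len <- sqrt(sum(d^2))
    if (len < 1e-9) return(p)
    d <- d / len
    sx <- p[1] + d[1] * steps
    sy <- p[2] + d[2] * steps
    r <- pmin(pmax(round(sy) + 1L, 1L), nrow(rim_channel))
    c2 <- pmin(pmax(round(sx) + 1L, 1L), ncol(rim_channel))
    i <- which.max(rim_channel[cbind(r, c2)])
    c(sx[i], sy[i])
  }))
}

#' Classify foci as rim or nucleoplasmic by distance to the rim reference
#'
#' The distance of each focus centroid to the rim reference (the lamina
#' intensity ridge when `rim_channel` is given, otherwise the nucleus
#' boundary) is computed in um; foci strictly closer than `cutoff_um`
#' (default 0.5 um) are classified `rim`, all others `nucleoplasm`
#' (a distance exactly equal to the cutoff is nucleoplasm).
#'
#' @param foci Tibble of focus records ([detect_foci()]) for one nucleus.
#' @param rim A [rim_geometry()].
#' @param cutoff_um Classification cutoff (um), default 0.5.
#' @param rim_channel Optional lamina-channel image defining the ridge.
#' @return The foci tibble with `distance_to_rim_um` and `compartment`
#'   filled in.
#' @export
classify_foci <- function(foci, rim, cutoff_um = 0.5, rim_channel = NULL) {
  check_number(cutoff_um, "cutoff_um", 0, strict_min = TRUE)
  if (nrow(foci) == 0L) return(foci)
  px <- rim$pixel_size_um
  pts <- cbind(foci$x_um, foci$y_um) / px
  r <- pmin(pmax(round(pts[, 2]) + 1L, 1L), nrow(rim$mask))
  c2 <- pmin(pmax(round(pts[, 1]) + 1L, 1L), ncol(rim$mask))
  if (any(rim$mask[cbind(r, c2)] == 0)) {
    abort("focus centroid outside its nucleus mask.")
  }
  ref <- rim_reference_points(rim, rim_channel)
  d_um <- nearest_point_distance(pts, ref) * px
  dplyr::mutate(foci,
                distance_to_rim_um = d_um,
                compartment = ifelse(d_um < cutoff_um, "rim", "nucleoplasm"))
}

#' Per-nucleus rim/nucleoplasm counts and percentages
#'
#' @param foci Classified foci tibble ([classify_foci()]), possibly pooled
#'   over nuclei (requires `nucleus` and `compartment` columns).
#' @return Tibble per nucleus: `n_rim`, `n_nucleoplasm`, `n_total`,
#'   `pct_rim`, `pct_nucleoplasm`.
#' @export
rim_counts <- function(foci) {
  dplyr::summarise(
    dplyr::group_by(foci, .data$nucleus),
    n_rim = sum(.data$compartment == "rim"),
    n_nucleoplasm = sum(.data$compartment == "nucleoplasm"),
    n_total = dplyr::n(),
    pct_rim = 100 * .data$n_rim / .data$n_total,
    pct_nucleoplasm = 100 * .data$n_nucleoplasm / .data$n_total,
    .groups = "drop"
  )
}

#' Percentage of the nuclear rim occupied by punctate signal
#'
#' Samples the boundary contour at pixel resolution and marks a sample
#' positive when any foreground pixel of the foci mask lies within
#' `occupancy_radius_um` of it; returns 100 x positive / total samples.
#'
#' @param foci_mask Binary image of detected foci pixels.
#' @param rim A [rim_geometry()].
#' @param occupancy_radius_um Capture radius (um); default 0.25, half the
#'   rim classification cutoff.
#' @return Percentage (0-100).
#' @export
percent_positive_rim <- function(foci_mask, rim, occupancy_radius_um = 0.25) {
  check_mask(foci_mask)
  check_number(occupancy_radius_um, "occupancy_radius_um", 0, strict_min = TRUE)
  ct <- rim$contour
  if (nrow(ct) == 0L) abort("empty contour.")
  if (sum(foci_mask) == 0) return(0)
  # distance from every pixel to the nearest foci pixel
  dt <- as.matrix(EBImage::distmap(1 - as_binary(foci_mask))) * rim$pixel_size_um
  d <- dt[cbind(ct[, 2] + 1L, ct[, 1] + 1L)]
  100 * mean(d <= occupancy_radius_um)
}

#' Intensity profile along the nuclear rim
#'
#' At each boundary-contour sample (1-px spacing), the mean intensity of
#' `channel` over a disc of radius `window_um` is recorded against the
#' cumulative arc length in um.
#'
#' @param channel Numeric matrix registered to the nucleus mask.
#' @param rim A [rim_geometry()].
#' @param window_um Averaging-disc radius (um).
#' @return Tibble: `sample`, `arc_um` (strictly increasing, covering the
#'   perimeter), `intensity`.
#' @export
rim_profile <- function(channel, rim, window_um = 0.2) {
  check_image(channel)
  check_number(window_um, "window_um", 0, strict_min = TRUE)
  px <- rim$pixel_size_um
  coords <- mask_coords(rim$mask)
  mxx <- stats::var(coords[, 1]); myy <- stats::var(coords[, 2])
  minor_um <- 4 * sqrt(min(mxx, myy)) * px
  if (window_um > minor_um) {
    abort("window_um exceeds the nucleus minor axis.")
  }
  brush <- disc_brush(window_um / px)
  local_mean <- as.matrix(EBImage::filter2(channel, brush / sum(brush)))
  ct <- rim$contour
  steps <- sqrt(diff(ct[, 1])^2 + diff(ct[, 2])^2)
  tibble(
    sample = seq_len(nrow(ct)),
    arc_um = cumsum(c(0, steps)) * px,
    intensity = local_mean[cbind(ct[, 2] + 1L, ct[, 1] + 1L)]
  )
}
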
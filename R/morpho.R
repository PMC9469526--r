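# Nuclear shape descriptors, bleb counting and the composite aberration
# metrics used to score laminopathy-like nuclear dysmorphism.

# Crofton perimeter estimate (px) from transition counts in 4 directions.
# Raw boundary-pixel counting systematically inflates the perimeter of
# smooth shapes (and hence deflates circularity); the Crofton estimator is
# unbiased for discs in expectation.
crofton_perimeter <- function(mask) {
  m <- as_binary(mask)
  padded <- rbind(0, cbind(0, m, 0), 0)
  h <- sum(abs(padded[, -1] - padded[, -ncol(padded)]))
  v <- sum(abs(padded[-1, ] - padded[-nrow(padded), ]))
  p1 <- padded[-nrow(padded), -ncol(padded)]
  d1 <- sum(abs(padded[-1, -1] - p1))
  p2 <- padded[-nrow(padded), -1]
  d2 <- sum(abs(padded[-1, -ncol(padded)] - p2))
  pi / 8 * (h + v + (d1 + d2) / sqrt(2))
}

# Convex hull polygon area over pixel centres. For a convex digitized
# region this slightly undershoots the pixel count (the hull polygon cuts
# through boundary pixel centres), so solidity of convex shapes lands at
# 1 after clamping; concave features enlarge the hull far beyond this
# half-pixel effect.
hull_area_px <- function(mask) {
  xy <- mask_coords(mask)
  hull <- grDevices::chull(xy)
  polygon_area(xy[hull, , drop = FALSE])
}

#' Nuclear shape descriptors
#'
#' Computes the three classical dimensionless indices of nuclear
#' dysmorphism together with their ingredients:
#' circularity = 4 pi area / perimeter^2 (Crofton perimeter estimate),
#' roundness = 4 area / (pi major_axis^2) with the major axis from the
#' second-moment ellipse fit (equal to minor/major for a true ellipse), and
#' solidity = area / convex hull area. Indices are clamped at 1 to absorb
#' rasterization overshoot on small regions.
#'
#' @param mask Binary matrix, one connected nucleus (>= 16 px).
#' @param pixel_size_um Pixel size (um/px).
#' @return One-row tibble: `area_um2`, `perimeter_um`, `major_axis_um`,
#'   `convex_hull_area_um2`, `circularity`, `roundness`, `solidity`.
#' @export
#' @examples
#' m <- matrix(0, 41, 41)
#' m[(row(m) - 21)^2 + (col(m) - 21)^2 <= 15^2] <- 1
#' shape_descriptors(m, pixel_size_um = 0.1)
shape_descriptors <- function(mask, pixel_size_um) {
  check_mask(mask)
  check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE)
  xy <- mask_coords(mask)
  if (nrow(xy) < 16L) abort("mask too small: area must be >= 16 px.")
  if (max(as.matrix(EBImage::bwlabel(as_binary(mask)))) != 1L) {
    abort("mask must be a single connected component.")
  }
  px <- pixel_size_um
  area_px <- nrow(xy)

  # second-moment ellipse fit; + 1/12 accounts for the unit pixel extent
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  mxx <- mean((xy[, 1] - cx)^2)
  myy <- mean((xy[, 2] - cy)^2)
  mxy <- mean((xy[, 1] - cx) * (xy[, 2] - cy))
  ev_raw <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
  if (ev_raw[2] <= 1e-9) abort("axis undefined: degenerate (line-like) mask.")
  ev <- eigen(matrix(c(mxx + 1 / 12, mxy, mxy, myy + 1 / 12), 2, 2),
              symmetric = TRUE)$values
  major_px <- 4 * sqrt(ev[1])

  perim_px <- crofton_perimeter(mask)
  hull_px <- hull_area_px(mask)

  tibble(
    area_um2 = area_px * px^2,
    perimeter_um = perim_px * px,
    major_axis_um = major_px * px,
    convex_hull_area_um2 = max(hull_px, area_px) * px^2,
    circularity = min(1, 4 * pi * area_px / perim_px^2),
    roundness = min(1, 4 * area_px / (pi * major_px^2)),
    solidity = min(1, area_px / hull_px)
  )
}

#' Count nuclear blebs by opening residue
#'
#' A bleb is operationalized as a connected component of the difference
#' between the mask and its morphological opening with a disc of radius
#' `r_open_um`, provided it is at least `min_bleb_area_um2` large and
#' touches the mask boundary. Smooth convex nuclei give 0.
#'
#' @param mask Binary nucleus mask.
#' @param pixel_size_um Pixel size (um/px).
#' @param r_open_um Opening disc radius (um), default 1.
#' @param min_bleb_area_um2 Minimum residue area to count (um^2), default 0.5.
#' @return Integer bleb count.
#' @export
count_blebs <- function(mask, pixel_size_um, r_open_um = 1,
                        min_bleb_area_um2 = 0.5) {
  check_mask(mask)
  check_number(r_open_um, "r_open_um", 0, strict_min = TRUE)
  px <- pixel_size_um
  xy <- mask_coords(mask)
  if (nrow(xy) == 0L) abort("empty mask.")
  # guard: the opening disc must fit inside the nucleus body
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  mxx <- mean((xy[, 1] - cx)^2); myy <- mean((xy[, 2] - cy)^2)
  mxy <- mean((xy[, 1] - cx) * (xy[, 2] - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
  minor_px <- 4 * sqrt(max(ev[2], 0))
  if (2 * r_open_um / px > minor_px) {
    abort("r_open_um exceeds the nucleus minor axis; choose a smaller opening radius.")
  }

  m <- as_binary(mask)
  opened <- as.matrix(EBImage::opening(m, disc_brush(r_open_um / px)))
  residue <- matrix(as.numeric(m > 0 & opened == 0), nrow(m), ncol(m))
  if (sum(residue) == 0) return(0L)
  lab <- as.matrix(EBImage::bwlabel(residue))
  # boundary pixels of the original mask (4-neighbour erosion complement)
  er <- as.matrix(EBImage::erode(m, EBImage::makeBrush(3, "diamond")))
  boundary <- m > 0 & er == 0
  min_px_area <- min_bleb_area_um2 / px^2
  n <- 0L
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    if (sum(comp) >= min_px_area && any(boundary[comp])) n <- n + 1L
  }
  n
}

#' Reference shape means from a designated condition
#'
#' @param morpho Tibble of per-nucleus morphometry (from
#'   [shape_descriptors()] rows, with a `condition` column).
#' @param reference Name of the reference (wild-type-like) condition.
#' @return Named list with `circularity`, `roundness`, `solidity` means.
#' @export
reference_means <- function(morpho, reference) {
  if (!reference %in% morpho$condition) {
    abort(sprintf("reference condition '%s' not present.", reference))
  }
  ref <- dplyr::filter(morpho, .data$condition == reference)
  list(circularity = mean(ref$circularity),
       roundness = mean(ref$roundness),
       solidity = mean(ref$solidity))
}

#' Per-nucleus aberration index and simultaneous-deviation flag
#'
#' The aberration index is the signed sum of deviations of the three shape
#' indices from the reference means, oriented so that larger means more
#' aberrant: (circ_ref - circ) + (sol_ref - sol) + (round - round_ref).
#' A nucleus is flagged `aberrant` when it simultaneously shows lower
#' circularity, lower solidity and higher roundness than the reference.
#'
#' @param morpho Tibble with `circularity`, `roundness`, `solidity` columns
#'   (one row per nucleus; other columns are preserved).
#' @param ref Reference means from [reference_means()] (or a named list).
#' @return The input tibble with `aberration_index` and `aberrant` added.
#' @export
aberration <- function(morpho, ref) {
  if (is.null(ref) || !all(c("circularity", "roundness", "solidity") %in% names(ref))) {
    abort("missing reference means: supply reference_means() output.")
  }
  dplyr::mutate(
    morpho,
    aberration_index = (ref$circularity - .data$circularity) +
      (ref$solidity - .data$solidity) +
      (.data$roundness - ref$roundness),
    aberrant = .data$circularity < ref$circularity &
      .data$solidity < ref$solidity &
      .data$roundness > ref$roundness
  )
}

#' Percentage of aberrant nuclei in a population
#'
#' @param results Tibble with a logical `aberrant` column ([aberration()]).
#' @return Percentage (0-100).
#' @export
population_aberrant_fraction <- function(results) {
  if (nrow(results) == 0L) abort("empty result set.")
  100 * mean(results$aberrant)
}

#' Per-condition morphometry summary
#'
#' Mean and SEM of each shape index plus the aberrant fraction, per
#' condition.
#'
#' @param morpho Tibble of per-nucleus morphometry with `condition`,
#'   `aberration_index` and `aberrant` columns.
#' @return Tibble with one row per condition.
#' @export
summarize_morphometry <- function(morpho) {
  sem <- function(x) sd(x) / sqrt(length(x))
  dplyr::summarise(
    dplyr::group_by(morpho, .data$condition),
    n = dplyr::n(),
    dplyr::across(c("circularity", "roundness", "solidity", "aberration_index"),
                  list(mean = mean, sem = sem)),
    aberrant_pct = 100 * mean(.data$aberrant),
    .groups = "drop"
  )
}
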
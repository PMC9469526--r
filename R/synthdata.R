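#' Specification for one synthetic nucleus image
#'
#' Bundles every parameter of the synthetic multi-channel nucleus generator:
#' an elliptical nucleus whose boundary is modulated by low-order Fourier
#' wrinkles and decorated with bleb lobes; a lamina-like rim band just inside
#' the boundary (optionally interrupted by a contiguous gap arc); and a
#' punctate channel whose foci sit inside the rim band with probability
#' `rim_fraction` and otherwise uniformly in the interior. All channels are
#' blurred by a Gaussian PSF and corrupted by Poisson photon noise followed
#' by additive Gaussian read noise (the standard camera model).
#'
#' @param image_size_px Integer pair, image height and width in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel. The default
#'   0.04 corresponds to structured-illumination-scale sampling, so a 0.5 um
#'   distance spans ~12 px.
#' @param ellipse_axes_um Semi-axes (a, b) of the base ellipse in um, a >= b.
#' @param wrinkle_amplitude Total radial modulation as a fraction of the
#'   local ellipse radius; must be < 0.5 so the boundary stays simple.
#' @param wrinkle_order Number of random Fourier boundary modes.
#' @param bleb_count Number of circular bleb lobes attached to the boundary.
#' @param bleb_radius_um Bleb radius in um. The 0.75 default keeps blebs
#'   smaller than the 1 um opening disc of [count_blebs()]: the
#'   opening-residue counter can only see lobes that cannot inscribe the
#'   opening disc.
#' @param rim_band_width_um Width of the rim band, measured inward from the
#'   boundary, in um.
#' @param rim_gap_fraction Fraction (0-1) of the perimeter covered by one
#'   contiguous rim interruption (the gap arc is set to background).
#' @param n_foci Number of punctate foci to place.
#' @param rim_fraction Probability that a focus is placed inside the rim
#'   band (else uniformly in the interior).
#' @param focus_sigma_um Gaussian PSF sigma in um; also sets the 3-sigma
#'   minimum centre separation enforced between foci.
#' @param focus_intensity Peak amplitude of a rendered focus (arbitrary
#'   units; the DNA and rim channels have unit amplitude).
#' @param background Constant background level added to all channels.
#' @param poisson_scale Photon scale for Poisson noise: intensities are
#'   multiplied by this, Poisson-sampled, and divided back. 0 disables.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#'
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
#' @examples
#' spec <- synthetic_spec(n_foci = 5, seed = 2)
#' nuc <- simulate_nucleus(spec)
#' dim(nuc$channels$dna)
synthetic_spec <- function(image_size_px = c(384L, 384L),
                           pixel_size_um = 0.04,
                           ellipse_axes_um = c(5, 3.8),
                           wrinkle_amplitude = 0.02,
                           wrinkle_order = 6L,
                           bleb_count = 0L,
                           bleb_radius_um = 0.75,
                           rim_band_width_um = 0.4,
                           rim_gap_fraction = 0,
                           n_foci = 20L,
                           rim_fraction = 0.8,
                           focus_sigma_um = 0.08,
                           focus_intensity = 1,
                           background = 0.1,
                           poisson_scale = 200,
                           read_noise_sd = 0.01,
                           seed = 1L) {
  spec <- list(
    image_size_px = as.integer(rep_len(image_size_px, 2L)),
    pixel_size_um = pixel_size_um,
    ellipse_axes_um = as.numeric(ellipse_axes_um),
    wrinkle_amplitude = wrinkle_amplitude,
    wrinkle_order = as.integer(wrinkle_order),
    bleb_count = as.integer(bleb_count),
    bleb_radius_um = bleb_radius_um,
    rim_band_width_um = rim_band_width_um,
    rim_gap_fraction = rim_gap_fraction,
    n_foci = as.integer(n_foci),
    rim_fraction = rim_fraction,
    focus_sigma_um = focus_sigma_um,
    focus_intensity = focus_intensity,
    background = background,
    poisson_scale = poisson_scale,
    read_noise_sd = read_noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
}

validate_spec <- function(spec) {
  if (any(spec$image_size_px < 16L)) abort("image_size_px must be >= 16.")
  check_number(spec$pixel_size_um, "pixel_size_um", 0, strict_min = TRUE)
  if (length(spec$ellipse_axes_um) != 2L || any(spec$ellipse_axes_um <= 0)) {
    abort("ellipse_axes_um must be two positive semi-axes.")
  }
  if (spec$ellipse_axes_um[1] < spec$ellipse_axes_um[2]) {
    abort("ellipse_axes_um must satisfy a >= b.")
  }
  check_number(spec$wrinkle_amplitude, "wrinkle_amplitude", 0, 0.5 - 1e-12)
  if (spec$wrinkle_order < 1L) abort("wrinkle_order must be >= 1.")
  if (spec$bleb_count < 0L) abort("bleb_count must be >= 0.")
  check_number(spec$bleb_radius_um, "bleb_radius_um", 0, strict_min = TRUE)
  check_number(spec$rim_band_width_um, "rim_band_width_um", 0, strict_min = TRUE)
  check_number(spec$rim_gap_fraction, "rim_gap_fraction", 0, 1)
  if (spec$n_foci < 0L) abort("n_foci must be >= 0.")
  check_number(spec$rim_fraction, "rim_fraction", 0, 1)
  check_number(spec$focus_sigma_um, "focus_sigma_um", 0, strict_min = TRUE)
  check_number(spec$background, "background", 0)
  check_number(spec$poisson_scale, "poisson_scale", 0)
  check_number(spec$read_noise_sd, "read_noise_sd", 0)
  spec
}

# Boundary radius (um) of the base shape at polar angles theta, given the
# per-mode wrinkle amplitudes/phases drawn for this nucleus.
boundary_radius <- function(theta, axes, modes) {
  a <- axes[1]; b <- axes[2]
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  mod <- rep(0, length(theta))
  if (nrow(modes) > 0L) {
    for (i in seq_len(nrow(modes))) {
      mod <- mod + modes$amplitude[i] * cos(modes$k[i] * theta + modes$phase[i])
    }
  }
  r_ell * (1 + mod)
}

#' Generate the binary nucleus shape for a synthetic spec
#'
#' Rasterizes the wrinkled-ellipse boundary and attaches bleb lobes, and
#' records analytic ground truth for the base shape.
#'
#' Bleb lobes are shallow circular caps: each bleb disc centre sits
#' 0.25 x bleb radius outside the boundary, so the protruding cap is visible
#' (height about 1.25 x radius) but never so deep that a 1 um opening disc
#' fits inside it, keeping the opening-residue bleb counter well posed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `mask` (binary matrix), `boundary` (dense
#'   polygon of the base boundary, um), `center_um`, `truth_nucleus`
#'   (one-row tibble: analytic area/perimeter of the base shape, axes and
#'   bleb count) and `truth_blebs` (tibble of bleb centres, um).
#' @export
generate_nucleus_shape <- function(spec) {
  spec <- validate_spec(spec)
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  h <- spec$image_size_px[1]; w <- spec$image_size_px[2]
  cx <- (w - 1) / 2 * px
  cy <- (h - 1) / 2 * px

  # random Fourier wrinkle modes; per-mode amplitudes sum to the requested
  # total so the maximal radial deviation is bounded by wrinkle_amplitude
  n_modes <- spec$wrinkle_order
  u <- runif(n_modes)
  modes <- tibble(
    k = seq(2L, length.out = n_modes),
    amplitude = if (spec$wrinkle_amplitude > 0) spec$wrinkle_amplitude * u / sum(u) else rep(0, n_modes),
    phase = runif(n_modes, 0, 2 * pi)
  )

  theta_grid <- seq(0, 2 * pi, length.out = 4096L + 1L)[-1L]
  r_grid <- boundary_radius(theta_grid, spec$ellipse_axes_um, modes)
  if (any(r_grid <= 0) || any(!is.finite(r_grid))) {
    abort("spec produces a self-intersecting boundary (radius <= 0); reduce wrinkle_amplitude.")
  }

  # rasterize: pixel centre inside iff polar radius <= boundary radius
  xs <- (seq_len(w) - 1) * px - cx
  ys <- (seq_len(h) - 1) * px - cy
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  th <- atan2(Y, X)
  rr <- sqrt(X^2 + Y^2)
  rb <- matrix(boundary_radius(as.vector(th), spec$ellipse_axes_um, modes), h, w)
  mask <- matrix(as.numeric(rr <= rb), h, w)

  # attach bleb lobes at random, angularly separated boundary positions
  truth_blebs <- tibble(bleb = integer(), angle = numeric(),
                        x_um = numeric(), y_um = numeric())
  if (spec$bleb_count > 0L) {
    min_sep <- 2.5 * spec$bleb_radius_um / mean(spec$ellipse_axes_um)
    angles <- numeric(0)
    attempts <- 0L
    while (length(angles) < spec$bleb_count && attempts < 1000L) {
      cand <- runif(1, 0, 2 * pi)
      if (!length(angles) ||
          all(pmin(abs(cand - angles), 2 * pi - abs(cand - angles)) > min_sep)) {
        angles <- c(angles, cand)
      }
      attempts <- attempts + 1L
    }
    if (length(angles) < spec$bleb_count) {
      abort("could not place bleb_count blebs with angular separation; reduce bleb_count or bleb_radius_um.")
    }
    rb_at <- boundary_radius(angles, spec$ellipse_axes_um, modes)
    bx <- (rb_at + 0.25 * spec$bleb_radius_um) * cos(angles)
    by <- (rb_at + 0.25 * spec$bleb_radius_um) * sin(angles)
    for (i in seq_along(angles)) {
      mask[(X - bx[i])^2 + (Y - by[i])^2 <= spec$bleb_radius_um^2] <- 1
    }
    truth_blebs <- tibble(bleb = seq_along(angles), angle = angles,
                          x_um = bx + cx, y_um = by + cy)
  }

  mask <- as.matrix(EBImage::fillHull(mask))
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1L) {
    abort("spec produced a disconnected mask; blebs must overlap the boundary.")
  }
  if (any(mask[1, ] != 0) || any(mask[h, ] != 0) ||
      any(mask[, 1] != 0) || any(mask[, w] != 0)) {
    abort("nucleus touches the image border; enlarge image_size_px.")
  }

  boundary <- cbind(x_um = r_grid * cos(theta_grid) + cx,
                    y_um = r_grid * sin(theta_grid) + cy)
  seg <- sqrt(diff(c(boundary[, 1], boundary[1, 1]))^2 +
              diff(c(boundary[, 2], boundary[1, 2]))^2)
  truth_nucleus <- tibble(
    area_um2 = polygon_area(boundary),
    perimeter_um = sum(seg),
    major_axis_um = 2 * spec$ellipse_axes_um[1],
    minor_axis_um = 2 * spec$ellipse_axes_um[2],
    mask_area_um2 = sum(mask) * px^2,
    bleb_count = spec$bleb_count
  )

  list(mask = mask, boundary = boundary, center_um = c(x = cx, y = cy),
       modes = modes, truth_nucleus = truth_nucleus, truth_blebs = truth_blebs)
}

# deposit a unit impulse at sub-pixel position (x, y) um via bilinear weights
deposit_spot <- function(img, x_um, y_um, value, px) {
  xc <- x_um / px; yc <- y_um / px        # 0-based pixel coords
  x0 <- floor(xc); y0 <- floor(yc)
  fx <- xc - x0; fy <- yc - y0
  for (dy in 0:1) for (dx in 0:1) {
    r <- y0 + dy + 1L; c <- x0 + dx + 1L
    if (r >= 1L && r <= nrow(img) && c >= 1L && c <= ncol(img)) {
      wgt <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
      img[r, c] <- img[r, c] + value * wgt
    }
  }
  img
}

#' Render the three channels of a synthetic nucleus
#'
#' Channel roles mirror a DNA stain (filled nucleus), a lamina rim band and
#' a punctate factor. Foci are placed in the rim band with probability
#' `rim_fraction`, else uniformly in the interior, with pairwise centre
#' separation of at least 3 x `focus_sigma_um` enforced by rejection
#' sampling. Rim foci are co-placed with the rendered rim signal: when the
#' band carries a gap arc, foci avoid the gap too. All channels are
#' PSF-blurred and corrupted by Poisson then Gaussian read noise.
#'
#' @param shape Output of [generate_nucleus_shape()].
#' @param spec The same [synthetic_spec()].
#' @return A list with `channels` (named list of matrices: dna, rim, foci),
#'   `rim_band` (binary matrix, before the gap is applied), `truth_foci`
#'   (tibble: focus, x_um, y_um, placed_rim, dist_to_boundary_um) and
#'   `gap_arc` (start/end arc-length positions of the rim gap, um).
#' @export
render_channels <- function(shape, spec) {
  spec <- validate_spec(spec)
  set.seed((spec$seed + 499979L) %% .Machine$integer.max)
  px <- spec$pixel_size_um
  mask <- shape$mask
  h <- nrow(mask); w <- ncol(mask)

  dist_in <- inside_distance(mask) * px
  rim_band <- matrix(as.numeric(mask > 0 & dist_in <= spec$rim_band_width_um), h, w)
  interior <- matrix(as.numeric(mask > 0 & dist_in > spec$rim_band_width_um), h, w)

  # rim channel with an optional contiguous gap arc, sized by arc length
  rim_ch <- rim_band
  gap_arc <- c(NA_real_, NA_real_)
  if (spec$rim_gap_fraction > 0) {
    bd <- shape$boundary
    seg <- sqrt(diff(c(bd[, 1], bd[1, 1]))^2 + diff(c(bd[, 2], bd[1, 2]))^2)
    arc <- cumsum(seg)
    total <- arc[length(arc)]
    start_arc <- runif(1, 0, total)
    end_arc <- start_arc + spec$rim_gap_fraction * total
    idx_arc <- (arc - start_arc) %% total
    in_gap <- idx_arc <= spec$rim_gap_fraction * total
    # gap membership decided by polar angle interval(s) of the gap arc
    cx <- shape$center_um[1]; cy <- shape$center_um[2]
    th_bd <- atan2(bd[, 2] - cy, bd[, 1] - cx)
    gap_th <- th_bd[in_gap]
    coords <- mask_coords(rim_band)
    th_px <- atan2(coords[, 2] * px - cy, coords[, 1] * px - cx)
    # match each rim pixel to nearest boundary angle in the gap set
    tol <- 2 * pi / length(th_bd) * 4
    is_gap <- vapply(th_px, function(t) {
      min(pmin(abs(t - gap_th), 2 * pi - abs(t - gap_th))) <= tol
    }, logical(1))
    gp <- coords[is_gap, , drop = FALSE]
    rim_ch[cbind(gp[, 2] + 1L, gp[, 1] + 1L)] <- 0
    gap_arc <- c(start_arc, end_arc %% total)
  }

  # place foci with 3-sigma minimum separation by rejection sampling;
  # rim foci are co-placed with the rendered rim signal (post-gap band),
  # so a rim interruption is also devoid of foci
  contour <- mask_contour(mask)
  min_sep <- 3 * spec$focus_sigma_um
  rim_px_set <- mask_coords(rim_ch)
  int_px_set <- mask_coords(interior)
  if (spec$n_foci > 0L && (nrow(rim_px_set) == 0L || nrow(int_px_set) == 0L)) {
    abort("nucleus too small: rim band or interior has no pixels to place foci in.")
  }
  placed <- matrix(numeric(0), ncol = 2)
  placed_rim <- logical(0)
  attempts <- 0L
  max_attempts <- 400L * max(spec$n_foci, 1L)
  while (nrow(placed) < spec$n_foci) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "could not place %d foci with %.3f um minimum separation (3 x focus_sigma_um) inside the nucleus; reduce n_foci or focus_sigma_um.",
        spec$n_foci, min_sep))
    }
    in_rim <- runif(1) < spec$rim_fraction
    set <- if (in_rim) rim_px_set else int_px_set
    i <- sample.int(nrow(set), 1L)
    cand <- (set[i, ] + runif(2, -0.5, 0.5)) * px
    if (nrow(placed) == 0L ||
        min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2)) >= min_sep) {
      placed <- rbind(placed, cand)
      placed_rim <- c(placed_rim, in_rim)
    }
  }

  truth_foci <- tibble(
    focus = seq_len(spec$n_foci),
    x_um = if (spec$n_foci) placed[, 1] else numeric(0),
    y_um = if (spec$n_foci) placed[, 2] else numeric(0),
    placed_rim = placed_rim,
    dist_to_boundary_um = if (spec$n_foci) {
      nearest_point_distance(placed / px, contour) * px
    } else numeric(0)
  )

  foci_ch <- matrix(0, h, w)
  sigma_px <- spec$focus_sigma_um / px
  amp <- spec$focus_intensity * 2 * pi * sigma_px^2   # post-blur peak = focus_intensity
  if (spec$n_foci > 0L) {
    for (i in seq_len(spec$n_foci)) {
      foci_ch <- deposit_spot(foci_ch, placed[i, 1], placed[i, 2], amp, px)
    }
  }

  blur <- function(img) as.matrix(EBImage::gblur(img, sigma = sigma_px))
  degrade <- function(img) {
    img <- img + spec$background
    if (spec$poisson_scale > 0) {
      img <- matrix(rpois(length(img), pmax(img, 0) * spec$poisson_scale) /
                      spec$poisson_scale, h, w)
    }
    if (spec$read_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$read_noise_sd), h, w)
    }
    img
  }

  channels <- list(
    dna = degrade(blur(mask)),
    rim = degrade(blur(rim_ch)),
    foci = degrade(blur(foci_ch))
  )
  list(channels = channels, rim_band = rim_band, truth_foci = truth_foci,
       gap_arc = gap_arc)
}

#' Simulate one complete synthetic nucleus
#'
#' Convenience wrapper: [generate_nucleus_shape()] followed by
#' [render_channels()].
#'
#' @inheritParams generate_nucleus_shape
#' @return A list combining both outputs: `mask`, `boundary`, `channels`,
#'   `rim_band`, `truth_nucleus`, `truth_blebs`, `truth_foci`.
#' @export
simulate_nucleus <- function(spec) {
  shape <- generate_nucleus_shape(spec)
  rend <- render_channels(shape, spec)
  c(shape[c("mask", "boundary", "center_um", "truth_nucleus", "truth_blebs")],
    rend)
}

#' Shape-class presets for the three nuclear phenotypes
#'
#' Returns generator specs emulating the canonical morphologies: a
#' wild-type-like fibroblast nucleus (smooth ellipse), an HGPS-like nucleus
#' (rounder outline with strong wrinkling and blebs — progeria nuclei lose
#' elongation while gaining boundary irregularity), and an MCF7-like tumor
#' nucleus (elongated, strongly wrinkled, with rim interruptions).
#'
#' @param ... Overrides applied to every preset (e.g. `n_foci = 0`).
#' @return Named list of [synthetic_spec()] objects (`wt`, `hgps`, `mcf7`).
#' @export
#' @examples
#' specs <- shape_class_specs(n_foci = 0)
#' names(specs)
shape_class_specs <- function(...) {
  overrides <- list(...)
  build <- function(args) do.call(synthetic_spec, utils::modifyList(args, overrides))
  list(
    wt = build(list(ellipse_axes_um = c(5, 3.8), wrinkle_amplitude = 0.02,
                    bleb_count = 0L)),
    hgps = build(list(ellipse_axes_um = c(4.6, 4.3), wrinkle_amplitude = 0.12,
                      bleb_count = 3L)),
    mcf7 = build(list(ellipse_axes_um = c(5.2, 3.5), wrinkle_amplitude = 0.18,
                      bleb_count = 1L, rim_gap_fraction = 0.25))
  )
}

# deterministic per-nucleus seed, independently reproducible per condition
derive_seed <- function(master_seed, condition, i) {
  chash <- sum(utf8ToInt(condition)) %% 9973L
  as.integer((as.numeric(master_seed) * 100003 + chash * 1009 + i) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Generate a population of synthetic nuclei across conditions
#'
#' @param n_nuclei Nuclei per condition.
#' @param spec_per_condition Named list mapping condition name to a
#'   [synthetic_spec()]; names must be unique.
#' @param seed Master seed; per-nucleus seeds are derived deterministically
#'   from it and the condition name, so each condition is reproducible on
#'   its own.
#' @return A list with `nuclei` (tibble: condition, nucleus, and list-columns
#'   `channels`, `mask`, `rim_band`), `truth_nuclei` and `truth_foci`
#'   tibbles keyed by (condition, nucleus).
#' @export
generate_population <- function(n_nuclei, spec_per_condition, seed = 1L) {
  if (n_nuclei < 1L) abort("n_nuclei must be >= 1.")
  nms <- names(spec_per_condition)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("spec_per_condition must be a uniquely named list of conditions.")
  }
  rows <- purrr::map(nms, function(cond) {
    purrr::map(seq_len(n_nuclei), function(i) {
      sp <- spec_per_condition[[cond]]
      sp$seed <- derive_seed(seed, cond, i)
      nuc <- simulate_nucleus(sp)
      list(
        row = tibble(condition = cond, nucleus = i,
                     channels = list(nuc$channels), mask = list(nuc$mask),
                     rim_band = list(nuc$rim_band)),
        tn = dplyr::mutate(nuc$truth_nucleus, condition = cond, nucleus = i,
                           .before = 1),
        tf = dplyr::mutate(nuc$truth_foci, condition = cond, nucleus = i,
                           .before = 1)
      )
    })
  })
  rows <- purrr::flatten(rows)
  list(
    nuclei = dplyr::bind_rows(purrr::map(rows, "row")),
    truth_nuclei = dplyr::bind_rows(purrr::map(rows, "tn")),
    truth_foci = dplyr::bind_rows(purrr::map(rows, "tf"))
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes one multi-channel TIFF per nucleus (channel order dna, rim, foci,
#' recorded in a sidecar YAML), a ground-truth CSV pair, and the generator
#' parameters.
#'
#' Channel intensities are rescaled to the TIFF 0-1 range per file; all
#' downstream measures are either intensity-free or affine-invariant
#' (Pearson) or re-thresholded per image, so the rescaling is harmless.
#'
#' @inheritParams generate_population
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a tibble manifest of (condition, nucleus, path).
#' @export
simulate_dataset <- function(spec_per_condition, n_nuclei, out_dir, seed = 1L) {
  pop <- generate_population(n_nuclei, spec_per_condition, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::pmap_dfr(
    pop$nuclei[, c("condition", "nucleus", "channels")],
    function(condition, nucleus, channels) {
      path <- file.path(out_dir, sprintf("%s_nucleus%03d.tif", condition, nucleus))
      planes <- lapply(channels, function(m) {
        m <- pmax(m, 0)
        if (max(m) > 0) m <- m / max(m)
        m
      })
      # writeTIFF writes each list element as one directory (plane)
      tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                      compression = "none")
      tibble(condition = condition, nucleus = nucleus, path = path)
    }
  )
  readr::write_csv(pop$truth_nuclei, file.path(out_dir, "truth_nuclei.csv"))
  readr::write_csv(pop$truth_foci, file.path(out_dir, "truth_foci.csv"))
  sidecar <- list(
    channel_order = c("dna", "rim", "foci"),
    pixel_size_um = spec_per_condition[[1]]$pixel_size_um,
    n_nuclei = n_nuclei,
    seed = seed,
    conditions = names(spec_per_condition)
  )
  yaml::write_yaml(sidecar, file.path(out_dir, "dataset.yaml"))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
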
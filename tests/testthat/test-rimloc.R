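# Rim geometry, distance classification, occupancy and profiles.

make_disk_rim <- function(r_px = 60, px = 0.04, width_um = 0.5) {
  mask <- disk_mask(r_px)
  rim_geometry(mask, px, width_um)
}

test_that("foci are classified by the strict 0.5 um cutoff", {
  px <- 0.04
  rim <- make_disk_rim(60, px)
  c0 <- unname(which(rim$mask != 0, arr.ind = TRUE) |> colMeans())  # row, col
  center_um <- c((c0[2] - 1) * px, (c0[1] - 1) * px)
  place <- function(dist_um) {
    r_um <- 60 * px - dist_um
    tibble::tibble(nucleus = 1L, focus = 1L,
                   x_um = center_um[1] + r_um, y_um = center_um[2],
                   area_um2 = 0.01, peak = 1,
                   distance_to_rim_um = NA_real_, compartment = NA_character_)
  }
  on_boundary <- classify_foci(place(0), rim)
  expect_identical(on_boundary$compartment, "rim")
  expect_lt(on_boundary$distance_to_rim_um, 0.05)

  expect_identical(classify_foci(place(0.3), rim)$compartment, "rim")
  expect_identical(classify_foci(place(0.7), rim)$compartment, "nucleoplasm")
  # distance exactly at the cutoff is nucleoplasm ("below" is strict)
  exact <- place(0.3)
  exact$x_um <- center_um[1]  # nucleus centre, far from rim
  far <- classify_foci(exact, rim)
  expect_identical(far$compartment, "nucleoplasm")

  outside <- place(0); outside$x_um <- 0; outside$y_um <- 0
  expect_error(classify_foci(outside, rim), "outside")
})

test_that("rim and nucleoplasm counts conserve the total", {
  for (seed in 1:3) {
    spec <- fast_spec(seed = 700 + seed, n_foci = 12, rim_fraction = 0.5)
    nuc <- simulate_nucleus(spec)
    seg <- segment_nuclei(nuc$channels$dna, spec$pixel_size_um)
    f <- detect_foci(nuc$channels$foci, seg,
                     min_area_px = psf_min_area_px(0.08 / spec$pixel_size_um))
    rim <- rim_geometry(seg$mask[[1]], spec$pixel_size_um, 0.4)
    cf <- classify_foci(f, rim)
    counts <- rim_counts(cf)
    expect_identical(counts$n_rim + counts$n_nucleoplasm, counts$n_total)
    expect_identical(counts$n_total, nrow(f))
  }
})

test_that("a lamina-channel ridge reference keeps rim foci at the rim", {
  spec <- fast_spec(seed = 9, n_foci = 10, rim_fraction = 1,
                    rim_band_width_um = 0.4)
  nuc <- simulate_nucleus(spec)
  seg <- segment_nuclei(nuc$channels$dna, spec$pixel_size_um)
  f <- detect_foci(nuc$channels$foci, seg,
                   min_area_px = psf_min_area_px(0.08 / spec$pixel_size_um))
  rim <- rim_geometry(seg$mask[[1]], spec$pixel_size_um, 0.4)
  boundary_ref <- classify_foci(f, rim)
  ridge_ref <- classify_foci(f, rim, rim_channel = nuc$channels$rim)
  expect_true(all(ridge_ref$compartment == "rim"))
  # ridge sits inside the band: references differ by less than its width
  expect_true(all(abs(ridge_ref$distance_to_rim_um -
                        boundary_ref$distance_to_rim_um) <= 0.4 + 0.05))
})

test_that("rim occupancy matches the analytic covered-arc fraction", {
  px <- 0.04
  r_px <- 60
  rim <- make_disk_rim(r_px, px)
  expect_identical(percent_positive_rim(matrix(0, nrow(rim$mask),
                                               ncol(rim$mask)), rim), 0)

  # single focus disk of radius rho centred on the boundary
  rho_px <- 5
  center <- (dim(rim$mask) + 1) / 2
  fm <- matrix(0, nrow(rim$mask), ncol(rim$mask))
  fx <- center[2] + r_px; fy <- center[1]
  fm[(row(fm) - fy)^2 + (col(fm) - fx)^2 <= rho_px^2] <- 1
  occ_um <- 0.25
  got <- percent_positive_rim(fm, rim, occ_um)
  t_px <- occ_um / px + rho_px
  expected <- 100 * 2 * asin(t_px / (2 * r_px)) / pi
  expect_lt(abs(got - expected), 2)

  # foci tiling the whole rim band: 100%
  expect_identical(percent_positive_rim(rim$rim_band, rim), 100)
})

test_that("rim occupancy is monotone in nested foci sets", {
  spec <- fast_spec(seed = 77, n_foci = 14, rim_fraction = 1)
  nuc <- simulate_nucleus(spec)
  px <- spec$pixel_size_um
  rim <- rim_geometry(nuc$mask, px, spec$rim_band_width_um)
  vals <- vapply(c(2, 6, 10, 14), function(k) {
    fm <- matrix(0, nrow(nuc$mask), ncol(nuc$mask))
    for (i in seq_len(k)) {
      r0 <- round(nuc$truth_foci$y_um[i] / px) + 1
      c0 <- round(nuc$truth_foci$x_um[i] / px) + 1
      fm[(row(fm) - r0)^2 + (col(fm) - c0)^2 <= 9] <- 1
    }
    percent_positive_rim(fm, rim)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("rim profiles are deterministic, cover the perimeter, and see gaps", {
  spec <- fast_spec(seed = 13, n_foci = 0, rim_gap_fraction = 0.25)
  nuc <- simulate_nucleus(spec)
  rim <- rim_geometry(nuc$mask, spec$pixel_size_um, spec$rim_band_width_um)

  uniform <- matrix(2, nrow(nuc$mask), ncol(nuc$mask))
  pu <- rim_profile(uniform, rim, window_um = 0.2)
  expect_true(all(abs(pu$intensity - 2) < 1e-6))
  expect_true(all(diff(pu$arc_um) > 0))
  # arc length covers the perimeter of the base shape
  expect_equal(max(pu$arc_um), nuc$truth_nucleus$perimeter_um,
               tolerance = 0.1)

  p1 <- rim_profile(nuc$channels$rim, rim, window_um = 0.2)
  p2 <- rim_profile(nuc$channels$rim, rim, window_um = 0.2)
  expect_identical(p1, p2)

  half <- (max(p1$intensity) + min(p1$intensity)) / 2
  gap_frac <- 100 * mean(p1$intensity < half)
  expect_lt(abs(gap_frac - 25), 5)

  expect_error(rim_profile(uniform, rim, window_um = 10), "minor axis")
})
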
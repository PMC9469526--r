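# Synthetic image generator: analytic ground truth, determinism,
# conservation and placement contracts.

test_that("unperturbed shapes match their analytic geometry", {
  # disk: axes equal, no wrinkles
  spec <- synthetic_spec(image_size_px = c(320, 320), pixel_size_um = 0.04,
                         ellipse_axes_um = c(5, 5), wrinkle_amplitude = 0,
                         n_foci = 0, seed = 11)
  sh <- generate_nucleus_shape(spec)
  expect_equal(sh$truth_nucleus$mask_area_um2, pi * 25, tolerance = 0.02)
  expect_equal(sh$truth_nucleus$area_um2, pi * 25, tolerance = 0.005)

  # 2:1 ellipse: fitted axis ratio
  spec2 <- synthetic_spec(image_size_px = c(320, 320),
                          ellipse_axes_um = c(5, 2.5), wrinkle_amplitude = 0,
                          n_foci = 0, seed = 11)
  sh2 <- generate_nucleus_shape(spec2)
  d <- shape_descriptors(sh2$mask, spec2$pixel_size_um)
  expect_equal(d$major_axis_um, 10, tolerance = 0.02)
  expect_equal(d$roundness, 0.5, tolerance = 0.02)
})

test_that("bleb truth rows sit outside the unperturbed ellipse", {
  spec <- synthetic_spec(bleb_count = 3, wrinkle_amplitude = 0, n_foci = 0,
                         seed = 4)
  sh <- generate_nucleus_shape(spec)
  expect_identical(nrow(sh$truth_blebs), 3L)
  a <- spec$ellipse_axes_um[1]; b <- spec$ellipse_axes_um[2]
  rel_x <- sh$truth_blebs$x_um - sh$center_um["x"]
  rel_y <- sh$truth_blebs$y_um - sh$center_um["y"]
  expect_true(all((rel_x / a)^2 + (rel_y / b)^2 > 1))
})

test_that("identical spec and seed give bit-identical output", {
  spec <- fast_spec(seed = 99, rim_gap_fraction = 0.2)
  a <- simulate_nucleus(spec)
  b <- simulate_nucleus(spec)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth_foci, b$truth_foci)
})

test_that("truth focus rows are conserved and respect placement rules", {
  for (seed in 1:3) {
    spec <- fast_spec(seed = seed, n_foci = 10, rim_fraction = 1)
    nuc <- simulate_nucleus(spec)
    expect_identical(nrow(nuc$truth_foci), 10L)
    # rim_fraction = 1: every focus inside the rim band
    expect_true(all(nuc$truth_foci$placed_rim))
    expect_true(all(nuc$truth_foci$dist_to_boundary_um <=
                      spec$rim_band_width_um + spec$pixel_size_um))
    # pairwise separation >= 3 sigma
    dmat <- as.matrix(dist(nuc$truth_foci[, c("x_um", "y_um")]))
    expect_true(all(dmat[upper.tri(dmat)] >= 3 * spec$focus_sigma_um - 1e-9))
  }
})

test_that("stored truth distances agree with brute-force boundary distance", {
  spec <- fast_spec(seed = 21, n_foci = 12, rim_fraction = 0.5,
                    wrinkle_amplitude = 0.1)
  nuc <- simulate_nucleus(spec)
  px <- spec$pixel_size_um
  boundary_px <- which(nuc$mask != 0 &
    as.matrix(EBImage::distmap(nuc$mask)) <= 1, arr.ind = TRUE)
  bf <- vapply(seq_len(nrow(nuc$truth_foci)), function(i) {
    min(sqrt((boundary_px[, 2] - 1 - nuc$truth_foci$x_um[i] / px)^2 +
             (boundary_px[, 1] - 1 - nuc$truth_foci$y_um[i] / px)^2)) * px
  }, numeric(1))
  expect_true(all(abs(bf - nuc$truth_foci$dist_to_boundary_um) <= px))
})

test_that("noise-free single-focus channel peaks at the truth centroid", {
  spec <- fast_spec(seed = 5, n_foci = 1, poisson_scale = 0,
                    read_noise_sd = 0, background = 0)
  nuc <- simulate_nucleus(spec)
  peak <- which(nuc$channels$foci == max(nuc$channels$foci), arr.ind = TRUE)
  px <- spec$pixel_size_um
  expect_lte(abs(peak[1, "col"] - 1 - nuc$truth_foci$x_um / px), 0.5 + 1e-9)
  expect_lte(abs(peak[1, "row"] - 1 - nuc$truth_foci$y_um / px), 0.5 + 1e-9)
})

test_that("n_foci = 0 leaves only background and noise in the foci channel", {
  spec <- fast_spec(seed = 2, n_foci = 0)
  nuc <- simulate_nucleus(spec)
  expect_identical(nrow(nuc$truth_foci), 0L)
  expect_lt(max(nuc$channels$foci), spec$background + 10 * sqrt(
    spec$background / spec$poisson_scale + spec$read_noise_sd^2))
})

test_that("invalid specs are rejected with diagnostics", {
  expect_error(synthetic_spec(wrinkle_amplitude = 0.6), "wrinkle_amplitude")
  expect_error(synthetic_spec(rim_fraction = 1.2), "rim_fraction")
  expect_error(synthetic_spec(ellipse_axes_um = c(3, 5)), "a >= b")
  # nucleus too small to host many well-separated foci
  spec <- synthetic_spec(image_size_px = c(128, 128), pixel_size_um = 0.04,
                         ellipse_axes_um = c(1.5, 1.2), n_foci = 200, seed = 1)
  expect_error(simulate_nucleus(spec), "minimum separation")
})

test_that("generate_population is keyed and reproducible per condition", {
  specs <- list(a = fast_spec(n_foci = 3), b = fast_spec(n_foci = 3))
  pop <- generate_population(5, specs, seed = 17)
  expect_identical(nrow(pop$nuclei), 10L)
  expect_identical(nrow(pop$truth_nuclei), 10L)
  expect_identical(nrow(pop$truth_foci), 30L)
  # condition b alone reproduces the same images as in the joint run
  pop_b <- generate_population(5, specs["b"], seed = 17)
  expect_identical(pop_b$nuclei$channels, pop$nuclei$channels[6:10])
  expect_error(generate_population(5, list(a = fast_spec(), a = fast_spec())),
               "uniquely named")
})

test_that("higher wrinkle amplitude lowers mean circularity and solidity", {
  mean_idx <- function(amp) {
    vals <- vapply(1:20, function(i) {
      spec <- synthetic_spec(seed = 300 + i, n_foci = 0,
                             wrinkle_amplitude = amp)
      d <- shape_descriptors(generate_nucleus_shape(spec)$mask,
                             spec$pixel_size_um)
      c(d$circularity, d$solidity)
    }, numeric(2))
    rowMeans(vals)
  }
  levels <- lapply(c(0.05, 0.12, 0.25), mean_idx)
  circ <- vapply(levels, `[`, numeric(1), 1)
  sol <- vapply(levels, `[`, numeric(1), 2)
  expect_true(all(diff(circ) < 0))
  expect_true(all(diff(sol) < 0))
})
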
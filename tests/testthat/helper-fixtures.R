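# Shared fixtures and independent oracles, all built in code.

# analytic binary masks -------------------------------------------------

disk_mask <- function(r_px, pad = 6L) {
  n <- 2L * (r_px + pad) + 1L
  c0 <- r_px + pad + 1L
  m <- matrix(0, n, n)
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r_px^2] <- 1
  m
}

ellipse_mask <- function(a_px, b_px, pad = 6L) {
  h <- 2L * (b_px + pad) + 1L
  w <- 2L * (a_px + pad) + 1L
  cy <- b_px + pad + 1L
  cx <- a_px + pad + 1L
  m <- matrix(0, h, w)
  m[((col(m) - cx) / a_px)^2 + ((row(m) - cy) / b_px)^2 <= 1] <- 1
  m
}

# small, fast generator spec for unit tests (not the study conditions)
fast_spec <- function(...) {
  args <- list(image_size_px = c(192L, 192L), ellipse_axes_um = c(3, 2.4),
               n_foci = 8L)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

# independent moment-preserving threshold oracle -----------------------
# Naive loop over all candidate thresholds; the two representative levels
# preserving the first two moments are obtained from the quadratic solved
# with polyroot(), and the threshold minimising the third-moment mismatch
# is returned on the same intensity scale as moments_threshold().
oracle_moments_threshold <- function(image, n_bins = 256L) {
  vals <- as.vector(image)
  lo <- min(vals); hi <- max(vals)
  g <- pmin(floor((vals - lo) / (hi - lo) * n_bins), n_bins - 1L)
  m1 <- mean(g); m2 <- mean(g^2); m3 <- mean(g^3)
  best_err <- Inf; best_t <- NA_integer_
  for (t in 0:(n_bins - 1L)) {
    q <- mean(g <= t)
    if (q <= 0 || q >= 1) next
    # q z0^2 - 2 m1 q z0 + m1^2 - m2 (1 - q) = 0
    roots <- Re(polyroot(c(m1^2 - m2 * (1 - q), -2 * m1 * q, q)))
    z0 <- min(roots)
    z1 <- (m1 - q * z0) / (1 - q)
    err <- abs(q * z0^3 + (1 - q) * z1^3 - m3)
    if (err < best_err) {
      best_err <- err
      best_t <- t
    }
  }
  lo + (best_t + 1) / n_bins * (hi - lo)
}

# random 8-bit test image with a lumpy histogram
random_histogram_image <- function(seed) {
  set.seed(seed)
  n_modes <- sample(2:4, 1)
  centers <- sample(20:235, n_modes)
  sds <- runif(n_modes, 5, 40)
  vals <- unlist(lapply(seq_len(n_modes), function(i) {
    rnorm(sample(100:400, 1), centers[i], sds[i])
  }))
  vals <- pmin(pmax(round(vals), 0), 255)
  n <- ceiling(sqrt(length(vals)))
  matrix(c(vals, rep(vals[1], n^2 - length(vals))), n, n)
}

# doublet fixture: two Gaussian spots whose binarisation merges ---------
doublet_image <- function(sep_px = 6, sigma_px = 2, size = 64L) {
  cx <- size / 2
  g <- function(x0, y0) {
    outer(seq_len(size), seq_len(size), function(r, c)
      exp(-((r - y0)^2 + (c - x0)^2) / (2 * sigma_px^2)))
  }
  g(cx - sep_px / 2, cx) + g(cx + sep_px / 2, cx)
}

# pooled two-sample t oracle (closed form) ------------------------------
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
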
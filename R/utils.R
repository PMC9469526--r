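# Internal geometry and validation helpers.
#
# Coordinate convention (used everywhere): images are numeric matrices
# indexed [row, col]; pixel-centre coordinates are 0-based with
# x = col - 1, y = row - 1; physical coordinates are x * pixel_size_um.

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g.", name, min))
  }
  if (!strict_min && (x < min || x > max)) {
    abort(sprintf("`%s` must be in [%g, %g].", name, min, max))
  }
  invisible(x)
}

check_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

check_mask <- function(x, name = "mask") {
  if (!is.matrix(x)) abort(sprintf("`%s` must be a matrix.", name))
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1, TRUE, FALSE))) {
    abort(sprintf("`%s` must be binary (0/1).", name))
  }
  invisible(x)
}

as_binary <- function(x) {
  m <- matrix(as.numeric(x != 0), nrow(x), ncol(x))
  m
}

# 0-based pixel-centre coordinates of mask pixels (x = col-1, y = row-1)
mask_coords <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Ordered 0-based boundary contour of a single connected mask.
# Returns a matrix with columns x, y.
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(as_binary(mask))
  if (length(oc) == 0L) abort("mask has no foreground pixels")
  # ocontour() is 0-based in matrix index order: dim1 = row, dim2 = col
  ct <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  cbind(x = ct[, 2], y = ct[, 1])
}

# Euclidean distance from each point (n x 2, columns x/y) to the nearest
# point of a reference set (m x 2). Plain vectorised computation; reference
# sets here are nucleus contours (a few thousand points at most).
nearest_point_distance <- function(points, reference) {
  if (nrow(reference) == 0L) abort("empty reference point set")
  apply(points, 1L, function(p) {
    sqrt(min((reference[, 1] - p[1])^2 + (reference[, 2] - p[2])^2))
  })
}

# Shoelace polygon area; vertices as (x, y) matrix, open or closed.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Distance (px) from every pixel to the nearest zero pixel of `mask`,
# evaluated at foreground pixels; background pixels get 0.
inside_distance <- function(mask) {
  as.matrix(EBImage::distmap(as_binary(mask)))
}

# Disc structuring element with odd size covering radius r (px).
disc_brush <- function(r_px) {
  size <- 2L * as.integer(ceiling(r_px)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

scale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x)
  (x - rng[1]) / diff(rng)
}
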
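# Masked Pearson colocalization. Plain sample Pearson over the masked
# pixel set, without automatic thresholding or Costes correction: the
# faithful counterpart of the Pearson coefficient reported by the common
# commercial colocalization modules.

new_coloc_result <- function(r, n, compartment, channels) {
  tibble(pearson_r = r, n_pixels = n, compartment = compartment,
         channel_1 = channels[1], channel_2 = channels[2])
}

#' Masked Pearson colocalization coefficient
#'
#' @param ch1,ch2 Numeric matrices of identical size.
#' @param mask Binary matrix selecting the pixels to correlate.
#' @param channels Length-2 character labels for the channel pair.
#' @param compartment Tag recorded in the result (default "whole").
#' @return One-row tibble: `pearson_r`, `n_pixels`, `compartment`,
#'   `channel_1`, `channel_2`.
#' @export
#' @examples
#' a <- matrix(runif(100), 10)
#' pearson_coloc(a, 2 * a + 5, matrix(1, 10, 10))
pearson_coloc <- function(ch1, ch2, mask,
                          channels = c("ch1", "ch2"),
                          compartment = "whole") {
  check_image(ch1); check_image(ch2); check_mask(mask)
  if (!all(dim(ch1) == dim(ch2)) || !all(dim(ch1) == dim(mask))) {
    abort("channels and mask must have identical dimensions.")
  }
  sel <- mask != 0
  n <- sum(sel)
  if (n < 2L) abort("mask must contain at least 2 pixels.")
  v1 <- ch1[sel]; v2 <- ch2[sel]
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("undefined correlation: a channel is constant within the mask.")
  }
  new_coloc_result(cor(v1, v2), n, compartment, channels)
}

#' Compartment-resolved colocalization (rim vs nucleoplasm)
#'
#' Runs [pearson_coloc()] separately over the rim band and over the rest of
#' the nucleus.
#'
#' @inheritParams pearson_coloc
#' @param rim A [rim_geometry()].
#' @param nucleus_mask Binary nucleus mask containing the rim band.
#' @return Two-row tibble (compartments `rim` and `nucleoplasm`).
#' @export
compartment_coloc <- function(ch1, ch2, rim, nucleus_mask,
                              channels = c("ch1", "ch2")) {
  check_mask(nucleus_mask)
  band <- rim$rim_band
  if (any(band > 0 & nucleus_mask == 0)) {
    abort("rim band must be contained in the nucleus mask.")
  }
  nucleoplasm <- matrix(as.numeric(nucleus_mask > 0 & band == 0),
                        nrow(band), ncol(band))
  dplyr::bind_rows(
    pearson_coloc(ch1, ch2, band, channels, compartment = "rim"),
    pearson_coloc(ch1, ch2, nucleoplasm, channels, compartment = "nucleoplasm")
  )
}

#' Fraction of foci colocalizing with a partner signal, per compartment
#'
#' A focus colocalizes when its centroid pixel, or any pixel within 1 px of
#' it, lies inside the binarized partner mask. Percentages are computed
#' separately over rim foci and nucleoplasm foci (each on the total of that
#' compartment); a compartment without foci is reported as `NA`.
#'
#' @param foci Classified foci tibble ([classify_foci()]).
#' @param partner_mask Binary image (moments-threshold binarization of the
#'   partner channel).
#' @param rim A [rim_geometry()] (supplies the pixel size).
#' @return Tibble: `compartment`, `n_foci`, `pct_colocalizing`.
#' @export
colocalizing_foci_fraction <- function(foci, partner_mask, rim) {
  check_mask(partner_mask)
  px <- rim$pixel_size_um
  hits <- function(df) {
    if (nrow(df) == 0L) return(NA_real_)
    ok <- vapply(seq_len(nrow(df)), function(i) {
      r0 <- round(df$y_um[i] / px) + 1L
      c0 <- round(df$x_um[i] / px) + 1L
      rr <- pmin(pmax(r0 + (-1:1), 1L), nrow(partner_mask))
      cc <- pmin(pmax(c0 + (-1:1), 1L), ncol(partner_mask))
      any(partner_mask[rr, cc] != 0)
    }, logical(1))
    100 * mean(ok)
  }
  tibble(
    compartment = c("rim", "nucleoplasm"),
    n_foci = c(sum(foci$compartment == "rim"),
               sum(foci$compartment == "nucleoplasm")),
    pct_colocalizing = c(
      hits(dplyr::filter(foci, .data$compartment == "rim")),
      hits(dplyr::filter(foci, .data$compartment == "nucleoplasm"))
    )
  )
}

#' Pearson correlation between two rim intensity profiles
#'
#' @param p1,p2 Profiles from [rim_profile()] sampled on the same
#'   arc-length grid (same nucleus).
#' @param channels Length-2 character labels.
#' @return One-row tibble with `compartment = "profile"`.
#' @export
profile_correlation <- function(p1, p2, channels = c("ch1", "ch2")) {
  if (nrow(p1) != nrow(p2)) {
    abort("profiles have different lengths; they must share the arc-length grid.")
  }
  if (max(abs(p1$arc_um - p2$arc_um)) > 1e-9) {
    abort("profiles are not sampled on the same arc-length grid.")
  }
  if (sd(p1$intensity) == 0 || sd(p2$intensity) == 0) {
    abort("undefined correlation: constant profile.")
  }
  new_coloc_result(cor(p1$intensity, p2$intensity), nrow(p1),
                   "profile", channels)
}
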
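#' Phantom region descriptors
#'
#' Regions carry a shape, a target Hurst exponent and a texture amplitude.
#' Supported shapes: the whole frame, axis-aligned rectangles, discs, and
#' horizontal bands (fractions of the frame height).
#'
#' @param hurst target Hurst exponent in (0, 1).
#' @param amplitude texture standard deviation in intensity units (> 0).
#' @param shape one of `"full"`, `"rect"`, `"disc"`, `"disc_complement"`
#'   (everything outside a disc), `"band"`.
#' @param ... shape parameters: `y0`, `y1`, `x0`, `x1` (rect, pixels);
#'   `cy`, `cx`, `radius` (disc and its complement); `from`, `to` (band,
#'   fractions of height).
#' @return List of class `phantom_region`.
#' @export
phantom_region <- function(hurst, amplitude = 1, shape = "full", ...) {
  if (hurst <= 0 || hurst >= 1) stop_bad_arg("region hurst must be in (0, 1)")
  if (amplitude <= 0) stop_bad_arg("region amplitude must be positive")
  structure(list(hurst = hurst, amplitude = amplitude, shape = shape,
                 params = list(...)), class = "phantom_region")
}

region_mask <- function(region, side) {
  p <- region$params
  switch(region$shape,
    full = matrix(TRUE, side, side),
    rect = {
      m <- matrix(FALSE, side, side)
      m[max(1, p$y0):min(side, p$y1), max(1, p$x0):min(side, p$x1)] <- TRUE
      m
    },
    disc = {
      yy <- matrix(seq_len(side), side, side)
      xx <- t(yy)
      (yy - p$cy)^2 + (xx - p$cx)^2 <= p$radius^2
    },
    disc_complement = {
      yy <- matrix(seq_len(side), side, side)
      xx <- t(yy)
      (yy - p$cy)^2 + (xx - p$cx)^2 > p$radius^2
    },
    band = {
      m <- matrix(FALSE, side, side)
      y0 <- max(1L, floor(p$from * side) + 1L); y1 <- max(y0, floor(p$to * side))
      m[y0:y1, ] <- TRUE
      m
    },
    stop_bad_arg("unknown region shape '%s'", region$shape))
}

#' Phantom mammogram specification
#'
#' @param image_side side of the square phantom in pixels.
#' @param mask_shape `"full_frame"` or `"half_ellipse_mlo"` (a breast-like
#'   half ellipse against the left image edge, as in an MLO view).
#' @param regions list of [phantom_region]s.  Overlapping regions must share
#'   the same target Hurst exponent.
#' @param background_level additive intensity offset.
#' @param bit_depth 8 or 12.
#' @param taper_px width of the raised-cosine blend at region borders
#'   (discontinuities are h = -1 singularities that would otherwise
#'   dominate the wavelet transform).
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 520L,
                         mask_shape = c("full_frame", "half_ellipse_mlo"),
                         regions = list(phantom_region(0.65)),
                         background_level = 0, bit_depth = 8L,
                         taper_px = 16L) {
  mask_shape <- match.arg(mask_shape)
  if (!length(regions)) stop_bad_arg("at least one region is required")
  for (r in regions)
    if (!inherits(r, "phantom_region")) stop_bad_arg("regions must be phantom_region objects")
  if (!bit_depth %in% c(8L, 12L)) stop_bad_arg("bit_depth must be 8 or 12")
  structure(list(image_side = as.integer(image_side), mask_shape = mask_shape,
                 regions = regions, background_level = background_level,
                 bit_depth = as.integer(bit_depth), taper_px = as.integer(taper_px)),
            class = "phantom_spec")
}

breast_mask <- function(side, shape) {
  if (shape == "full_frame") return(matrix(TRUE, side, side))
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  ## half ellipse against the left edge, slightly tilted extent as in MLO views
  (xx / (0.92 * side))^2 + ((yy - side / 2) / (0.48 * side))^2 <= 1
}

## raised-cosine ramp of the region mask over `taper` pixels (inside the region)
taper_weight <- function(mask, taper) {
  if (taper <= 0L || all(mask) ) return(mask * 1)
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  w <- pmin(as.matrix(d) / taper, 1)
  (1 - cos(pi * w)) / 2
}

#' Generate a phantom mammogram with known tissue classes
#'
#' Each region is filled with a unit-variance fractional Brownian texture of
#' its target Hurst exponent, scaled by its amplitude and blended with a
#' raised-cosine taper at the region border; the background level is added
#' and the result is quantized to the requested bit depth.  The ground-truth
#' class map labels every window-center position of the sliding-window grid
#' by the class of the region containing it.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed (per-region textures are derived from it).
#' @param geom [window_geometry] used for the ground-truth grid.
#' @return List: `image` ([gray_image]), `mask` (logical breast mask),
#'   `truth` (character matrix over the window grid: expected class at each
#'   window center, `NA` outside all regions or outside the mask).
#' @export
generate_phantom_mammogram <- function(spec, seed, geom = window_geometry()) {
  side <- spec$image_side
  masks <- lapply(spec$regions, region_mask, side = side)
  ## overlapping regions with different H are ill-defined
  nr <- length(masks)
  if (nr > 1L) for (i in 1:(nr - 1L)) for (j in (i + 1L):nr) {
    if (any(masks[[i]] & masks[[j]]) &&
        spec$regions[[i]]$hurst != spec$regions[[j]]$hurst)
      stop_bad_arg("regions %d and %d overlap with different target H", i, j)
  }
  f <- matrix(spec$background_level, side, side)
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    tex <- generate_fbm_surface(side, r$hurst, derive_seed(seed, i))$values
    tex <- tex / stats::sd(tex)
    f <- f + taper_weight(masks[[i]], spec$taper_px) * r$amplitude * tex
  }
  top <- 2^spec$bit_depth - 1
  rng <- range(f)
  vals <- round((f - rng[1]) / (rng[2] - rng[1]) * top)
  img <- gray_image(vals, bit_depth = spec$bit_depth)
  bm <- breast_mask(side, spec$mask_shape)

  ## ground truth on the window grid
  tiles <- suppressWarnings(tile_image(img, NULL, geom))
  gd <- attr(tiles, "grid_dim") %||% c(0L, 0L)
  truth <- matrix(NA_character_, gd[1], gd[2])
  half <- geom$window_side %/% 2L
  for (k in seq_len(nrow(tiles))) {
    cy <- tiles$y0[k] + half; cx <- tiles$x0[k] + half
    if (!bm[cy, cx]) next
    for (i in seq_along(masks)) {
      if (masks[[i]][cy, cx]) {
        truth[tiles$row[k], tiles$col[k]] <-
          as.character(classify_hurst(spec$regions[[i]]$hurst))
        break
      }
    }
  }
  list(image = img, mask = bm, truth = truth)
}
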
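#' Sliding-window geometry of the mammogram protocol
#'
#' Windows of `window_side` pixels are slid in steps of `stride`; the
#' wavelet transform is computed over the full window but only the centred
#' `core_side` portion contributes maxima statistics, so every analyzed
#' core sees real surrounding context.  Defaults follow the published
#' protocol: 360-px windows, 256-px cores, 32-px increments.
#'
#' @param window_side,core_side,stride geometry in pixels.
#' @param min_mask_coverage minimum fraction of core pixels inside the
#'   breast mask for a window to be analyzed.
#' @return List of class `window_geometry`.
#' @export
window_geometry <- function(window_side = 360L, core_side = 256L, stride = 32L,
                            min_mask_coverage = 0.5) {
  if (core_side > window_side) stop_bad_arg("core_side cannot exceed window_side")
  if ((window_side - core_side) %% 2L != 0L)
    stop_bad_arg("window_side - core_side must be even (centred core)")
  structure(list(window_side = as.integer(window_side),
                 core_side = as.integer(core_side),
                 stride = as.integer(stride),
                 min_mask_coverage = min_mask_coverage),
            class = "window_geometry")
}

#' Tile an image into overlapping analysis windows
#'
#' Enumerates, in raster order (top-left to bottom-right), every grid
#' position where the full window fits inside the image and the breast-mask
#' coverage of the central core reaches `min_mask_coverage`.  The grid has
#' `floor((image - window)/stride) + 1` positions per axis.
#'
#' @param image a [gray_image] or matrix.
#' @param mask logical matrix of the breast region (same size as the image),
#'   or `NULL` for full coverage.
#' @param geom a [window_geometry].
#' @return `data.frame` with 1-based `row`, `col` grid indices and `y0`,
#'   `x0` window origins (top-left pixel, 1-based).  Empty (with a warning)
#'   when the image is smaller than one window.
#' @export
tile_image <- function(image, mask = NULL, geom = window_geometry()) {
  img <- as_gray_image(image)
  n1 <- nrow(img$values); n2 <- ncol(img$values)
  w <- geom$window_side; s <- geom$stride
  if (n1 < w || n2 < w) {
    warning("image smaller than one analysis window; nothing to tile")
    return(data.frame(row = integer(), col = integer(),
                      y0 = integer(), x0 = integer()))
  }
  nr <- (n1 - w) %/% s + 1L
  nc <- (n2 - w) %/% s + 1L
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, c("row", "col")]
  grid$y0 <- (grid$row - 1L) * s + 1L
  grid$x0 <- (grid$col - 1L) * s + 1L
  if (!is.null(mask)) {
    m <- (w - geom$core_side) %/% 2L
    cs <- geom$core_side
    S <- matrix(0, n1 + 1L, n2 + 1L)     # S[i+1, j+1] = sum(mask[1:i, 1:j])
    S[-1, -1] <- t(apply(apply(mask * 1, 2, cumsum), 1, cumsum))
    boxsum <- function(y0, x0, side) {
      y1 <- y0 + side - 1L; x1 <- x0 + side - 1L
      S[cbind(y1 + 1L, x1 + 1L)] - S[cbind(y0, x1 + 1L)] -
        S[cbind(y1 + 1L, x0)] + S[cbind(y0, x0)]
    }
    cov <- boxsum(grid$y0 + m, grid$x0 + m, cs) / (cs * cs)
    grid <- grid[cov >= geom$min_mask_coverage, , drop = FALSE]
  }
  rownames(grid) <- NULL
  attr(grid, "grid_dim") <- c(nr, nc)
  grid
}

#' Classify a Hurst exponent into a tissue class
#'
#' Anti-correlated fluctuations (`H <= 0.45`) are fatty tissue (blue in the
#' conventional rendering); long-range correlated fluctuations
#' (`H >= 0.55`) are dense tissue (red); uncorrelated fluctuations in
#' between (`0.45 < H < 0.55`) are disrupted tissue (yellow).  Both
#' boundaries are closed for the outer classes.
#'
#' @param H numeric vector of Hurst exponents (finite).
#' @return factor with levels `fatty`, `disrupted`, `dense`.
#' @examples
#' classify_hurst(c(0.45, 0.5, 0.55))
#' @export
classify_hurst <- function(H) {
  if (any(!is.finite(H))) stop_bad_arg("H must be finite")
  cls <- ifelse(H <= 0.45, "fatty", ifelse(H >= 0.55, "dense", "disrupted"))
  factor(cls, levels = c("fatty", "disrupted", "dense"))
}

#' Analyze one sliding window
#'
#' Runs the WTMM engine on a window (transform over the full window,
#' statistics over the centred core) and classifies the resulting Hurst
#' exponent.  Rejection is a value, not an error: rejected windows carry a
#' reason (`no-scaling`, `multifractal`, `too-few-lines`) and a null H,
#' matching the gray windows of the published maps.
#'
#' @param window numeric matrix of size `window_side` x `window_side`.
#' @param config a [wtmm_config].
#' @param core_side analysis core (default 256).
#' @return List with `H`, `class` (`"rejected"` or a tissue class),
#'   `reason`, and the underlying `hurst_estimate`.
#' @export
analyze_window <- function(window, config = wtmm_config(), core_side = 256L) {
  est <- estimate_hurst(window, config, core_side = core_side)
  if (est$status != "ok")
    return(list(H = NA_real_, class = "rejected", reason = est$reason,
                estimate = est))
  list(H = est$H, class = as.character(classify_hurst(est$H)), reason = NA_character_,
       estimate = est)
}

#' Sliding-window analysis of a whole mammogram
#'
#' Applies [analyze_window] to every tile of [tile_image] and assembles a
#' tissue-class map aligned with the window grid.  Deterministic given the
#' configuration.
#'
#' @param image a [gray_image] or matrix.
#' @param mask optional logical breast mask.
#' @param config a [wtmm_config].
#' @param geom a [window_geometry].
#' @param progress print a dot per window.
#' @return List of class `mammogram_analysis`: `class_map` (character matrix
#'   over the window grid: tissue classes, `"rejected"`, or `NA` for
#'   windows outside the mask), `windows` (per-window data.frame with
#'   0-based origins), `geometry`, `config`.
#' @export
analyze_mammogram <- function(image, mask = NULL, config = wtmm_config(),
                              geom = window_geometry(), progress = FALSE) {
  img <- as_gray_image(image)
  tiles <- tile_image(img, mask, geom)
  gd <- attr(tiles, "grid_dim")
  cmap <- matrix(NA_character_, gd[1], gd[2])
  res <- vector("list", nrow(tiles))
  w <- geom$window_side
  for (k in seq_len(nrow(tiles))) {
    y0 <- tiles$y0[k]; x0 <- tiles$x0[k]
    win <- img$values[y0:(y0 + w - 1L), x0:(x0 + w - 1L)]
    r <- analyze_window(win, config, geom$core_side)
    cmap[tiles$row[k], tiles$col[k]] <- r$class
    res[[k]] <- data.frame(row = tiles$row[k], col = tiles$col[k],
                           origin_y = y0 - 1L, origin_x = x0 - 1L,
                           H = r$H, class = r$class, reason = r$reason)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  windows <- if (length(res)) do.call(rbind, res) else
    data.frame(row = integer(), col = integer(), origin_y = integer(),
               origin_x = integer(), H = numeric(), class = character(),
               reason = character())
  structure(list(class_map = cmap, windows = windows, geometry = geom,
                 config = config), class = "mammogram_analysis")
}

#' Render a tissue-class map as an RGB array
#'
#' Blue = fatty, yellow = disrupted, red = dense, gray = rejected,
#' white = outside the breast mask; one pixel per window.
#'
#' @param class_map character matrix from [analyze_mammogram] (or a
#'   `mammogram_analysis`).
#' @return numeric array (rows x cols x 3) in `[0, 1]`, suitable for
#'   [png::writePNG].
#' @export
render_class_map <- function(class_map) {
  if (inherits(class_map, "mammogram_analysis")) class_map <- class_map$class_map
  pal <- list(fatty = c(0.13, 0.37, 0.66), disrupted = c(0.95, 0.87, 0.22),
              dense = c(0.78, 0.15, 0.15), rejected = c(0.55, 0.55, 0.55))
  out <- array(1, c(nrow(class_map), ncol(class_map), 3))
  for (cl in names(pal))
    for (ch in 1:3)
      out[, , ch][class_map == cl] <- pal[[cl]][ch]
  out
}
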
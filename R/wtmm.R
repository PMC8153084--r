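#' Log-spaced family of analyzing scales
#'
#' Scales are the standard deviation (in pixels) of the smoothing Gaussian
#' \eqn{\theta(r) = e^{-r^2/2}} after dilation.  The default family spans
#' 3 to 12 px in 10 logarithmic steps: above roughly 1/20 of the patch side
#' the finite analysis window truncates the low-frequency content that
#' drives the gradient modulus, and the power-law regime degrades.
#'
#' @param a_min,a_max smallest / largest scale in pixels.
#' @param n_scales number of scales (>= 10 for scaling-range selection).
#' @return Numeric vector of class `scale_family`, strictly increasing.
#' @export
scale_family <- function(a_min = 3, a_max = 12, n_scales = 10L) {
  if (a_min <= 0 || a_max <= a_min) stop_bad_arg("need 0 < a_min < a_max")
  if (!is_count(n_scales) || n_scales < 2) stop_bad_arg("n_scales must be >= 2")
  structure(2^seq(log2(a_min), log2(a_max), length.out = n_scales),
            class = "scale_family")
}

#' WTMM engine configuration
#'
#' Collects every tunable of the Hurst-estimation engine with the defaults
#' used throughout the package.  All entries are plain values so the object
#' serializes cleanly into run manifests.
#'
#' @param scales a [scale_family].
#' @param q_grid statistical moment orders for the partition functions.
#' @param min_chain_length chains with fewer pixels are discarded.
#' @param maxima_window_frac along-chain maxima are selected within a
#'   Chebyshev window of radius `maxima_window_frac * a` pixels, keeping the
#'   maxima spacing proportional to the analyzing scale.
#' @param link_radius_min minimum scale-to-scale linking radius in pixels.
#' @param min_span_octaves,min_r2,rmse_tol scaling-range acceptance: widest
#'   window spanning at least `min_span_octaves` where every gating moment is
#'   linear (R-squared >= `min_r2`, or residual RMSE <= `rmse_tol` log2 units
#'   for nearly flat moments).
#' @param range_q_set moments that gate the scaling range.
#' @param curvature_tol monofractality screen: reject when the quadratic
#'   coefficient of the tau(q) fit exceeds this in absolute value.
#' @param detrend_degree degree of the polynomial surface removed from each
#'   patch before the transform (the gradient wavelet has a single vanishing
#'   moment, so trends are not blind to it).
#' @param finite_size_correction apply the Monte-Carlo attenuation correction
#'   for the finite analysis window (see [attenuation_table]).
#' @param n_correction_iter fixed-point iterations of the correction.
#' @param attenuation_K reference surfaces per grid point of the table.
#' @return A list of class `wtmm_config`.
#' @export
wtmm_config <- function(scales = scale_family(),
                        q_grid = seq(-2, 3, by = 0.25),
                        min_chain_length = 4L,
                        maxima_window_frac = 1 / 3,
                        link_radius_min = 2,
                        min_span_octaves = 1.5,
                        min_r2 = 0.95,
                        rmse_tol = 0.12,
                        range_q_set = c(-1, 0, 1, 2),
                        curvature_tol = 0.05,
                        detrend_degree = 2L,
                        finite_size_correction = TRUE,
                        n_correction_iter = 3L,
                        attenuation_K = 8L) {
  structure(list(scales = as.numeric(scales), q_grid = q_grid,
                 min_chain_length = as.integer(min_chain_length),
                 maxima_window_frac = maxima_window_frac,
                 link_radius_min = link_radius_min,
                 min_span_octaves = min_span_octaves, min_r2 = min_r2,
                 rmse_tol = rmse_tol, range_q_set = range_q_set,
                 curvature_tol = curvature_tol,
                 detrend_degree = as.integer(detrend_degree),
                 finite_size_correction = finite_size_correction,
                 n_correction_iter = as.integer(n_correction_iter),
                 attenuation_K = as.integer(attenuation_K)),
            class = "wtmm_config")
}

## ---------------------------------------------------------------------------
## gradient wavelet transform

#' Gradient-of-Gaussian wavelet transform of an image
#'
#' Computes, for every scale \eqn{a}, the Gaussian-smoothed image
#' \eqn{T_\theta[f](b,a) = a^{-2}\int f(r)\,\theta(a^{-1}(r-b))\,d^2r} and the
#' two-component gradient wavelet transform
#' \eqn{T_\psi[f](b,a) = \nabla T_\theta[f](b,a)}, realized by FFT
#' multiplication (the Gaussian and the spectral derivative are applied
#' analytically in Fourier space).  The modulus field is
#' \eqn{M_\psi = a\,|\nabla T_\theta|}; the factor \eqn{a} makes the modulus
#' of an isolated singularity of Holder exponent \eqn{h} scale as \eqn{a^h}.
#' The image is mirror-padded to twice its side before the FFT, which
#' periodizes it continuously and suppresses wrap-around.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param scales a [scale_family] (or numeric vector of scales in pixels).
#' @param keep_smooth keep the smoothed images (memory heavy for many scales).
#' @return Object of class `gradient_wt_field`: per scale, `modulus` and
#'   `argument` (gradient direction, radians in (-pi, pi]) matrices aligned
#'   with the input image, plus the scale vector and padded size `np`.
#' @export
gradient_wavelet_transform <- function(image, scales = scale_family(),
                                       keep_smooth = FALSE) {
  img <- as_gray_image(image)
  f <- img$values
  scales <- as.numeric(scales)
  n1 <- nrow(f); n2 <- ncol(f)
  if (max(scales) >= min(n1, n2))
    stop_bad_arg("largest scale (%.1f px) must be smaller than the image side", max(scales))
  p1 <- (2L * n1 - n1) %/% 2L   # pad to twice the side: full reflection
  p2 <- (2L * n2 - n2) %/% 2L
  fp <- f[refl_idx(n1, p1), refl_idx(n2, p2)]
  np1 <- nrow(fp); np2 <- ncol(fp)
  kx <- matrix(fft_freq(np2), np1, np2, byrow = TRUE)
  ky <- matrix(fft_freq(np1), np1, np2)
  Fhat <- stats::fft(fp)
  ry <- (p1 + 1L):(p1 + n1); rx <- (p2 + 1L):(p2 + n2)
  out <- vector("list", length(scales))
  for (s in seq_along(scales)) {
    a <- scales[s]
    G <- exp(-(a * a) * (kx * kx + ky * ky) / 2)
    sm <- NULL
    if (keep_smooth)
      sm <- Re(stats::fft(Fhat * G, inverse = TRUE))[ry, rx] / (np1 * np2)
    Tx <- Re(stats::fft(Fhat * G * (1i * kx), inverse = TRUE))[ry, rx] / (np1 * np2)
    Ty <- Re(stats::fft(Fhat * G * (1i * ky), inverse = TRUE))[ry, rx] / (np1 * np2)
    out[[s]] <- list(scale = a,
                     modulus = a * sqrt(Tx * Tx + Ty * Ty),
                     argument = atan2(Ty, Tx),
                     smooth = sm)
  }
  structure(list(scales = scales, fields = out, np = c(np1, np2),
                 dim = c(n1, n2)), class = "gradient_wt_field")
}

## restrict every per-scale field to a centred core (used by the sliding
## window protocol: transform the full window, analyze only the core)
crop_wt_field <- function(field, core_side) {
  d <- field$dim
  m1 <- (d[1] - core_side) %/% 2L; m2 <- (d[2] - core_side) %/% 2L
  ry <- (m1 + 1L):(m1 + core_side); rx <- (m2 + 1L):(m2 + core_side)
  field$fields <- lapply(field$fields, function(fl) {
    fl$modulus <- fl$modulus[ry, rx]
    fl$argument <- fl$argument[ry, rx]
    if (!is.null(fl$smooth)) fl$smooth <- fl$smooth[ry, rx]
    fl
  })
  field$dim <- c(core_side, core_side)
  field
}

## ---------------------------------------------------------------------------
## modulus-maxima chains

## non-maximum suppression along the gradient direction; returns logical mask
wtmm_mask <- function(modulus, argument) {
  n1 <- nrow(modulus); n2 <- ncol(modulus)
  ii <- 2:(n1 - 1L); jj <- 2:(n2 - 1L)
  I <- matrix(rep(ii, length(jj)), length(ii))
  J <- matrix(rep(jj, each = length(ii)), length(ii))
  dx <- cos(argument)[ii, jj]
  dy <- sin(argument)[ii, jj]
  Mc <- modulus[ii, jj]
  p_fwd <- bilinear_at(modulus, I + dy, J + dx)
  p_bwd <- bilinear_at(modulus, I - dy, J - dx)
  keep <- Mc >= p_fwd & Mc > p_bwd & Mc > 0
  keep[is.na(keep)] <- FALSE
  km <- matrix(FALSE, n1, n2)
  km[ii, jj] <- keep
  km
}

#' Extract WTMM chains at one scale
#'
#' The wavelet transform modulus maxima are the pixels whose modulus exceeds
#' the modulus interpolated one pixel away on either side along the local
#' gradient direction (non-maximum suppression with bilinear sub-pixel
#' interpolation; non-strict in the forward direction so that flat ties keep
#' exactly one pixel).  Surviving pixels are grouped into 8-connected chains
#' (single-pixel gaps are bridged) and chains shorter than
#' `min_chain_length` are dropped.
#'
#' @param field a `gradient_wt_field`.
#' @param scale one of the scales in `field` (or its index via `scale_index`).
#' @param scale_index alternative to `scale`.
#' @param min_chain_length minimum chain size in pixels.
#' @return A `data.table` with columns `chain`, `y`, `x`, `modulus`; the
#'   scale is carried in attribute `"scale"`.  Zero rows when the field has
#'   no maxima (e.g. a constant image).
#' @export
extract_wtmm_chains <- function(field, scale = NULL, scale_index = NULL,
                                min_chain_length = 4L) {
  if (is.null(scale_index)) {
    scale_index <- which(abs(field$scales - scale) < 1e-9)
    if (length(scale_index) != 1L) stop_bad_arg("scale %s not present in field", scale)
  }
  fl <- field$fields[[scale_index]]
  km <- wtmm_mask(fl$modulus, fl$argument)
  empty <- data.table::data.table(chain = integer(), y = integer(), x = integer(),
                                  modulus = numeric())
  data.table::setattr(empty, "scale", fl$scale)
  if (!any(km)) return(empty)
  ## bridge 1-px gaps so that curvature-induced breaks do not fragment chains
  kd <- EBImage::dilate(EBImage::Image(km * 1), EBImage::makeBrush(3, "box")) > 0.5
  lab <- EBImage::bwlabel(kd)
  idx <- which(km)
  labv <- as.integer(lab)[idx]
  sz <- tabulate(labv)
  keep <- sz[labv] >= min_chain_length
  idx <- idx[keep]; labv <- labv[keep]
  if (!length(idx)) return(empty)
  n1 <- nrow(km)
  res <- data.table::data.table(
    chain = match(labv, sort(unique(labv))),
    y = ((idx - 1L) %% n1) + 1L,
    x = ((idx - 1L) %/% n1) + 1L,
    modulus = fl$modulus[idx])
  data.table::setattr(res, "scale", fl$scale)
  res[]
}

## along-chain local maxima with a scale-proportional window
chain_maxima <- function(chains, a, dim, window_frac = 1 / 3) {
  if (!nrow(chains)) return(chains[0])
  n1 <- dim[1]; n2 <- dim[2]
  idx <- (chains$x - 1L) * n1 + chains$y
  on_chain <- logical(n1 * n2); on_chain[idx] <- TRUE
  modv <- numeric(n1 * n2); modv[idx] <- chains$modulus
  ra <- max(1L, as.integer(round(a * window_frac)))
  best <- rep(TRUE, nrow(chains))
  Mv <- chains$modulus
  for (oy in -ra:ra) for (ox in -ra:ra) {
    if (oy == 0L && ox == 0L) next
    y2 <- chains$y + oy; x2 <- chains$x + ox
    valid <- y2 >= 1L & y2 <= n1 & x2 >= 1L & x2 <= n2
    id2 <- (x2 - 1L) * n1 + y2; id2[!valid] <- 1L
    nb <- valid & on_chain[id2]
    ## lose to a strictly larger neighbour, or an equal one earlier in raster order
    lose <- nb & (modv[id2] > Mv | (modv[id2] == Mv & id2 < idx))
    best[lose] <- FALSE
  }
  chains[best]
}

#' Build the space-scale skeleton from per-scale chains
#'
#' On every chain the local maxima of the modulus are located (within a
#' window proportional to the scale), and maxima at successive scales are
#' linked by greedy nearest-neighbour matching within `linking_radius`
#' (default `max(link_radius_min, a_{i+1} - a_i)`).  Points that receive no
#' link start new lines; every line extends from the smallest scale at which
#' it was detected up to the scale where it loses track.
#'
#' @param chains_by_scale list of chain tables from [extract_wtmm_chains],
#'   one per scale, ordered by increasing scale.
#' @param scales the corresponding scales.
#' @param linking_radius optional fixed radius in pixels.
#' @param link_radius_min floor for the default radius.
#' @param maxima_window_frac see [wtmm_config].
#' @param dim image dimensions (rows, cols).
#' @return `data.table` of class `wtmm_skeleton` with columns `line`,
#'   `scale_index`, `scale`, `y`, `x`, `modulus`, or `NULL` when no maxima
#'   exist at the smallest scale.
#' @export
build_skeleton <- function(chains_by_scale, scales, linking_radius = NULL,
                           link_radius_min = 2, maxima_window_frac = 1 / 3,
                           dim = NULL) {
  ns <- length(scales)
  if (is.null(dim)) {
    mx <- do.call(rbind, chains_by_scale)
    dim <- c(max(mx$y) + 1L, max(mx$x) + 1L)
  }
  pts <- lapply(seq_len(ns), function(s)
    chain_maxima(chains_by_scale[[s]], scales[s], dim, maxima_window_frac))
  out <- vector("list", ns)
  prev <- pts[[1]]
  if (is.null(prev) || !nrow(prev)) return(NULL)
  prev <- data.table::copy(prev)
  prev[, line := .I]
  nextline <- nrow(prev) + 1L
  out[[1]] <- data.table::data.table(line = prev$line, scale_index = 1L,
                                     scale = scales[1], y = prev$y, x = prev$x,
                                     modulus = prev$modulus)
  for (s in 2:ns) {
    cur <- pts[[s]]
    if (is.null(cur) || !nrow(cur)) { prev <- NULL; next }
    cur <- data.table::copy(cur)
    r <- linking_radius %||% max(link_radius_min, scales[s] - scales[s - 1])
    cur[, line := NA_integer_]
    if (!is.null(prev) && nrow(prev)) {
      D <- outer(cur$y, prev$y, "-")^2 + outer(cur$x, prev$x, "-")^2
      D[D > r * r] <- NA
      ord <- order(D, na.last = NA)
      if (length(ord)) {
        usedc <- logical(nrow(cur)); usedp <- logical(nrow(prev))
        ci <- ((ord - 1L) %% nrow(cur)) + 1L
        pj <- ((ord - 1L) %/% nrow(cur)) + 1L
        for (k in seq_along(ord)) {
          if (usedc[ci[k]] || usedp[pj[k]]) next
          cur$line[ci[k]] <- prev$line[pj[k]]
          usedc[ci[k]] <- TRUE; usedp[pj[k]] <- TRUE
        }
      }
    }
    nn <- sum(is.na(cur$line))
    if (nn) {
      cur$line[is.na(cur$line)] <- nextline:(nextline + nn - 1L)
      nextline <- nextline + nn
    }
    out[[s]] <- data.table::data.table(line = cur$line, scale_index = s,
                                       scale = scales[s], y = cur$y, x = cur$x,
                                       modulus = cur$modulus)
    prev <- cur
  }
  skel <- data.table::rbindlist(out)
  data.table::setattr(skel, "scales", scales)
  data.table::setattr(skel, "class", c("wtmm_skeleton", class(skel)))
  skel[]
}

## ---------------------------------------------------------------------------
## partition functions and scaling fits

#' Partition functions over the WT skeleton
#'
#' \deqn{Z(q,a) = \sum_{l \in L(a)} \Big(\sup_{(x,a') \in l,\, a' \le a}
#' M_\psi[f](b,a')\Big)^q}
#' where \eqn{L(a)} is the set of maxima lines existing at scale \eqn{a}.
#' \eqn{Z(0,a)} is exactly the number of lines in \eqn{L(a)}.  Alongside
#' \eqn{Z}, the weighted diagnostic means \eqn{h(q,a)} (mean log2 supremum
#' under the \eqn{q}-weights) and \eqn{D(q,a)} (weight entropy) are returned.
#'
#' @param skeleton a `wtmm_skeleton`.
#' @param q_grid moment orders.
#' @param scales scale vector (defaults to the skeleton's).
#' @return Object of class `partition_functions`: `Z` (|q| x |a| matrix),
#'   `n_lines`, `h_qa`, `D_qa`, `q_grid`, `scales`.  Scales with empty
#'   \eqn{L(a)} hold `NA` and raise a warning.
#' @export
compute_partition_functions <- function(skeleton, q_grid = seq(-2, 3, by = 0.25),
                                        scales = attr(skeleton, "scales")) {
  sk <- data.table::as.data.table(skeleton)
  data.table::setkey(sk, line, scale_index)
  sk[, sup_mod := cummax(modulus), by = line]
  ns <- length(scales)
  Z <- h_qa <- D_qa <- matrix(NA_real_, length(q_grid), ns)
  n_lines <- integer(ns)
  for (s in seq_len(ns)) {
    v <- sk[scale_index == s, sup_mod]
    n_lines[s] <- length(v)
    if (!length(v)) next
    lv <- log2(v)
    for (iq in seq_along(q_grid)) {
      q <- q_grid[iq]
      vq <- v^q
      Z[iq, s] <- sum(vq)
      w <- vq / sum(vq)
      h_qa[iq, s] <- sum(w * lv)
      D_qa[iq, s] <- sum(w * log2(w))
    }
  }
  if (any(n_lines == 0L))
    warning("empty skeleton at ", sum(n_lines == 0L), " scale(s); dropped from fits")
  structure(list(Z = Z, n_lines = n_lines, h_qa = h_qa, D_qa = D_qa,
                 q_grid = q_grid, scales = as.numeric(scales)),
            class = "partition_functions")
}

#' Select the scaling range of the partition functions
#'
#' Returns the widest contiguous scale window, spanning at least
#' `min_span_octaves`, on which `log2 Z(q,a)` is simultaneously linear in
#' `log2 a` for every gating moment in `q_set`.  Linearity is accepted when
#' the regression R-squared reaches `min_r2` or, for nearly flat moments
#' where R-squared is uninformative, when the residual RMSE stays below
#' `rmse_tol` log2 units.  When no window qualifies the patch is rejected
#' with reason `"no-scaling"` (a value, not an error).
#'
#' @param pfs a `partition_functions` object.
#' @param min_span_octaves,min_r2,rmse_tol,q_set see [wtmm_config].
#' @return A list: `status` (`"ok"` or `"rejected"`), `reason`, and for
#'   accepted ranges `i_min`, `i_max` (scale indices), `a_min`, `a_max`.
#' @export
select_scaling_range <- function(pfs, min_span_octaves = 1.5, min_r2 = 0.95,
                                 rmse_tol = 0.12, q_set = c(-1, 0, 1, 2)) {
  la <- log2(pfs$scales)
  iq <- match(q_set, pfs$q_grid)
  if (anyNA(iq)) stop_bad_arg("q_set must be a subset of the q_grid")
  ns <- length(pfs$scales)
  best <- NULL
  for (i in seq_len(max(ns - 3L, 0L))) for (j in (i + 3L):ns) {
    if (la[j] - la[i] < min_span_octaves) next
    ok <- TRUE
    for (q in iq) {
      y <- log2(pfs$Z[q, i:j])
      if (anyNA(y)) { ok <- FALSE; break }
      ft <- stats::lm.fit(cbind(1, la[i:j]), y)
      rmse <- sqrt(mean(ft$residuals^2))
      ss <- sum((y - mean(y))^2)
      r2 <- if (ss > 0) 1 - sum(ft$residuals^2) / ss else 1
      if (!(r2 >= min_r2 || rmse <= rmse_tol)) { ok <- FALSE; break }
    }
    if (ok && (is.null(best) || (la[j] - la[i]) > (la[best[2]] - la[best[1]])))
      best <- c(i, j)
  }
  if (is.null(best))
    return(list(status = "rejected", reason = "no-scaling"))
  list(status = "ok", reason = NULL, i_min = best[1], i_max = best[2],
       a_min = pfs$scales[best[1]], a_max = pfs$scales[best[2]])
}

#' Fit the scaling exponents tau(q)
#'
#' Least-squares slope of `log2 Z(q,a)` against `log2 a` within the selected
#' scaling range, one regression per moment order; standard errors and
#' R-squared come from the per-q regressions.
#'
#' @param pfs a `partition_functions` object.
#' @param range result of [select_scaling_range] (or a list with `i_min`,
#'   `i_max`).
#' @return Object of class `scaling_fit` with `tau`, `stderr`, `r2` per q,
#'   the `q_grid`, the scaling range, and `status`; status `"rejected"`
#'   (reason `"short-range"`) when the range holds fewer than 4 scales.
#' @export
fit_tau <- function(pfs, range) {
  if (!is.null(range$status) && range$status != "ok")
    return(structure(list(status = "rejected", reason = range$reason),
                     class = "scaling_fit"))
  idx <- range$i_min:range$i_max
  if (length(idx) < 4L)
    return(structure(list(status = "rejected", reason = "short-range"),
                     class = "scaling_fit"))
  la <- log2(pfs$scales[idx])
  nq <- length(pfs$q_grid)
  tau <- se <- r2 <- rep(NA_real_, nq)
  n <- length(la)
  sxx <- sum((la - mean(la))^2)
  for (iq in seq_len(nq)) {
    y <- log2(pfs$Z[iq, idx])
    if (anyNA(y)) next
    b <- sum((la - mean(la)) * (y - mean(y))) / sxx
    res <- y - mean(y) - b * (la - mean(la))
    sse <- sum(res^2); sst <- sum((y - mean(y))^2)
    tau[iq] <- b
    se[iq] <- sqrt(sse / (n - 2) / sxx)
    r2[iq] <- if (sst > 0) 1 - sse / sst else 1
  }
  structure(list(status = "ok", reason = NULL, q_grid = pfs$q_grid, tau = tau,
                 stderr = se, r2 = r2,
                 scaling_range = c(range$a_min, range$a_max),
                 range_index = c(range$i_min, range$i_max)),
            class = "scaling_fit")
}

#' Singularity spectrum by discrete Legendre transform
#'
#' \eqn{D(h) = \min_q (qh - \tau(q))}; equivalently \eqn{h(q) = d\tau/dq}
#' by central differences and \eqn{D = q\,h(q) - \tau(q)}.  A warning flag is
#' set when \eqn{\tau(q)} is non-concave beyond `concavity_tol` (the
#' spectrum is still returned).
#'
#' @param fit a `scaling_fit` with status `"ok"`.
#' @param concavity_tol tolerance on positive second differences.
#' @return A `data.frame` with columns `q`, `h`, `D`; attribute
#'   `"non_concave"` is `TRUE` when concavity is violated.
#' @export
legendre_spectrum <- function(fit, concavity_tol = 1e-8) {
  if (fit$status != "ok") stop_bad_arg("cannot compute a spectrum from a rejected fit")
  q <- fit$q_grid; tau <- fit$tau
  nq <- length(q)
  h <- rep(NA_real_, nq)
  h[2:(nq - 1)] <- (tau[3:nq] - tau[1:(nq - 2)]) / (q[3:nq] - q[1:(nq - 2)])
  h[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  h[nq] <- (tau[nq] - tau[nq - 1]) / (q[nq] - q[nq - 1])
  D <- q * h - tau
  d2 <- diff(tau, differences = 2)
  non_concave <- any(d2 > concavity_tol, na.rm = TRUE)
  if (non_concave) warning("tau(q) is non-concave beyond tolerance")
  out <- data.frame(q = q, h = h, D = D)
  attr(out, "non_concave") <- non_concave
  out
}

#' Monofractality screening and Hurst exponent
#'
#' Fits a quadratic in `q` to tau(q), weighting each point by the inverse
#' squared standard error of its slope estimate.  The patch is monofractal
#' when the absolute quadratic coefficient stays within `curvature_tol`
#' (in tau units); the Hurst exponent is then the linear coefficient of the
#' fit.  Otherwise the estimate is rejected with reason `"multifractal"`.
#'
#' @param fit a `scaling_fit`.
#' @param curvature_tol see [wtmm_config].
#' @return Object of class `hurst_estimate`: `H`, `stderr`, `curvature`,
#'   `monofractal`, `status`, `reason` and the fit as `provenance`.
#' @export
assess_monofractality <- function(fit, curvature_tol = 0.05) {
  if (fit$status != "ok")
    return(structure(list(status = "rejected", reason = fit$reason, H = NA_real_,
                          monofractal = FALSE),
                     class = "hurst_estimate"))
  q <- fit$q_grid
  w <- 1 / pmax(fit$stderr, 1e-6)^2
  ok <- is.finite(fit$tau) & is.finite(w)
  qf <- stats::lm(fit$tau[ok] ~ q[ok] + I(q[ok]^2), weights = w[ok])
  cf <- stats::coef(qf)
  curv <- unname(cf[3])
  H <- unname(cf[2])
  mono <- abs(curv) <= curvature_tol
  structure(list(status = if (mono) "ok" else "rejected",
                 reason = if (mono) NULL else "multifractal",
                 H = if (mono) H else NA_real_, H_raw = H,
                 stderr = unname(sqrt(diag(stats::vcov(qf)))[2]),
                 curvature = curv, monofractal = mono, provenance = fit),
            class = "hurst_estimate")
}

#' @export
print.hurst_estimate <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<hurst_estimate H = %.3f (se %.3f), curvature %+.3f, monofractal>\n",
                x$H, x$stderr, x$curvature))
  else
    cat(sprintf("<hurst_estimate rejected: %s>\n", x$reason))
  invisible(x)
}

## ---------------------------------------------------------------------------
## finite-size attenuation correction

#' Finite-window attenuation table for the gradient modulus
#'
#' On a finite (mirror-periodized) domain the low-frequency part of a
#' monofractal surface is truncated, so the RMS of the scale-`a` gradient
#' modulus falls below the ideal \eqn{a^H} law by a factor that grows with
#' `a` and with `H`.  This table measures that factor by Monte Carlo: for
#' each `H` on a grid, `K` reference surfaces are drawn from the package
#' generator, passed through the same detrend + mirror-pad chain as an
#' analyzed patch, and the mean log2 RMS of the modulus (via Parseval, one
#' FFT per surface) is recorded; `log2 g(a,H)` is that mean minus
#' `H log2 a`.  Reference seeds are fixed constants, so the table - and
#' every estimate that uses it - is fully deterministic.  Tables are
#' memoized per geometry within a session.
#'
#' @param side analyzed patch side in pixels.
#' @param scales scale vector.
#' @param detrend_degree as in [wtmm_config].
#' @param Hgrid grid of Hurst exponents covered by the table.
#' @param K reference surfaces per grid point.
#' @param context context multiplier for the reference surfaces: 1 analyzes
#'   stand-alone patches (references come from the patch generator); values
#'   above 1 (the sliding-window protocol uses 3) draw each reference as the
#'   centre of a periodically synthesized field `context` times the analyzed
#'   side, emulating a window embedded in a larger mammogram.
#' @return List with `Hgrid` and matrix `logg` (|scales| x |Hgrid|).
#' @export
attenuation_table <- function(side, scales, detrend_degree = 2L,
                              Hgrid = seq(0.05, 0.95, by = 0.05), K = 8L,
                              context = 1L) {
  key <- paste0("att_", side, "_", detrend_degree, "_", K, "_", context, "_",
                paste(signif(scales, 6), collapse = "_"))
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])
  pad <- side %/% 2L
  np <- side + 2L * pad
  kx <- matrix(fft_freq(np), np, np, byrow = TRUE)
  ky <- matrix(fft_freq(np), np, np)
  k2 <- kx * kx + ky * ky
  W <- lapply(scales, function(a) k2 * exp(-a * a * k2))
  G <- matrix(0, length(scales), length(Hgrid))
  for (j in seq_along(Hgrid)) {
    acc <- numeric(length(scales))
    for (r in seq_len(K)) {
      ref <- if (context > 1L) {
        ## window embedded in a context-times-larger field: synthesize the
        ## field periodically at that size and take the centre
        big <- fbm_periodic(side * context, Hgrid[j], derive_seed(770011L, j, r))
        off <- (nrow(big) - side) %/% 2L
        big[(off + 1L):(off + side), (off + 1L):(off + side)]
      } else {
        generate_fbm_surface(side, Hgrid[j],
                             seed = derive_seed(770011L, j, r))$values
      }
      ref <- detrend_surface(ref, detrend_degree)
      P <- Mod(stats::fft(mirror_pad(ref, pad)))^2 / (np^4)
      v <- vapply(seq_along(scales), function(s) sum(W[[s]] * P), numeric(1))
      acc <- acc + log2(scales * sqrt(v))
    }
    G[, j] <- acc / K - log2(scales) * Hgrid[j]
  }
  tab <- list(Hgrid = Hgrid, logg = G)
  .pkg_env[[key]] <- tab
  tab
}

## ---------------------------------------------------------------------------
## patch-level driver

#' Estimate the Hurst exponent of an image patch
#'
#' Runs the complete WTMM chain on one patch: polynomial detrend, gradient
#' wavelet transform (optionally restricted to a centred core), maxima
#' chains, space-scale skeleton, partition functions, scaling-range
#' selection, tau(q) fit and monofractality screening.  When
#' `finite_size_correction` is on, the line moduli are divided by the
#' attenuation factor `g(a, H)` of [attenuation_table] and the fit repeated
#' for a few fixed-point iterations in `H`.
#'
#' The engine is fully deterministic: identical input and configuration give
#' identical estimates.
#'
#' @param image a [gray_image] or numeric matrix (square patch).
#' @param config a [wtmm_config].
#' @param core_side when the patch carries surrounding context (the sliding
#'   window protocol), statistics are restricted to this centred core.
#' @return A `hurst_estimate`; rejected estimates carry a reason code
#'   (`"no-scaling"`, `"multifractal"`, `"too-few-lines"`).
#' @export
estimate_hurst <- function(image, config = wtmm_config(), core_side = NULL) {
  img <- as_gray_image(image)
  f <- detrend_surface(img$values, config$detrend_degree)
  outer_side <- nrow(f)
  field <- gradient_wavelet_transform(gray_image(f), config$scales)
  if (!is.null(core_side)) field <- crop_wt_field(field, core_side)
  scales <- field$scales
  chains <- lapply(seq_along(scales), function(s)
    extract_wtmm_chains(field, scale_index = s,
                        min_chain_length = config$min_chain_length))
  skel <- build_skeleton(chains, scales, link_radius_min = config$link_radius_min,
                         maxima_window_frac = config$maxima_window_frac,
                         dim = field$dim)
  if (is.null(skel) || nrow(skel) < 10L * length(scales))
    return(structure(list(status = "rejected", reason = "too-few-lines",
                          H = NA_real_, monofractal = FALSE),
                     class = "hurst_estimate"))
  tab <- if (config$finite_size_correction)
    attenuation_table(outer_side, scales, config$detrend_degree,
                      K = config$attenuation_K,
                      context = if (is.null(core_side)) 1L else 3L) else NULL
  gvec <- rep(1, length(scales))
  est <- NULL
  n_iter <- if (config$finite_size_correction) config$n_correction_iter else 1L
  for (it in seq_len(n_iter)) {
    sk <- data.table::copy(skel)
    sk[, modulus := modulus / gvec[scale_index]]
    data.table::setattr(sk, "scales", scales)
    pfs <- suppressWarnings(compute_partition_functions(sk, config$q_grid, scales))
    rg <- select_scaling_range(pfs, config$min_span_octaves, config$min_r2,
                               config$rmse_tol, config$range_q_set)
    fit <- fit_tau(pfs, rg)
    est <- assess_monofractality(fit, config$curvature_tol)
    est$partition_functions <- pfs
    if (est$status == "rejected" && is.na(est$H_raw %||% NA_real_)) return(est)
    if (is.null(tab)) break
    Hc <- min(max(est$H_raw, tab$Hgrid[1]), tab$Hgrid[length(tab$Hgrid)])
    lg <- vapply(seq_along(scales),
                 function(s) stats::approx(tab$Hgrid, tab$logg[s, ], Hc)$y,
                 numeric(1))
    gvec <- 2^(lg - lg[1])
  }
  est
}
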
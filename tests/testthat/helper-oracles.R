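## Independent oracles used across the suite.  These re-derive expected
## values through routes that do not share code with the implementation.

## radially resolved log-periodogram slope -> Hurst exponent
oracle_periodogram_H <- function(mat) {
  n <- nrow(mat)
  per <- Mod(stats::fft(mat))^2
  fr <- c(0:(n / 2), -((n / 2 - 1):1)) / n
  kx <- matrix(fr, n, n, byrow = TRUE)
  ky <- matrix(fr, n, n)
  kk <- sqrt(kx^2 + ky^2)
  sel <- kk > 2 / n & kk < 0.25 & per > 0
  beta <- -unname(coef(lm(log(per[sel]) ~ log(kk[sel])))[2])
  (beta - 2) / 2
}

## isotropic second-order structure function slope over lags 2..16 px
oracle_structure_H <- function(mat, lags = c(2, 4, 8, 16)) {
  n <- nrow(mat)
  sf <- sapply(lags, function(e) {
    mean((mat[, (e + 1):n] - mat[, 1:(n - e)])^2) +
      mean((mat[(e + 1):n, ] - mat[1:(n - e), ])^2)
  })
  unname(coef(lm(log(sf) ~ log(lags)))[2]) / 2
}

## brute-force scan of the modulus-maxima definition: for every interior
## pixel, compare against bilinear interpolation one pixel away on either
## side of the gradient direction (scalar loops, no shared code)
oracle_wtmm_scan <- function(modulus, argument) {
  n1 <- nrow(modulus); n2 <- ncol(modulus)
  bil <- function(y, x) {
    y0 <- floor(y); x0 <- floor(x)
    if (y0 < 1 || x0 < 1 || y0 + 1 > n1 || x0 + 1 > n2) return(NA_real_)
    fy <- y - y0; fx <- x - x0
    modulus[y0, x0] * (1 - fy) * (1 - fx) + modulus[y0 + 1, x0] * fy * (1 - fx) +
      modulus[y0, x0 + 1] * (1 - fy) * fx + modulus[y0 + 1, x0 + 1] * fy * fx
  }
  keep <- matrix(FALSE, n1, n2)
  for (i in 2:(n1 - 1)) for (j in 2:(n2 - 1)) {
    m <- modulus[i, j]
    if (m <= 0) next
    dy <- sin(argument[i, j]); dx <- cos(argument[i, j])
    pf <- bil(i + dy, j + dx)
    pb <- bil(i - dy, j - dx)
    if (is.na(pf) || is.na(pb)) next
    keep[i, j] <- (m >= pf) && (m > pb)
  }
  keep
}

## exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

## brute-force re-scan of the along-chain maxima rule used by the skeleton:
## a chain pixel survives iff no chain pixel within Chebyshev radius r has a
## larger modulus (ties: earlier raster index wins)
oracle_chain_maxima <- function(chains, a, dim, window_frac = 1 / 3) {
  if (!nrow(chains)) return(chains)
  r <- max(1L, as.integer(round(a * window_frac)))
  idx <- (chains$x - 1L) * dim[1] + chains$y
  keep <- logical(nrow(chains))
  for (i in seq_len(nrow(chains))) {
    win <- abs(chains$y - chains$y[i]) <= r & abs(chains$x - chains$x[i]) <= r
    win[i] <- FALSE
    keep[i] <- !any(chains$modulus[win] > chains$modulus[i] |
                      (chains$modulus[win] == chains$modulus[i] & idx[win] < idx[i]))
  }
  chains[keep, ]
}

## hand-built partition-function object for exact-scaling fixtures
make_pfs <- function(Z, q_grid, scales) {
  structure(list(Z = Z, n_lines = rep(1L, length(scales)),
                 h_qa = NULL, D_qa = NULL, q_grid = q_grid,
                 scales = scales),
            class = "partition_functions")
}

## hand-built skeleton: lines with constant modulus across all scales
make_const_skeleton <- function(moduli, scales) {
  sk <- data.table::rbindlist(lapply(seq_along(moduli), function(l)
    data.table::data.table(line = l, scale_index = seq_along(scales),
                           scale = scales, y = l, x = l,
                           modulus = moduli[l])))
  data.table::setattr(sk, "scales", scales)
  sk
}

## shared small fixtures (memoized per test process)
fbm_patch <- local({
  cache <- list()
  function(side, H, seed) {
    key <- paste(side, H, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_fbm_surface(side, H, seed)
    cache[[key]]
  }
})
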
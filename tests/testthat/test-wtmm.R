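## gradient wavelet transform -------------------------------------------------

test_that("constant image has zero modulus and no chains at any scale", {
  field <- gradient_wavelet_transform(matrix(5, 64, 64), scale_family(2, 8, 10))
  for (s in seq_along(field$scales)) {
    expect_lt(max(field$fields[[s]]$modulus), 1e-9)
    expect_equal(nrow(extract_wtmm_chains(field, scale_index = s)), 0L)
  }
})

test_that("planar ramp gives a constant gradient along +x", {
  n <- 64L
  ramp <- matrix(rep(seq_len(n), each = n), n, n)  # f(x, y) = x
  field <- gradient_wavelet_transform(ramp, scales = c(2, 3, 4))
  ctr <- 24:40
  for (s in 1:3) {
    a <- field$scales[s]
    ## argument ~ 0 (gradient along +x), modulus ~ a * |slope| in the interior
    expect_lt(max(abs(field$fields[[s]]$argument[ctr, ctr])), 1e-6)
    expect_lt(max(abs(field$fields[[s]]$modulus[ctr, ctr] / a - 1)), 0.02)
  }
})

test_that("isotropic Gaussian bump yields a radially symmetric ring of maxima", {
  n <- 128L; sigma <- 8
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  bump <- exp(-((yy - 64)^2 + (xx - 64)^2) / (2 * sigma^2))
  a <- 4
  field <- gradient_wavelet_transform(bump, scales = c(a, 6))
  M <- field$fields[[1]]$modulus
  ## closed form: smoothing by the scale-a Gaussian gives width
  ## sqrt(sigma^2 + a^2); the radial derivative peaks at that radius
  r_max <- sqrt(sigma^2 + a^2)
  rad <- sqrt((yy - 64)^2 + (xx - 64)^2)
  peak_r <- mean(rad[M > 0.98 * max(M)])
  expect_lt(abs(peak_r - r_max), 1)
  ## radial symmetry: modulus at the four axis points of the ring agree
  r0 <- round(r_max)
  vals <- c(M[64 + r0, 64], M[64 - r0, 64], M[64, 64 + r0], M[64, 64 - r0])
  expect_lt(diff(range(vals)) / mean(vals), 0.01)
  ## maxima trace the ring: all chain pixels near radius r_max, covering
  ## (nearly) the full circle (discretization may split the ring into arcs)
  ch <- extract_wtmm_chains(field, scale_index = 1)
  ch <- ch[ch$modulus > 1e-3 * max(ch$modulus), ]   # drop numerical ripple
  expect_gt(nrow(ch), 30)
  r_ch <- sqrt((ch$y - 64)^2 + (ch$x - 64)^2)
  expect_lt(max(abs(r_ch - r_max)), 2)
  ang <- atan2(ch$y - 64, ch$x - 64)
  expect_gte(length(unique(cut(ang, seq(-pi, pi, length.out = 25)))), 20L)
})

test_that("transform is linear in the image", {
  set.seed(42)
  f <- matrix(rnorm(64^2), 64, 64)
  g <- matrix(rnorm(64^2), 64, 64)
  sc <- c(2, 4, 8)
  Ff <- gradient_wavelet_transform(f, sc, keep_smooth = TRUE)
  Fg <- gradient_wavelet_transform(g, sc, keep_smooth = TRUE)
  Fs <- gradient_wavelet_transform(f + g, sc, keep_smooth = TRUE)
  for (s in 1:3) {
    expect_lt(max(abs(Fs$fields[[s]]$smooth -
                        (Ff$fields[[s]]$smooth + Fg$fields[[s]]$smooth))), 1e-10)
    ## gradient components reconstructed from modulus/argument are additive
    gx <- function(F) with(F$fields[[s]], modulus * cos(argument))
    gy <- function(F) with(F$fields[[s]], modulus * sin(argument))
    expect_lt(max(abs(gx(Fs) - (gx(Ff) + gx(Fg)))), 1e-10)
    expect_lt(max(abs(gy(Fs) - (gy(Ff) + gy(Fg)))), 1e-10)
  }
})

test_that("scale larger than the image is refused", {
  expect_error(gradient_wavelet_transform(matrix(0, 64, 64), scales = c(4, 70)),
               "scale")
})

## maxima chains: oracle equivalence ------------------------------------------

test_that("chain pixels match a brute-force scan of the maxima definition", {
  img <- fbm_patch(64, 0.5, 3)
  field <- gradient_wavelet_transform(img, scales = c(2, 3, 5))
  for (s in 1:3) {
    fl <- field$fields[[s]]
    want <- which(oracle_wtmm_scan(fl$modulus, fl$argument))
    got <- extract_wtmm_chains(field, scale_index = s, min_chain_length = 1L)
    got_idx <- sort((got$x - 1L) * 64L + got$y)
    expect_identical(got_idx, sort(want))
  }
})

## skeleton -------------------------------------------------------------------

test_that("an isolated cusp singularity produces one line converging to it", {
  n <- 96L
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  cusp <- sqrt(sqrt((yy - 48)^2 + (xx - 48)^2))    # |r - r0|^0.5
  sc <- scale_family(2, 8, 10)
  field <- gradient_wavelet_transform(cusp, sc)
  chains <- lapply(seq_along(sc), function(s)
    extract_wtmm_chains(field, scale_index = s))
  skel <- build_skeleton(chains, as.numeric(sc), dim = field$dim)
  first <- skel[skel$scale_index == 1L, ]
  ## the strongest maxima line at the smallest scale sits on the singularity
  top <- first[which.max(first$modulus), ]
  expect_lt(sqrt((top$y - 48)^2 + (top$x - 48)^2), 5)
  ## the singularity is tracked at every scale: the nearest maxima ring
  ## sits at a radius proportional to a and converges onto the cusp
  dmin <- sapply(seq_along(sc), function(s) {
    at_s <- skel[skel$scale_index == s, ]
    min(sqrt((at_s$y - 48)^2 + (at_s$x - 48)^2))
  })
  expect_true(all(dmin < 2.5 * as.numeric(sc) + 1))
  expect_true(all(diff(dmin) > 0))     # monotone convergence as a -> 0
})

test_that("two distant bumps give two disjoint sets of lines", {
  n <- 160L
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  two <- exp(-((yy - 40)^2 + (xx - 40)^2) / 32) +
    exp(-((yy - 120)^2 + (xx - 120)^2) / 32)
  sc <- scale_family(2, 6, 10)
  field <- gradient_wavelet_transform(two, sc)
  chains <- lapply(seq_along(sc), function(s)
    extract_wtmm_chains(field, scale_index = s))
  skel <- build_skeleton(chains, as.numeric(sc), dim = field$dim)
  skel <- skel[skel$modulus > 1e-3 * max(skel$modulus), ]   # drop numerical ripple
  d1 <- sqrt((skel$y - 40)^2 + (skel$x - 40)^2)
  d2 <- sqrt((skel$y - 120)^2 + (skel$x - 120)^2)
  expect_true(all(pmin(d1, d2) < 30))          # every point belongs to a bump
  near1 <- unique(skel$line[d1 < 30])
  near2 <- unique(skel$line[d2 < 30])
  expect_gt(length(near1), 0); expect_gt(length(near2), 0)
  expect_length(intersect(near1, near2), 0)    # no line wanders between bumps
})

test_that("along-chain maxima equal a brute-force re-scan (white noise)", {
  set.seed(9)
  img <- matrix(rnorm(64^2), 64, 64)
  field <- gradient_wavelet_transform(img, scales = c(3, 4))
  ch <- extract_wtmm_chains(field, scale_index = 1)
  got <- mammowtmm:::chain_maxima(ch, 3, c(64L, 64L))
  want <- oracle_chain_maxima(ch, 3, c(64L, 64L))
  expect_equal(nrow(got), nrow(want))
  expect_identical(got$y, want$y)
  expect_identical(got$x, want$x)
})

## partition functions ---------------------------------------------------------

test_that("hand-built skeletons give exact partition-function arithmetic", {
  sc <- 2^seq(1, 3, length.out = 5)
  sk3 <- make_const_skeleton(c(2, 4, 8), sc)
  pfs <- compute_partition_functions(sk3, q_grid = c(0, 2), scales = sc)
  expect_equal(pfs$Z[1, ], rep(3, 5))                   # Z(0, a) = |L(a)|
  expect_equal(pfs$Z[2, ], rep(4 + 16 + 64, 5))          # Z(2, a) = 84
  sk1 <- make_const_skeleton(5, sc)
  pfs1 <- compute_partition_functions(sk1, q_grid = c(-1, 0, 1, 3), scales = sc)
  expect_equal(pfs1$Z[, 1], 5^c(-1, 0, 1, 3))            # single line: m^q
})

test_that("Z(0, a) equals the line count exactly on real skeletons", {
  img <- fbm_patch(128, 0.5, 4)
  sc <- scale_family(3, 8, 10)
  field <- gradient_wavelet_transform(img, sc)
  chains <- lapply(seq_along(sc), function(s) extract_wtmm_chains(field, scale_index = s))
  skel <- build_skeleton(chains, as.numeric(sc), dim = field$dim)
  pfs <- compute_partition_functions(skel, q_grid = c(-1, 0, 1, 2))
  counts <- sapply(1:10, function(s) sum(skel$scale_index == s))
  expect_identical(as.integer(pfs$Z[pfs$q_grid == 0, ]), as.integer(counts))
  expect_identical(pfs$n_lines, counts)
})

test_that("(1/q) log Z is non-decreasing in q (moment inequality)", {
  sc <- 2^seq(1, 3, length.out = 5)
  qg <- c(-2, -1, -0.5, 0.5, 1, 2, 3)
  for (moduli in list(c(2, 4, 8), c(0.5, 1, 2, 4), c(1, 10))) {
    pfs <- compute_partition_functions(make_const_skeleton(moduli, sc), qg, sc)
    ## power-mean inequality: (1/q) log (Z(q)/N) is non-decreasing in q
    v <- (log2(pfs$Z[, 1]) - log2(length(moduli))) / qg
    expect_true(all(diff(v) >= -1e-12))
  }
})

## scaling range, tau, spectrum, monofractality -------------------------------

test_that("exact power laws recover tau to machine precision over the full range", {
  sc <- 2^seq(log2(3), log2(12), length.out = 12)
  qg <- seq(-2, 3, by = 0.5)
  Z <- outer(qg, sc, function(q, a) a^(0.5 * q - 2))
  pfs <- make_pfs(Z, qg, sc)
  rg <- select_scaling_range(pfs)
  expect_equal(rg$status, "ok")
  expect_equal(c(rg$i_min, rg$i_max), c(1L, 12L))
  fit <- fit_tau(pfs, rg)
  expect_lt(max(abs(fit$tau - (0.5 * qg - 2))), 1e-10)
})

test_that("piecewise fixture: range restricted to the power-law half", {
  sc <- 2^seq(0, 4, length.out = 24)
  qg <- c(-1, 0, 1, 2)
  Z <- outer(qg, sc, function(q, a) a^(0.4 * q - 2))
  Z[, 1:12] <- Z[, 12]                     # constant on the lower half
  pfs <- make_pfs(Z, qg, sc)
  ## at the default linearity gate the selected window sheds most of the
  ## flat prefix; at a strict gate it lies entirely in the power-law half
  rg <- select_scaling_range(pfs, min_span_octaves = 1)
  expect_equal(rg$status, "ok")
  expect_gte(rg$i_min, 8L)
  rg_strict <- select_scaling_range(pfs, min_span_octaves = 1, min_r2 = 0.995,
                                    rmse_tol = 0.05)
  expect_gte(rg_strict$i_min, 11L)   # within one scale of the break
})

test_that("shuffled (pure-noise) partition functions are rejected", {
  sc <- 2^seq(log2(3), log2(12), length.out = 12)
  qg <- c(-1, 0, 1, 2)
  set.seed(11)
  Z <- outer(qg, sc, function(q, a) a^(0.5 * q - 2))
  Z <- Z[, sample(ncol(Z))] * matrix(2^runif(length(Z), -2, 2), nrow(Z))
  rg <- select_scaling_range(make_pfs(Z, qg, sc))
  expect_equal(rg$status, "rejected")
  expect_equal(rg$reason, "no-scaling")
  fit <- fit_tau(make_pfs(Z, qg, sc), rg)
  expect_equal(fit$status, "rejected")
})

test_that("Legendre spectrum: linear, kinked and quadratic tau", {
  qg <- seq(-2, 3, by = 0.25)
  sc <- 2^seq(log2(3), log2(12), length.out = 10)
  mk_fit <- function(tau) {
    pfs <- make_pfs(outer(seq_along(qg), seq_along(sc), function(i, s)
      2^(tau[i] * log2(sc[s]))), qg, sc)
    fit_tau(pfs, list(status = "ok", i_min = 1L, i_max = length(sc),
                      a_min = sc[1], a_max = sc[length(sc)]))
  }
  ## linear tau -> spectrum collapses to (h = 0.5, D = 2)
  spec1 <- legendre_spectrum(mk_fit(0.5 * qg - 2))
  expect_lt(max(abs(spec1$h - 0.5)), 1e-9)
  expect_lt(max(abs(spec1$D - 2)), 1e-9)
  ## kinked tau -> h spans [0.3, 0.7]
  kink <- ifelse(qg < 0, 0.3 * qg - 2, 0.7 * qg - 2)
  spec2 <- suppressWarnings(legendre_spectrum(mk_fit(kink)))
  expect_equal(min(spec2$h), 0.3, tolerance = 1e-9)
  expect_equal(max(spec2$h), 0.7, tolerance = 1e-9)
  ## quadratic tau -> parabolic D(h) with apex D = 2 at q = 0
  quad <- -2 + 0.5 * qg - 0.05 * qg^2
  spec3 <- legendre_spectrum(mk_fit(quad))
  inner <- seq(2, nrow(spec3) - 1)         # one-sided endpoints are O(dq)
  expect_lt(max(abs(spec3$h[inner] - (0.5 - 0.1 * spec3$q[inner]))), 1e-9)
  expect_lt(max(abs(spec3$D[inner] - (2 - 0.05 * spec3$q[inner]^2))), 1e-9)
  expect_equal(max(spec3$D), 2, tolerance = 1e-9)
})

test_that("monofractality screening separates linear from curved tau", {
  qg <- seq(-2, 3, by = 0.25)
  sc <- 2^seq(log2(3), log2(12), length.out = 10)
  mk_fit <- function(tau) {
    f <- fit_tau(make_pfs(outer(seq_along(qg), seq_along(sc), function(i, s)
      2^(tau[i] * log2(sc[s]))), qg, sc),
      list(status = "ok", i_min = 1L, i_max = length(sc),
           a_min = sc[1], a_max = sc[length(sc)]))
    f
  }
  lin <- assess_monofractality(mk_fit(0.62 * qg - 2))
  expect_true(lin$monofractal)
  expect_equal(lin$H, 0.62, tolerance = 1e-8)
  multi <- assess_monofractality(mk_fit(-2 + 0.5 * qg - 0.2 * qg^2),
                                 curvature_tol = 0.05)
  expect_false(multi$monofractal)
  expect_equal(multi$reason, "multifractal")
})

test_that("fBm patch with H = 0.7 is accepted as monofractal with H in [0.6, 0.8]", {
  est <- estimate_hurst(fbm_patch(256, 0.7, 1))
  expect_equal(est$status, "ok")
  expect_true(est$monofractal)
  expect_gt(est$H, 0.6)
  expect_lt(est$H, 0.8)
  expect_lt(abs(est$curvature), 0.05)
})
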
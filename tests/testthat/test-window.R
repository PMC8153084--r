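test_that("window grid counts follow the closed form", {
  expect_equal(nrow(tile_image(matrix(0, 1000, 1000))), 441L)   # 21 x 21
  expect_equal(nrow(tile_image(matrix(0, 360, 360))), 1L)
  expect_warning(t0 <- tile_image(matrix(0, 200, 200)), "smaller")
  expect_equal(nrow(t0), 0L)
  ## property: random sizes vs brute-force enumeration
  set.seed(21)
  for (rep in 1:8) {
    n1 <- sample(360:900, 1); n2 <- sample(360:900, 1)
    tl <- tile_image(matrix(0, n1, n2))
    brute <- 0L
    y0 <- 1L
    while (y0 + 359L <= n1) {
      x0 <- 1L
      while (x0 + 359L <= n2) { brute <- brute + 1L; x0 <- x0 + 32L }
      y0 <- y0 + 32L
    }
    expect_equal(nrow(tl), brute)
  }
})

test_that("mask coverage excludes windows outside the breast", {
  n <- 680L
  mask <- matrix(FALSE, n, n); mask[, 1:(n / 2)] <- TRUE  # left half only
  tl_full <- tile_image(matrix(0, n, n))
  tl <- tile_image(matrix(0, n, n), mask)
  expect_lt(nrow(tl), nrow(tl_full))
  ## windows whose core sits fully in the right half are gone
  m <- (360L - 256L) %/% 2L
  right_core <- tl$x0 + m > n / 2
  expect_false(any(right_core))
})

test_that("tissue classification matches the printed boundary semantics", {
  expect_equal(as.character(classify_hurst(0.45)), "fatty")
  expect_equal(as.character(classify_hurst(0.50)), "disrupted")
  expect_equal(as.character(classify_hurst(0.55)), "dense")
  ## total and monotone w.r.t. the class order fatty < disrupted < dense
  grid <- seq(0.01, 0.99, by = 0.001)
  cls <- classify_hurst(grid)
  expect_false(any(is.na(cls)))
  expect_true(all(diff(as.integer(cls)) >= 0))
  ## boundary suprema / infima on the fine grid
  g2 <- seq(0.40, 0.60, by = 0.001)
  c2 <- classify_hurst(g2)
  expect_equal(max(g2[c2 == "fatty"]), 0.45)
  expect_equal(min(g2[c2 == "dense"]), 0.55)
})

test_that("constant window is rejected for lack of maxima", {
  r <- analyze_window(matrix(7, 360, 360))
  expect_equal(r$class, "rejected")
  expect_equal(r$reason, "too-few-lines")
  expect_true(is.na(r$H))
})

test_that("windows from fatty- and dense-textured surfaces classify correctly", {
  ## H = 0.30 texture -> fatty; H = 0.65 -> dense (fixed seeds, deterministic)
  r_fat <- analyze_window(fbm_patch(360, 0.30, 1)$values)
  expect_equal(r_fat$class, "fatty")
  r_den <- analyze_window(fbm_patch(360, 0.65, 1)$values)
  expect_equal(r_den$class, "dense")
})

test_that("sliding-window analysis is deterministic and class map aligns with grid", {
  spec <- phantom_spec(image_side = 392L, mask_shape = "full_frame",
                       regions = list(phantom_region(0.3)))
  ph <- generate_phantom_mammogram(spec, seed = 5)
  a1 <- analyze_mammogram(ph$image, ph$mask)
  a2 <- analyze_mammogram(ph$image, ph$mask)
  expect_identical(a1$class_map, a2$class_map)
  expect_identical(a1$windows, a2$windows)
  expect_equal(dim(a1$class_map), c(2L, 2L))   # floor((392-360)/32)+1 per axis
  expect_true(all(a1$windows$class %in%
                    c("fatty", "disrupted", "dense", "rejected")))
  ## rejected <=> H is null
  expect_identical(is.na(a1$windows$H), a1$windows$class == "rejected")
  ## fatty texture: accepted windows overwhelmingly fatty
  acc <- a1$windows$class != "rejected"
  expect_gte(mean(acc), 0.8)
  expect_gte(mean(a1$windows$class[acc] == "fatty"), 0.7)
})

test_that("two-region phantom segregates classes between regions", {
  ## top half fatty-like (H = 0.30), bottom half dense-like (H = 0.65);
  ## bands are one full window tall so that window cores sample pure texture
  spec <- phantom_spec(image_side = 720L, mask_shape = "full_frame",
                       regions = list(
                         phantom_region(0.30, shape = "band", from = 0, to = 0.5),
                         phantom_region(0.65, shape = "band", from = 0.5, to = 1)))
  ph <- generate_phantom_mammogram(spec, seed = 2)
  v <- ph$image$values
  origins <- expand.grid(y0 = c(1L, 361L), x0 = c(1L, 181L, 361L))
  res <- lapply(seq_len(nrow(origins)), function(k) {
    y0 <- origins$y0[k]; x0 <- origins$x0[k]
    r <- analyze_window(v[y0:(y0 + 359L), x0:(x0 + 359L)])
    data.frame(band = if (y0 == 1L) "fatty" else "dense", H = r$H,
               class = r$class)
  })
  res <- do.call(rbind, res)
  expect_true(all(res$class != "rejected"))
  hf <- res$H[res$band == "fatty"]; hd <- res$H[res$band == "dense"]
  ## regions segregate: dense-band windows read rougher, with a clear gap
  expect_gt(mean(hd) - mean(hf), 0.2)
  expect_lt(max(hf), min(hd))
  ## one-sided class majorities within each region
  expect_gte(mean(res$class[res$band == "fatty"] == "fatty"), 0.7)
  expect_gte(mean(res$class[res$band == "dense"] == "dense"), 0.7)
})

test_that("class map renders to a valid RGB array", {
  cm <- matrix(c("fatty", "dense", "rejected", NA), 2, 2)
  arr <- render_class_map(cm)
  expect_equal(dim(arr), c(2, 2, 3))
  expect_true(all(arr >= 0 & arr <= 1))
})
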
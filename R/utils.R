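## internal helpers shared across modules

.pkg_env <- new.env(parent = emptyenv())
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(sprintf(...), call. = FALSE)

## run code with an isolated RNG stream seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## deterministic 31-bit child seed from a parent seed and an index tuple
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h %% .Machine$integer.max) + 1L
}

## reflection (mirror) padding by p pixels on every side; p may exceed dim
refl_idx <- function(n, p) {
  base <- c(seq_len(n), rev(seq_len(n)))           # period-2n reflection
  base[(((1 - p):(n + p)) - 1L) %% (2L * n) + 1L]
}

mirror_pad <- function(m, p) {
  m[refl_idx(nrow(m), p), refl_idx(ncol(m), p)]
}

## remove a low-order 2D polynomial surface (degree 0, 1 or 2)
detrend_surface <- function(m, degree = 2L) {
  if (degree < 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  x <- rep(seq_len(nc), each = nr) / nc
  y <- rep(seq_len(nr), nc) / nr
  X <- switch(as.character(degree),
    "0" = cbind(1),
    "1" = cbind(1, x, y),
    cbind(1, x, y, x * y, x * x, y * y))
  matrix(lm.fit(X, as.vector(m))$residuals, nr, nc)
}

## bilinear sample of matrix M at fractional (row, col) positions
bilinear_at <- function(M, yi, xi) {
  n <- nrow(M)
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  id <- function(y, x) (x - 1L) * n + y
  M[id(y0, x0)] * (1 - fy) * (1 - fx) +
    M[id(y0 + 1L, x0)] * fy * (1 - fx) +
    M[id(y0, x0 + 1L)] * (1 - fy) * fx +
    M[id(y0 + 1L, x0 + 1L)] * fy * fx
}

## angular frequency grid (radians per pixel) for an n-point FFT axis
fft_freq <- function(n) {
  c(0:(n %/% 2), -(((n + 1L) %/% 2 - 1L):1)) / n * 2 * pi
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
  x == round(x)
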
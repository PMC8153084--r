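#' Read a mammogram image losslessly
#'
#' Supports PNG, TIFF, PGM (P2/P5) and uncompressed 8-bit BMP (converted at
#' import).  Pixel values are preserved as integers at the container's bit
#' depth; 12-bit data in a 16-bit container is not rescaled.  Lossy JPEG
#' input is refused explicitly.
#'
#' @param path file path.
#' @param bit_depth_hint override the inferred bit depth (e.g. 12 for
#'   12-bit data stored in 16-bit PNGs).
#' @param pixel_size pixel size in micrometres (default 50).
#' @return A [gray_image] with integer values.
#' @export
read_mammogram <- function(path, bit_depth_hint = NULL, pixel_size = 50) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) < 2L) stop_bad_arg("truncated or empty file: %s", path)
  vals <- NULL; depth <- NULL
  if (identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    stop_bad_arg("JPEG input refused: lossy compression corrupts intensity statistics")
  } else if (identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    bits <- info$bit.depth %||% 8L
    if (length(dim(x)) == 3L) x <- x[, , 1]        # first channel of gray-alpha
    attr(x, "info") <- NULL
    vals <- round(x * (2^bits - 1))
    depth <- bits
  } else if (identical(magic[1:2], charToRaw("II")) ||
             identical(magic[1:2], charToRaw("MM"))) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    vals <- x
    depth <- if (max(x) > 255) 16L else 8L
  } else if (identical(magic[1:2], charToRaw("P5")) ||
             identical(magic[1:2], charToRaw("P2"))) {
    r <- read_pgm(path)
    vals <- r$values; depth <- if (r$maxval > 255) 16L else 8L
  } else if (identical(magic[1:2], charToRaw("BM"))) {
    vals <- read_bmp8(path)
    depth <- 8L
  } else {
    stop_bad_arg("unsupported image format (magic bytes %s)",
                 paste(magic, collapse = " "))
  }
  depth <- bit_depth_hint %||% depth
  depth <- if (depth <= 8) 8L else 12L
  if (max(vals) > 2^depth - 1 && depth == 12L)
    stop_bad_arg("values exceed the 12-bit range; pass a correct bit_depth_hint")
  gray_image(vals, pixel_size = pixel_size, bit_depth = depth)
}

## minimal PGM reader (binary P5 and ascii P2)
read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || ch == "") stop_bad_arg("truncated PGM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (!length(c2) || c2 %in% c("\n", "")) break } ; next }
      if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[ \t\r\n]", ch) || ch == "") break
      out <- paste0(out, ch)
    }
    out
  }
  type <- tok()
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  n <- w * h
  if (type == "P5") {
    sz <- if (maxval > 255) 2L else 1L
    raw <- readBin(con, "integer", n = n, size = sz, signed = FALSE,
                   endian = "big")
    if (length(raw) < n) stop_bad_arg("truncated PGM pixel data")
    vals <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  } else if (type == "P2") {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    nums <- as.integer(strsplit(trimws(txt), "[ \t\r\n]+")[[1]])
    if (length(nums) < n) stop_bad_arg("truncated PGM pixel data")
    vals <- matrix(nums[seq_len(n)], nrow = h, ncol = w, byrow = TRUE)
  } else stop_bad_arg("not a PGM file")
  list(values = vals, maxval = maxval)
}

## minimal uncompressed 8-bit BMP reader (BITMAPINFOHEADER, palette ignored:
## grayscale palettes map index i to intensity i)
read_bmp8 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (length(raw) < 54L) stop_bad_arg("truncated BMP")
  data_off <- u32(10L)
  w <- u32(18L); h <- u32(22L)
  bpp <- u16(28L); comp <- u32(30L)
  if (bpp != 8L || comp != 0L)
    stop_bad_arg("only uncompressed 8-bit BMP is supported (got %d bpp)", bpp)
  stride <- ((w + 3L) %/% 4L) * 4L
  need <- data_off + stride * h
  if (length(raw) < need) stop_bad_arg("truncated BMP pixel data")
  m <- matrix(0L, h, w)
  for (r in seq_len(h)) {               # BMP rows are stored bottom-up
    off <- data_off + (r - 1L) * stride
    m[h - r + 1L, ] <- as.integer(raw[(off + 1L):(off + w)])
  }
  m
}

#' Write a grayscale image as 16-bit PGM
#'
#' @param image a [gray_image] or integer matrix.
#' @param path destination path.
#' @param maxval container maximum (default 65535).
#' @export
write_pgm <- function(image, path, maxval = 65535L) {
  img <- as_gray_image(image)
  v <- round(img$values)
  if (any(v < 0 | v > maxval)) stop_bad_arg("values out of range for maxval %d", maxval)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(v), nrow(v), maxval), con,
            eos = NULL)
  writeBin(as.integer(t(v)), con, size = if (maxval > 255) 2L else 1L,
           endian = "big")
  invisible(path)
}

#' Segment the breast region of a mammogram
#'
#' Fallback segmentation when no mask is provided: Otsu threshold on the
#' intensity histogram, largest connected foreground component,
#' morphological closing with a disc brush.
#'
#' @param image a [gray_image] or matrix.
#' @param closing_radius disc radius in pixels.
#' @return Logical matrix; all-`FALSE` with a warning when no foreground is
#'   found.
#' @export
segment_breast <- function(image, closing_radius = 5L) {
  img <- as_gray_image(image)
  v <- img$values
  rng <- range(v)
  if (rng[2] == rng[1]) {
    warning("flat image: empty breast mask")
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  x <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  fg <- x > th
  if (!any(fg)) {
    warning("empty foreground: empty breast mask")
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  sz <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  big <- lab == which.max(sz)
  r <- max(3L, as.integer(closing_radius))
  if (r %% 2L == 0L) r <- r + 1L
  closed <- EBImage::closing(EBImage::Image(big * 1), EBImage::makeBrush(r, "disc"))
  as.matrix(closed) > 0.5
}

#' Run configuration for end-to-end analyses
#'
#' Bundles the window geometry, engine configuration, classification
#' thresholds and bookkeeping switches; `config_hash()` of this object is
#' embedded in every output so runs can be matched to their configuration.
#'
#' @param geometry a [window_geometry].
#' @param wtmm a [wtmm_config].
#' @param include_rejected_in_denominator see [compute_metrics].
#' @param seed integer seed recorded in outputs (the analysis engine itself
#'   is deterministic; the seed governs synthetic-data generation).
#' @param output_dir where end-to-end drivers write their files.
#' @return List of class `run_config`.
#' @export
run_config <- function(geometry = window_geometry(), wtmm = wtmm_config(),
                       include_rejected_in_denominator = FALSE,
                       seed = 1L, output_dir = ".") {
  structure(list(geometry = geometry, wtmm = wtmm,
                 thresholds = c(fatty_max = 0.45, dense_min = 0.55),
                 include_rejected_in_denominator = include_rejected_in_denominator,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Stable hash of a configuration object
#' @param config any serializable object.
#' @return Character scalar.
#' @export
config_hash <- function(config) rlang::hash(config)

#' Analyze a patient (tumor and contralateral breast)
#'
#' Runs the sliding-window analysis on both breasts, computes per-breast
#' metrics and the YB Factor, and returns a [patient_record].  A missing
#' opposite image yields a partial record without a factor.
#'
#' @param tumor_image,opposite_image [gray_image]s (opposite may be `NULL`).
#' @param tumor_mask,opposite_mask optional logical masks; when `NULL` the
#'   breast is segmented automatically.
#' @param config a [run_config].
#' @param patient_id,group,tumor_side record annotations.
#' @return A [patient_record] with the two `mammogram_analysis` objects
#'   attached as attribute `"analyses"`.
#' @export
run_patient <- function(tumor_image, opposite_image = NULL,
                        tumor_mask = NULL, opposite_mask = NULL,
                        config = run_config(),
                        patient_id = "P000", group = NA_character_,
                        tumor_side = NA_character_) {
  one <- function(img, mask) {
    if (is.null(mask)) mask <- segment_breast(img)
    analyze_mammogram(img, mask, config$wtmm, config$geometry)
  }
  at <- one(tumor_image, tumor_mask)
  mt <- compute_metrics(at, config$include_rejected_in_denominator)
  ao <- NULL; mo <- NULL
  if (!is.null(opposite_image)) {
    ao <- one(opposite_image, opposite_mask)
    mo <- compute_metrics(ao, config$include_rejected_in_denominator)
  }
  rec <- patient_record(patient_id, group, tumor_side, mt, mo)
  attr(rec, "analyses") <- list(tumor = at, opposite = ao)
  attr(rec, "config_hash") <- config_hash(config)
  rec
}

#' Write per-window results as CSV (0-based origins, documented header)
#'
#' @param analysis a `mammogram_analysis`.
#' @param path destination CSV.
#' @param config optional [run_config] whose hash is recorded in a comment
#'   header line.
#' @export
write_window_csv <- function(analysis, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# origins are 0-based, row-major; config_hash=%s",
                     if (is.null(config)) "NA" else config_hash(config)), con)
  utils::write.csv(analysis$windows, con, row.names = FALSE)
  invisible(path)
}
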
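#' Read a raster image into the canonical [0, 1] representation
#'
#' Reads a PNG or TIFF file (single- or three-channel) and returns an
#' [rgb_image()] with values scaled to `[0, 1]` by the file's bit depth.
#' Single-channel inputs are replicated to three identical channels so that
#' every downstream operator sees the same shape.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return An [rgb_image()] whose `source_depth` attribute records the file's
#'   bit depth (`"8-bit"`, `"16-bit"` or `"float"`).
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    depth <- if (attr(px, "info")$bit.depth >= 16L) "16-bit" else "8-bit"
    attr(px, "info") <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    bps <- info$bits.per.sample[1L]
    depth <- if (bps >= 32L) "float" else if (bps >= 16L) "16-bit" else "8-bit"
    px <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)",
         call. = FALSE)
  }
  if (is.null(dim(px))) dim(px) <- c(length(px), 1L)
  nch <- if (length(dim(px)) == 2L) 1L else dim(px)[3L]
  if (nch == 1L) {
    m <- if (length(dim(px)) == 3L) px[, , 1L, drop = TRUE] else px
    px <- array(rep(m, 3L), dim = c(dim(m), 3L))
  } else if (nch != 3L) {
    stop("unsupported channel count: ", nch, " (1 or 3 expected)",
         call. = FALSE)
  }
  px[] <- pmin(pmax(px, 0), 1)
  rgb_image(px, source_depth = depth)
}

#' Write an image, quantizing by the requested bit depth
#'
#' Values in `[0, 1]` are exported with round-half-up quantization (`0.5` at
#' 8-bit is stored as 128). PNG files are always 8-bit; 16-bit and 32-bit
#' float exports use TIFF. A float TIFF round trip is exact to 32-bit float
#' precision.
#'
#' @param img an [rgb_image()] or [gray_image()] (or a bare array/matrix with
#'   values in `[0, 1]`).
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param depth storage depth: `"8-bit"`, `"16-bit"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, depth = c("8-bit", "16-bit", "float")) {
  depth <- match.arg(depth)
  px <- as_array(img)
  check_unit_range(px)
  px[] <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff"))
    stop("unsupported output format: .", ext, call. = FALSE)
  if (depth != "float") {
    scale <- if (depth == "8-bit") 255 else 65535
    px[] <- floor(px * scale + 0.5) / scale  # round half up
  }
  if (ext == "png") {
    if (depth != "8-bit")
      stop("PNG export is 8-bit only; use TIFF for ", depth, call. = FALSE)
    png::writePNG(px, path)
  } else {
    bps <- switch(depth, "8-bit" = 8L, "16-bit" = 16L, "float" = 32L)
    tiff::writeTIFF(px, path, bits.per.sample = bps)
  }
  invisible(path)
}

#' Resize an image with bilinear interpolation
#'
#' Bilinear interpolation with anti-aliasing on downscale (delegated to
#' \pkg{EBImage}). The target may be given as a scale `factor` (a factor of 4
#' maps 1536 x 1376 tiles to 384 x 344) or as an explicit `size = c(height,
#' width)`.
#'
#' @param img an [rgb_image()] or [gray_image()].
#' @param factor positive scale divisor: output is `dim(img) / factor`
#'   (rounded to the nearest pixel, minimum 1).
#' @param size integer target `c(height, width)`; overrides `factor`.
#' @return An image of the same class with the requested dimensions.
#' @export
resize_image <- function(img, factor = NULL, size = NULL) {
  d <- dim(img)[1:2]
  if (is.null(size)) {
    if (is.null(factor) || !is.finite(factor) || factor <= 0)
      stop("need a positive 'factor' or an explicit 'size'", call. = FALSE)
    size <- pmax(1L, as.integer(round(d / factor)))
  }
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L))
    stop("'size' must be two positive integers (height, width)",
         call. = FALSE)
  if (all(size == d)) return(img)
  px <- as_array(img)
  # EBImage indexes dim 1 as x; passing w = rows keeps our row/col convention
  out <- EBImage::resize(EBImage::Image(px), w = size[1L], h = size[2L],
                         filter = "bilinear", antialias = TRUE)
  out <- EBImage::imageData(out)
  out[] <- pmin(pmax(out, 0), 1)
  if (inherits(img, "gray_image"))
    gray_image(out, method = attr(img, "method"),
               dialect = attr(img, "dialect"))
  else if (inherits(img, "rgb_image"))
    rgb_image(out, source_depth = attr(img, "source_depth"))
  else out
}

#' Channel-wise standardization statistics
#'
#' `fit_standardization()` computes the per-channel mean and population
#' standard deviation (`ddof = 0`) over all pixels of a collection of images,
#' as used to standardize model inputs. `apply_standardization()` applies
#' `(value - mean) / sd` per channel; with `invert = TRUE` it undoes it.
#'
#' @param images a single image or a list of [rgb_image()]/[gray_image()]
#'   objects, all with the same channel count.
#' @return `fit_standardization()` returns a `standardization_stats` object
#'   (fields `mean` and `sd`, one entry per channel);
#'   `apply_standardization()` returns a bare numeric array (standardized
#'   values are not restricted to `[0, 1]`).
#' @examples
#' imgs <- list(gray_image(matrix(c(0, 1, 0, 1), 2, 2)))
#' s <- fit_standardization(imgs)
#' s$mean  # 0.5
#' s$sd    # 0.5 (population sd of a two-point distribution)
#' @export
fit_standardization <- function(images) {
  if (!is.list(images)) images <- list(images)
  if (length(images) == 0L) stop("empty image collection", call. = FALSE)
  nch <- vapply(images, function(im) {
    d <- dim(as_array(im))
    if (length(d) == 2L) 1L else d[3L]
  }, integer(1))
  if (length(unique(nch)) != 1L)
    stop("all images must share a channel count", call. = FALSE)
  nch <- nch[1L]
  vals <- lapply(seq_len(nch), function(ch) {
    unlist(lapply(images, function(im) {
      a <- as_array(im)
      if (length(dim(a)) == 2L) as.vector(a) else as.vector(a[, , ch])
    }), use.names = FALSE)
  })
  mu <- vapply(vals, mean, numeric(1))
  sig <- vapply(vals, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  if (any(sig <= 0))
    stop("degenerate (constant) channel: standardization undefined",
         call. = FALSE)
  structure(list(mean = mu, sd = sig), class = "standardization_stats")
}

#' @rdname fit_standardization
#' @param img image (or bare array) to standardize.
#' @param stats a `standardization_stats` object from `fit_standardization()`.
#' @param invert if `TRUE`, map standardized values back to the original
#'   scale (`value * sd + mean`).
#' @export
apply_standardization <- function(img, stats, invert = FALSE) {
  stopifnot(inherits(stats, "standardization_stats"))
  a <- as_array(img)
  nch <- if (length(dim(a)) == 2L) 1L else dim(a)[3L]
  if (nch != length(stats$mean))
    stop("channel count mismatch: image has ", nch, ", stats have ",
         length(stats$mean), call. = FALSE)
  out <- a
  for (ch in seq_len(nch)) {
    sl <- if (nch == 1L) a else a[, , ch]
    v <- if (invert) sl * stats$sd[ch] + stats$mean[ch]
         else (sl - stats$mean[ch]) / stats$sd[ch]
    if (nch == 1L) out[] <- v else out[, , ch] <- v
  }
  out
}

#' @export
print.standardization_stats <- function(x, ...) {
  cat("<standardization_stats>\n  mean:", signif(x$mean, 6),
      "\n  sd:  ", signif(x$sd, 6), "\n")
  invisible(x)
}
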
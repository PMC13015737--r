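#' Image and mask containers
#'
#' The toolkit works on a single canonical representation: floating-point
#' arrays with values in `[0, 1]`, row = image row (height), column = image
#' column (width). Three light S3 wrappers carry the metadata the rest of the
#' package needs:
#'
#' * `rgb_image(pixels, source_depth)` -- an `H x W x 3` array; `source_depth`
#'   records the bit depth of the file the image came from (`"8-bit"`,
#'   `"16-bit"` or `"float"`).
#' * `gray_image(pixels, method, dialect)` -- an `H x W` matrix plus the name
#'   of the conversion that produced it and, for luminance, its rounding
#'   dialect.
#' * `label_mask(labels)` -- an `H x W` integer matrix over the label set
#'   `0` (background), `1` (benign/normal tissue), `2` (cancer).
#'
#' @param pixels numeric array (`H x W x 3` for `rgb_image`, `H x W` for
#'   `gray_image`) with all values in `[0, 1]`.
#' @param source_depth source bit depth, one of `"8-bit"`, `"16-bit"`,
#'   `"float"`.
#' @param method name of the conversion that produced a gray image.
#' @param dialect optional rounding-dialect tag (luminance only).
#' @param labels integer matrix with values in `{0, 1, 2}`.
#' @return An object of class `rgb_image`, `gray_image` or `label_mask`; the
#'   underlying data is the array itself.
#' @examples
#' img <- rgb_image(array(runif(2 * 2 * 3), dim = c(2, 2, 3)))
#' gray_image(matrix(0.5, 2, 2), method = "intensity")
#' label_mask(matrix(0L, 4, 4))
#' @export
rgb_image <- function(pixels, source_depth = "float") {
  pixels <- unclass(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("an rgb_image needs an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("image dimensions must be at least 1 x 1", call. = FALSE)
  check_unit_range(pixels)
  source_depth <- match.arg(source_depth, c("8-bit", "16-bit", "float"))
  structure(pixels, source_depth = source_depth, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
gray_image <- function(pixels, method = "unknown", dialect = NULL) {
  pixels <- unclass(pixels)
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop("a gray_image needs an H x W matrix", call. = FALSE)
  check_unit_range(pixels)
  structure(pixels, method = method, dialect = dialect, class = "gray_image")
}

#' @rdname rgb_image
#' @export
label_mask <- function(labels) {
  if (is.null(dim(labels)) || length(dim(labels)) != 2L)
    stop("a label_mask needs an H x W matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || !all(labels %in% 0:2))
    stop("mask labels must lie in {0 = background, 1 = benign, 2 = cancer}",
         call. = FALSE)
  structure(labels, class = "label_mask")
}

check_unit_range <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("pixel values must be finite", call. = FALSE)
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, source depth %s, range [%.3f, %.3f]>\n",
              d[1], d[2], attr(x, "source_depth"), min(x), max(x)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x)
  dial <- attr(x, "dialect")
  cat(sprintf("<gray_image %d x %d, method %s%s, range [%.3f, %.3f]>\n",
              d[1], d[2], attr(x, "method"),
              if (is.null(dial)) "" else paste0("/", dial), min(x), max(x)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x)
  tb <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf("<label_mask %d x %d: background %d, benign %d, cancer %d>\n",
              d[1], d[2], tb[1], tb[2], tb[3]))
  invisible(x)
}

# strip class/attrs down to a bare numeric array
as_array <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(a))
  a
}

# channel planes of an rgb_image as H x W matrices (dims kept even at 1 x 1)
channel <- function(img, i) {
  a <- as_array(img)
  m <- a[, , i, drop = FALSE]
  dim(m) <- dim(a)[1:2]
  m
}
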
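#' Classical grayscale conversion operators
#'
#' Four classical reductions of an RGB image to one intensity channel, each a
#' convex per-pixel combination of the channels and therefore mapping
#' `[0, 1]` inputs to `[0, 1]` outputs:
#'
#' * `intensity()`: the channel average `(R + G + B) / 3`.
#' * `luster()`: the lightness channel of the HLS color model,
#'   `(max(R, G, B) + min(R, G, B)) / 2`.
#' * `luminosity()`: `0.21 R + 0.72 G + 0.07 B`, a perception-motivated
#'   weighting that favors green.
#' * `luminance()`: `0.3 R + 0.59 G + 0.11 B`, the weighting commonly shipped
#'   by computer-vision libraries. Libraries differ in low-level rounding, so
#'   two dialects are provided: `"float"` evaluates the weighted sum in
#'   floating point, while `"fixed-point-8bit"` quantizes channels to 0--255,
#'   rounds the 8-bit weighted sum half to even, and rescales. The dialects
#'   differ by at most 1/255 per pixel, emulating the discrepancy between
#'   real library implementations.
#'
#' The weighted operators accept alternative `coefficients` (for instance the
#' ITU-R-style `c(0.299, 0.587, 0.114)`) for cross-library comparison.
#'
#' @param img an [rgb_image()].
#' @param coefficients three non-negative channel weights.
#' @param dialect luminance rounding dialect, `"float"` or
#'   `"fixed-point-8bit"`.
#' @return A [gray_image()] tagged with the conversion method (and dialect).
#' @examples
#' img <- rgb_image(array(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0),
#'                        dim = c(2, 2, 3)))
#' intensity(img)[1, 1]   # 1/3
#' luster(img)[1, 1]      # 0.5
#' luminosity(img)[1, 1]  # 0.21
#' luminance(img)[1, 1]   # 0.3
#' @name conversions
NULL

#' @rdname conversions
#' @export
intensity <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  g <- (channel(img, 1) + channel(img, 2) + channel(img, 3)) / 3
  gray_image(g, method = "intensity")
}

#' @rdname conversions
#' @export
luster <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  r <- channel(img, 1); g <- channel(img, 2); b <- channel(img, 3)
  out <- (pmax(r, g, b) + pmin(r, g, b)) / 2
  gray_image(out, method = "luster")
}

#' @rdname conversions
#' @export
luminosity <- function(img, coefficients = c(0.21, 0.72, 0.07)) {
  stopifnot(inherits(img, "rgb_image"))
  w <- check_weights(coefficients)
  g <- w[1] * channel(img, 1) + w[2] * channel(img, 2) + w[3] * channel(img, 3)
  gray_image(pmin(g, 1), method = "luminosity")
}

#' @rdname conversions
#' @export
luminance <- function(img, dialect = c("float", "fixed-point-8bit"),
                      coefficients = c(0.3, 0.59, 0.11)) {
  stopifnot(inherits(img, "rgb_image"))
  dialect <- match.arg(dialect)
  w <- check_weights(coefficients)
  if (dialect == "float") {
    g <- w[1] * channel(img, 1) + w[2] * channel(img, 2) +
      w[3] * channel(img, 3)
    g <- pmin(g, 1)
  } else {
    # quantize channels to 0..255 (half up, matching export), accumulate at
    # 8 bits with round half to even, rescale
    q <- function(x) floor(x * 255 + 0.5)
    acc <- w[1] * q(channel(img, 1)) + w[2] * q(channel(img, 2)) +
      w[3] * q(channel(img, 3))
    g <- pmin(pmax(round(acc), 0), 255) / 255
  }
  gray_image(g, method = "luminance", dialect = dialect)
}

check_weights <- function(w) {
  if (length(w) != 3L || anyNA(w) || any(w < 0))
    stop("'coefficients' must be three non-negative weights", call. = FALSE)
  if (abs(sum(w) - 1) > 0.02)
    warning("channel weights sum to ", signif(sum(w), 4),
            "; output may leave [0, 1] and will be clipped")
  w
}

#' Dispatch a grayscale conversion by name
#'
#' Convenience front end used by the command-line interface: maps a method
#' name to the corresponding operator, including `"acsrm"`.
#'
#' @param img an [rgb_image()].
#' @param method one of `"intensity"`, `"luster"`, `"luminosity"`,
#'   `"luminance"`, `"acsrm"`.
#' @param dialect luminance dialect (ignored by other methods).
#' @param epsilon ACSRM degeneracy guard (ignored by other methods).
#' @return A [gray_image()].
#' @export
convert_gray <- function(img, method, dialect = "float", epsilon = 1e-8) {
  method <- match.arg(method, c("intensity", "luster", "luminosity",
                                "luminance", "acsrm"))
  switch(method,
         intensity = intensity(img),
         luster = luster(img),
         luminosity = luminosity(img),
         luminance = luminance(img, dialect = dialect),
         acsrm = acsrm_convert(img, epsilon = epsilon))
}
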
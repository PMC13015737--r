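#' Attention-based grayscale conversion (ACSRM)
#'
#' ACSRM derives one convex weight per color channel from the relationships
#' *between* channels and collapses the image with those weights. Let `F` be
#' the `3 x N` matrix whose rows are the flattened R, G, B channel vectors
#' (`N = H * W` pixels). The operator forms the channel Gram matrix
#' `G = F F^T`, standardizes each row of `G` by its own mean and population
#' standard deviation (`Z_i = (G_i - mean(G_i)) / (sd(G_i) + epsilon)`),
#' applies a row-wise softmax to obtain a row-stochastic attention matrix
#' `S`, and averages its rows into the weight vector
#' `w = (1/3) * colSums(S)`. The gray output is `w . (R, G, B)` per pixel --
#' equivalently `(1/3) 1^T S F` reshaped to `H x W`.
#'
#' Because every row of `S` sums to one, `w` is non-negative and sums to one,
#' so the output is a convex channel combination and stays in `[0, 1]`.
#' `G`, its row means and row standard deviations all scale by `a^2` under
#' `img -> a * img`, so `Z`, `S` and `w` are invariant to global intensity
#' scaling and the operator is positively homogeneous of degree one. On an
#' achromatic image (R = G = B) all rows of `G` are constant, the `epsilon`
#' guard takes `Z` to zero, and the weights reduce to the uniform
#' `(1/3, 1/3, 1/3)`.
#'
#' @param img an [rgb_image()].
#' @param epsilon small positive guard added to each row standard deviation
#'   so that achromatic (zero-variance) rows degrade to uniform attention.
#' @return `acsrm_weights()` returns the length-3 weight vector (named R, G,
#'   B) with the attention matrix `S` and Gram matrix `G` attached as
#'   attributes `"attention"` and `"gram"`. `acsrm_convert()` returns a
#'   [gray_image()] with method `"acsrm"`.
#' @examples
#' flat <- rgb_image(array(0.4, dim = c(3, 3, 3)))
#' acsrm_weights(flat)          # uniform 1/3 weights
#' acsrm_convert(flat)[1, 1]    # 0.4
#' @export
acsrm_weights <- function(img, epsilon = 1e-8) {
  stopifnot(inherits(img, "rgb_image"))
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a small positive scalar", call. = FALSE)
  a <- as_array(img)
  if (any(!is.finite(a))) stop("non-finite pixel values", call. = FALSE)
  fm <- t(matrix(a, ncol = 3L))            # 3 x N, rows = R, G, B
  g <- tcrossprod(fm)                      # 3 x 3 Gram matrix
  mu <- rowMeans(g)
  sig <- sqrt(rowMeans((g - mu)^2))        # population sd across 3 entries
  z <- (g - mu) / (sig + epsilon)
  z <- z - apply(z, 1L, max)               # stabilized row-wise softmax
  s <- exp(z)
  s <- s / rowSums(s)
  w <- colSums(s) / 3
  names(w) <- c("R", "G", "B")
  dimnames(s) <- list(c("R", "G", "B"), c("R", "G", "B"))
  structure(w, attention = s, gram = g)
}

#' @rdname acsrm_weights
#' @export
acsrm_convert <- function(img, epsilon = 1e-8) {
  w <- acsrm_weights(img, epsilon = epsilon)
  g <- w[[1]] * channel(img, 1) + w[[2]] * channel(img, 2) +
    w[[3]] * channel(img, 3)
  out <- gray_image(pmin(pmax(g, 0), 1), method = "acsrm")
  attr(out, "weights") <- as.numeric(w)
  out
}
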
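#' Specification for a synthetic H&E phantom
#'
#' The phantom emulates the appearance contract of an H&E tile: dark
#' blue/purple elliptical nuclei scattered over pink stroma, on a near-white
#' slide background, with an optional set of "cancer" blobs in which nuclei
#' are denser. It is a statistical stand-in for histology -- sufficient for
#' exercising conversion operators, patch extraction and metrics -- not a
#' tissue renderer.
#'
#' The default palette (nuclei `(0.29, 0.20, 0.51)`, stroma
#' `(0.91, 0.63, 0.75)`, background `(0.97, 0.96, 0.97)`) was chosen to
#' satisfy the intensity ordering nuclei < stroma < background that real H&E
#' exhibits under every conversion in this package.
#'
#' @param size canvas `c(height, width)` in pixels.
#' @param n_nuclei number of nuclei in benign tissue.
#' @param nucleus_radius `c(min, max)` semi-axis range in pixels.
#' @param n_cancer_blobs number of circular cancer regions.
#' @param cancer_nuclei_factor nuclear density multiplier inside cancer
#'   blobs.
#' @param nucleus_color,stroma_color,background_color RGB triples in
#'   `[0, 1]`.
#' @param noise_sd Gaussian texture noise standard deviation (clipped to
#'   `[0, 1]` after addition).
#' @param seed integer; fixes the phantom exactly.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(256L, 256L),
                         n_nuclei = 120L,
                         nucleus_radius = c(2, 5),
                         n_cancer_blobs = 2L,
                         cancer_nuclei_factor = 2,
                         nucleus_color = c(0.29, 0.20, 0.51),
                         stroma_color = c(0.91, 0.63, 0.75),
                         background_color = c(0.97, 0.96, 0.97),
                         noise_sd = 0.02,
                         seed = 1L) {
  for (col in list(nucleus_color, stroma_color, background_color))
    if (length(col) != 3L || any(col < 0) || any(col > 1))
      stop("colors must be RGB triples in [0, 1]", call. = FALSE)
  if (max(nucleus_radius) * 2 >= min(size))
    stop("nucleus size exceeds the canvas", call. = FALSE)
  structure(list(size = as.integer(size), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 n_cancer_blobs = as.integer(n_cancer_blobs),
                 cancer_nuclei_factor = cancer_nuclei_factor,
                 nucleus_color = nucleus_color, stroma_color = stroma_color,
                 background_color = background_color, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic H&E phantom with its ground-truth mask
#'
#' Draws an elliptical tissue region (benign, label 1) on a white background
#' (label 0), stamps circular cancer blobs (label 2) inside it, scatters
#' elliptical nuclei (denser inside cancer blobs), adds Gaussian texture
#' noise and clips to `[0, 1]`. Deterministic for a given spec: the seed is
#' applied to R's Mersenne-Twister generator at entry.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` ([rgb_image()]), `mask` ([label_mask()]) and
#'   `nuclei` (logical matrix marking nucleus pixels, for appearance
#'   audits).
#' @examples
#' ph <- generate_phantom(phantom_spec(size = c(96, 96), seed = 7))
#' mean(intensity(ph$image)[ph$nuclei]) <
#'   mean(intensity(ph$image)[unclass(ph$mask) == 1 & !ph$nuclei])
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  h <- spec$size[1L]; w <- spec$size[2L]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)

  # tissue = centered ellipse covering most of the canvas
  tissue <- ((rr - (h + 1) / 2) / (0.45 * h))^2 +
    ((cc - (w + 1) / 2) / (0.45 * w))^2 <= 1
  mask <- matrix(0L, h, w)
  mask[tissue] <- 1L

  # cancer blobs: circles with centers well inside the tissue
  if (spec$n_cancer_blobs > 0L) {
    for (i in seq_len(spec$n_cancer_blobs)) {
      cen <- c(runif(1, 0.3, 0.7) * h, runif(1, 0.3, 0.7) * w)
      rad <- runif(1, 0.10, 0.16) * min(h, w)
      blob <- (rr - cen[1])^2 + (cc - cen[2])^2 <= rad^2
      mask[blob & tissue] <- 2L
    }
  }

  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(spec$background_color[ch], h, w)
    plane[mask == 1L] <- spec$stroma_color[ch]
    # cancer stroma: stroma tinted toward the nuclear purple
    plane[mask == 2L] <- 0.8 * spec$stroma_color[ch] +
      0.2 * spec$nucleus_color[ch]
    img[, , ch] <- plane
  }

  # nuclei: random ellipses, denser in cancer blobs
  nuclei <- matrix(FALSE, h, w)
  n_cancer_extra <- if (any(mask == 2L))
    as.integer(round(spec$n_nuclei * (spec$cancer_nuclei_factor - 1) *
                       sum(mask == 2L) / max(1L, sum(mask > 0L)))) else 0L
  n_total <- spec$n_nuclei + n_cancer_extra
  inside <- which(mask > 0L)
  in_cancer <- which(mask == 2L)
  if (n_total > 0L && length(inside) > 0L) {
    for (i in seq_len(n_total)) {
      pool <- if (i > spec$n_nuclei && length(in_cancer) > 0L) in_cancer
              else inside
      cen_idx <- pool[sample.int(length(pool), 1L)]
      cen <- c((cen_idx - 1L) %% h + 1L, (cen_idx - 1L) %/% h + 1L)
      ax <- runif(2, spec$nucleus_radius[1], spec$nucleus_radius[2])
      th <- runif(1, 0, pi)
      # bounding window around the nucleus
      ext <- ceiling(max(ax))
      r0 <- max(1L, cen[1] - ext); r1 <- min(h, cen[1] + ext)
      c0 <- max(1L, cen[2] - ext); c1 <- min(w, cen[2] + ext)
      wr <- rr[r0:r1, c0:c1] - cen[1]; wc <- cc[r0:r1, c0:c1] - cen[2]
      u <- cos(th) * wr + sin(th) * wc
      v <- -sin(th) * wr + cos(th) * wc
      hit <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
      sub <- nuclei[r0:r1, c0:c1]
      sub[hit & mask[r0:r1, c0:c1] > 0L] <- TRUE
      nuclei[r0:r1, c0:c1] <- sub
    }
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[nuclei] <- spec$nucleus_color[ch]
    img[, , ch] <- plane
  }

  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  img[] <- pmin(pmax(img, 0), 1)
  list(image = rgb_image(img), mask = label_mask(mask), nuclei = nuclei)
}

#' Simulated scanner/center color shift
#'
#' Models cross-domain color variation as a channel-wise affine perturbation
#' plus an optional hue rotation: `out = clip(gain * rotate_hue(img, angle)
#' + bias)`. The identity shift (unit gains, zero biases, zero angle) returns
#' the input bit-exactly. Hue rotation is performed in the
#' hue-saturation-value (HSV) parameterization: hue is shifted modulo one
#' full turn with saturation and value untouched.
#'
#' @param gain positive per-channel multipliers (length 3).
#' @param bias per-channel offsets (length 3).
#' @param hue_rotation rotation angle in degrees.
#' @return `domain_shift()` returns a `domain_shift` object;
#'   `apply_domain_shift()` returns a shifted [rgb_image()].
#' @export
domain_shift <- function(gain = c(1, 1, 1), bias = c(0, 0, 0),
                         hue_rotation = 0) {
  if (length(gain) != 3L || any(!is.finite(gain)) || any(gain <= 0))
    stop("'gain' must be three positive values", call. = FALSE)
  if (length(bias) != 3L || any(!is.finite(bias)))
    stop("'bias' must be three finite values", call. = FALSE)
  structure(list(gain = gain, bias = bias, hue_rotation = hue_rotation),
            class = "domain_shift")
}

#' @rdname domain_shift
#' @param img an [rgb_image()].
#' @param shift a `domain_shift` object.
#' @export
apply_domain_shift <- function(img, shift) {
  stopifnot(inherits(img, "rgb_image"), inherits(shift, "domain_shift"))
  if (all(shift$gain == 1) && all(shift$bias == 0) &&
      shift$hue_rotation %% 360 == 0)
    return(img)
  a <- as_array(img)
  if (shift$hue_rotation %% 360 != 0) {
    d <- dim(a)
    flat <- t(matrix(a, ncol = 3L))  # 3 x N in [0, 1]
    hsv <- grDevices::rgb2hsv(flat, maxColorValue = 1)
    hsv[1L, ] <- (hsv[1L, ] + shift$hue_rotation / 360) %% 1
    a <- array(t(hsv_to_rgb(hsv)), dim = d)
  }
  for (ch in 1:3)
    a[, , ch] <- shift$gain[ch] * a[, , ch] + shift$bias[ch]
  a[] <- pmin(pmax(a, 0), 1)
  rgb_image(a, source_depth = attr(img, "source_depth"))
}

# vectorized HSV -> RGB (h, s, v rows in [0, 1]); returns 3 x N matrix
hsv_to_rgb <- function(hsv) {
  h <- hsv[1L, ] * 6; s <- hsv[2L, ]; v <- hsv[3L, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Simulate correlated paired correct/incorrect outcomes
#'
#' Builds fixtures for McNemar-type comparisons: two binary outcome vectors
#' with prescribed marginal accuracies and a prescribed agreement rate
#' (probability the two models agree, i.e. both correct or both wrong). The
#' joint cell probabilities follow from the marginals and agreement:
#' `P(both correct) = (agreement - 1 + acc_a + acc_b) / 2`, and the
#' remaining cells by subtraction. The triple is feasible iff
#' `|1 - acc_a - acc_b| <= agreement <= 1 - |acc_a - acc_b|`.
#'
#' @param n number of samples.
#' @param acc_a,acc_b marginal accuracies in `[0, 1]`.
#' @param agreement probability the models agree.
#' @param seed integer seed.
#' @return A list with outcome vectors `a` and `b` (0/1) and the solved
#'   joint `probs` (`p11`, `p10`, `p01`, `p00`).
#' @export
simulate_paired_outcomes <- function(n, acc_a, acc_b, agreement, seed = 1L) {
  p11 <- (agreement - 1 + acc_a + acc_b) / 2
  probs <- c(p11 = p11, p10 = acc_a - p11, p01 = acc_b - p11,
             p00 = 1 - acc_a - acc_b + p11)
  if (any(probs < -1e-9)) {
    lo <- abs(1 - acc_a - acc_b); hi <- 1 - abs(acc_a - acc_b)
    stop(sprintf(paste0("infeasible (acc_a, acc_b, agreement) triple; ",
                        "feasible agreement interval is [%.4f, %.4f]"),
                 lo, hi), call. = FALSE)
  }
  probs <- pmax(probs, 0)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  cell <- sample.int(4L, n, replace = TRUE, prob = probs)
  list(a = as.integer(cell %in% c(1L, 2L)), b = as.integer(cell %in% c(1L, 3L)),
       probs = probs)
}

#' Simulate paired per-sample IoU scores
#'
#' Fixtures for the Wilcoxon signed-rank test: baseline scores
#' `a_i ~ U(0.35, 0.8)` (the working range of competent segmentation models)
#' and `b_i = clip(a_i + shift_effect + e_i)` with Gaussian noise
#' `e_i ~ N(0, noise)`. With `shift_effect = 0` the paired test is calibrated
#' (rejects at the nominal 5% rate); large `shift_effect / noise` drives
#' power toward 1.
#'
#' @param n number of pairs.
#' @param shift_effect systematic score difference added to the second
#'   model.
#' @param noise standard deviation (> 0) of the pair noise.
#' @param seed integer seed.
#' @return A data frame with columns `a` and `b` (class `paired_scores`).
#' @export
simulate_paired_ious <- function(n, shift_effect = 0, noise = 0.05,
                                 seed = 1L) {
  if (!is.finite(noise) || noise <= 0)
    stop("'noise' must be positive", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  a <- runif(n, 0.35, 0.8)
  b <- pmin(pmax(a + shift_effect + rnorm(n, 0, noise), 0), 1)
  structure(data.frame(a = a, b = b), class = c("paired_scores",
                                                "data.frame"))
}
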
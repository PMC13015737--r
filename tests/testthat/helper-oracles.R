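# Shared fixtures and independent oracles. Every oracle here is written as
# plain scalar loops / enumeration, deliberately avoiding the vectorized
# code paths it is used to check.

random_rgb <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), dim = c(h, w, 3)))
}

# per-pixel scalar-loop grayscale oracle
loop_convert <- function(img, method) {
  a <- unclass(img)
  h <- dim(a)[1]; w <- dim(a)[2]
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- a[i, j, 1]; g <- a[i, j, 2]; b <- a[i, j, 3]
    out[i, j] <- switch(method,
      intensity = (r + g + b) / 3,
      luster = (max(c(r, g, b)) + min(c(r, g, b))) / 2,
      luminosity = 0.21 * r + 0.72 * g + 0.07 * b,
      luminance = 0.3 * r + 0.59 * g + 0.11 * b)
  }
  out
}

# step-by-step scalar ACSRM oracle: explicit loops for G, Z, S, w, output
loop_acsrm <- function(img, epsilon = 1e-8) {
  a <- unclass(img)
  n <- dim(a)[1] * dim(a)[2]
  f <- matrix(NA_real_, 3, n)
  for (ch in 1:3) f[ch, ] <- as.vector(a[, , ch])
  g <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in seq_len(n)) acc <- acc + f[i, k] * f[j, k]
    g[i, j] <- acc
  }
  z <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    mu <- (g[i, 1] + g[i, 2] + g[i, 3]) / 3
    sig <- sqrt(((g[i, 1] - mu)^2 + (g[i, 2] - mu)^2 + (g[i, 3] - mu)^2) / 3)
    for (j in 1:3) z[i, j] <- (g[i, j] - mu) / (sig + epsilon)
  }
  s <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    mx <- max(z[i, ])
    e <- exp(z[i, ] - mx)
    s[i, ] <- e / sum(e)
  }
  w <- numeric(3)
  for (j in 1:3) w[j] <- (s[1, j] + s[2, j] + s[3, j]) / 3
  gray <- matrix(NA_real_, dim(a)[1], dim(a)[2])
  for (k in seq_len(n)) {
    gray[k] <- w[1] * f[1, k] + w[2] * f[2, k] + w[3] * f[3, k]
  }
  list(G = g, Z = z, S = s, w = w, gray = gray)
}

# O(n^2) concordant-pair AUC oracle
pair_auc <- function(scores, labels) {
  pos <- which(as.logical(labels)); neg <- which(!as.logical(labels))
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# exact two-tailed McNemar by explicit binomial enumeration
enum_mcnemar <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  k <- min(b, cc)
  mass <- 0
  for (x in 0:k) mass <- mass + choose(n, x) * 0.5^n
  min(1, 2 * mass)
}

# exact two-tailed Wilcoxon by explicit enumeration of all 2^m sign patterns
enum_wilcoxon <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  tot <- sum(r)
  wlow <- min(wplus, tot - wplus)
  whigh <- tot - wlow
  count <- 0
  for (bits in 0:(2^m - 1)) {
    signs <- as.integer(intToBits(bits))[1:m]
    wp <- sum(r[signs == 1])
    if (wp <= wlow + 1e-9 || wp >= whigh - 1e-9) count <- count + 1
  }
  min(1, count / 2^m)
}

# brute-force enumeration of eligible top-left positions: re-derives the
# composition of every window by direct pixel counting (no summed-area
# shortcut), then applies the eligibility rules scalar-wise
enum_eligible <- function(mask, crit) {
  s <- crit$patch_size
  d <- dim(mask)
  out <- list()
  for (r in 0:(d[1] - s)) for (cc in 0:(d[2] - s)) {
    fr <- count_composition(mask, c(r, cc), s)
    cls <- "none"
    if (fr[1] < crit$max_background_fraction) {
      if (fr[3] >= crit$cancer_min_cancer_fraction) cls <- "cancer"
      else if (fr[3] < crit$noncancer_max_cancer_fraction &&
                 fr[2] >= crit$noncancer_min_benign_fraction)
        cls <- "non-cancer"
    }
    if (cls != "none")
      out[[length(out) + 1L]] <- data.frame(r = r, c = cc, class = cls)
  }
  if (length(out) == 0) return(data.frame(r = integer(), c = integer(),
                                          class = character()))
  do.call(rbind, out)
}

# exact maximum number of pairwise-disjoint S-windows whose top-left corners
# fill a complete rectangle [rmin, rmax] x [cmin, cmax] of positions. For
# such sets the maximum is (floor((rmax-rmin)/S)+1) * (floor((cmax-cmin)/S)+1):
# achieved by an S-strided grid, and matched from above by a piercing
# argument (points spaced S apart hit every window exactly once per axis).
max_disjoint <- function(pos, s) {
  n <- nrow(pos)
  if (n == 0) return(0L)
  rr <- range(pos$r); cr <- range(pos$c)
  full <- (diff(rr) + 1) * (diff(cr) + 1)
  stopifnot("oracle needs a complete rectangle of positions" = n == full)
  as.integer((floor(diff(rr) / s) + 1) * (floor(diff(cr) / s) + 1))
}

# brute-force per-window composition by pixel counting
count_composition <- function(mask, origin, s) {
  m <- unclass(mask)
  counts <- c(0, 0, 0)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    lbl <- m[origin[1] + i, origin[2] + j]
    counts[lbl + 1] <- counts[lbl + 1] + 1
  }
  counts / s^2
}

# exhaustive 256-threshold Otsu search maximizing between-class variance
search_otsu <- function(gray, levels = 256) {
  v <- as.vector(unclass(gray))
  bins <- pmin(floor(v * levels), levels - 1)
  h <- tabulate(bins + 1, nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf; best_t <- NA
  for (t in 1:(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t / levels }
  }
  best_t
}
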
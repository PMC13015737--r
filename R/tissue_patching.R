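#' Otsu threshold of a gray image
#'
#' Returns the threshold in `[0, 1]` that maximizes the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2` over a 256-bin histogram, splitting
#' the bins exclusively into a lower and an upper class. The returned value
#' is the upper edge of the last lower-class bin, so `pixel < threshold`
#' selects the dark class. Used to separate (dark) tissue from the
#' (near-white) slide background. On a plateau of equally optimal splits the
#' lowest is returned.
#'
#' @param gray a [gray_image()] or numeric matrix in `[0, 1]`.
#' @param levels number of histogram bins.
#' @return Threshold value in `(0, 1)`.
#' @export
otsu_threshold <- function(gray, levels = 256L) {
  m <- as_array(gray)
  check_unit_range(m)
  v <- as.vector(m)
  if (length(unique(v)) < 2L)
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  bins <- pmin(floor(v * levels), levels - 1L)
  counts <- tabulate(bins + 1L, nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(counts)
  n <- w0[levels]
  m0 <- cumsum(counts * mids)
  t_idx <- seq_len(levels - 1L)
  w1 <- n - w0[t_idx]
  valid <- w0[t_idx] > 0 & w1 > 0
  mu0 <- m0[t_idx] / w0[t_idx]
  mu1 <- (m0[levels] - m0[t_idx]) / w1
  bcv <- ifelse(valid, w0[t_idx] * w1 * (mu0 - mu1)^2, -Inf)
  which.max(bcv) / levels
}

#' Localize tissue regions on a slide image
#'
#' H&E tissue is darker than the white slide background, so foreground is
#' taken as the darker-than-Otsu side of the intensity-converted image. The
#' binary map is cleaned by morphological closing and hole filling, small
#' components are dropped, and one bounding box is returned per remaining
#' 8-connected component.
#'
#' @param img an [rgb_image()].
#' @param min_area minimum component area in pixels; defaults to 0.1% of the
#'   image area.
#' @param closing_radius radius (pixels) of the disc structuring element for
#'   morphological closing; `0` skips closing.
#' @return A list with `boxes` (data frame: `component`, `rmin`, `rmax`,
#'   `cmin`, `cmax`, `area`; 0-based inclusive pixel coordinates) and `mask`
#'   (logical tissue map). An image with no surviving foreground yields zero
#'   boxes, not an error.
#' @export
localize_tissue <- function(img, min_area = NULL, closing_radius = 5) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)[1:2]
  if (is.null(min_area)) min_area <- ceiling(0.001 * prod(d))
  g <- as_array(intensity(img))
  if (length(unique(as.vector(g))) < 2L) {
    return(list(boxes = empty_boxes(), mask = matrix(FALSE, d[1], d[2])))
  }
  fg <- g < otsu_threshold(g)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L,
                                shape = "disc")
    fg <- EBImage::imageData(EBImage::closing(EBImage::Image(fg * 1),
                                              brush)) > 0.5
  }
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0.5
  lab <- label_components8(fg)
  n <- max(lab)
  if (n == 0L) {
    message("localize_tissue: no foreground component survived")
    return(list(boxes = empty_boxes(), mask = fg & FALSE))
  }
  keep <- which(tabulate(lab[lab > 0L], nbins = n) >= min_area)
  if (length(keep) == 0L) {
    message("localize_tissue: no component reached min_area = ", min_area)
    return(list(boxes = empty_boxes(), mask = fg & FALSE))
  }
  boxes <- do.call(rbind, lapply(seq_along(keep), function(i) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    data.frame(component = i,
               rmin = min(idx[, 1]) - 1L, rmax = max(idx[, 1]) - 1L,
               cmin = min(idx[, 2]) - 1L, cmax = max(idx[, 2]) - 1L,
               area = nrow(idx))
  }))
  mask <- lab %in% keep
  dim(mask) <- d
  list(boxes = boxes, mask = mask)
}

empty_boxes <- function() {
  data.frame(component = integer(), rmin = integer(), rmax = integer(),
             cmin = integer(), cmax = integer(), area = integer())
}

# 8-connected component labeling by iterative minimum-label propagation.
# (EBImage::bwlabel is 4-connected, which splits diagonally touching tissue.)
label_components8 <- function(fg) {
  d <- dim(fg)
  lab <- matrix(0L, d[1], d[2])
  lab[fg] <- seq_len(sum(fg))
  if (max(lab) == 0L) return(lab)
  pad <- function(m) {
    out <- matrix(.Machine$integer.max, d[1] + 2L, d[2] + 2L)
    out[2:(d[1] + 1L), 2:(d[2] + 1L)] <- ifelse(m == 0L,
                                                .Machine$integer.max, m)
    out
  }
  repeat {
    p <- pad(lab)
    best <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- p[(2:(d[1] + 1L)) + dr, (2:(d[2] + 1L)) + dc, drop = FALSE]
      best <- pmin(best, ifelse(fg & nb != .Machine$integer.max, nb, best))
    }
    best[!fg] <- 0L
    if (identical(best, lab)) break
    lab <- best
  }
  # relabel 1..n
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Patch eligibility criteria
#'
#' Bundles the class-aware area rules used for conditional patch extraction.
#' A candidate window is first screened on background (`background fraction <
#' max_background_fraction`, strict); if it passes, it is *cancer*-eligible
#' when its cancer fraction is `>= cancer_min_cancer_fraction` (inclusive),
#' otherwise *non-cancer*-eligible when its cancer fraction is `<
#' noncancer_max_cancer_fraction` (strict) **and** its benign fraction is
#' `>= noncancer_min_benign_fraction` (inclusive); otherwise it is
#' ineligible.
#'
#' Two presets mirror the published extraction rules:
#' * `panda_criteria()`: background < 50%; non-cancer: cancer < 30% and
#'   benign >= 50%; cancer: cancer >= 30%; target 10 patches per class.
#' * `camelyon16_criteria()`: background < 70%; non-cancer: cancer < 20% and
#'   normal tissue >= 30%; targets 10 non-cancer and 30 cancer patches.
#'
#' @param patch_size square patch side in pixels.
#' @param max_background_fraction strict upper bound on background area.
#' @param noncancer_max_cancer_fraction strict upper bound on cancer area for
#'   non-cancer patches.
#' @param noncancer_min_benign_fraction inclusive lower bound on benign area
#'   for non-cancer patches.
#' @param cancer_min_cancer_fraction inclusive lower bound on cancer area for
#'   cancer patches.
#' @param targets_per_class named integer vector
#'   `c(noncancer = ..., cancer = ...)`.
#' @return A `patch_criteria` object.
#' @export
patch_criteria <- function(patch_size = 224,
                           max_background_fraction = 0.5,
                           noncancer_max_cancer_fraction = 0.3,
                           noncancer_min_benign_fraction = 0.5,
                           cancer_min_cancer_fraction = 0.3,
                           targets_per_class = c(noncancer = 10L,
                                                 cancer = 10L)) {
  fr <- c(max_background_fraction, noncancer_max_cancer_fraction,
          noncancer_min_benign_fraction, cancer_min_cancer_fraction)
  if (any(fr < 0) || any(fr > 1))
    stop("all area fractions must lie in [0, 1]", call. = FALSE)
  if (patch_size < 1) stop("patch_size must be >= 1", call. = FALSE)
  if (!all(c("noncancer", "cancer") %in% names(targets_per_class)) ||
      any(targets_per_class < 1))
    stop("targets_per_class needs positive 'noncancer' and 'cancer' entries",
         call. = FALSE)
  structure(list(patch_size = as.integer(patch_size),
                 max_background_fraction = max_background_fraction,
                 noncancer_max_cancer_fraction = noncancer_max_cancer_fraction,
                 noncancer_min_benign_fraction = noncancer_min_benign_fraction,
                 cancer_min_cancer_fraction = cancer_min_cancer_fraction,
                 targets_per_class = targets_per_class),
            class = "patch_criteria")
}

#' @rdname patch_criteria
#' @export
panda_criteria <- function(patch_size = 224) {
  patch_criteria(patch_size = patch_size,
                 max_background_fraction = 0.5,
                 noncancer_max_cancer_fraction = 0.3,
                 noncancer_min_benign_fraction = 0.5,
                 cancer_min_cancer_fraction = 0.3,
                 targets_per_class = c(noncancer = 10L, cancer = 10L))
}

#' @rdname patch_criteria
#' @export
camelyon16_criteria <- function(patch_size = 224) {
  patch_criteria(patch_size = patch_size,
                 max_background_fraction = 0.7,
                 noncancer_max_cancer_fraction = 0.2,
                 noncancer_min_benign_fraction = 0.3,
                 cancer_min_cancer_fraction = 0.3,
                 targets_per_class = c(noncancer = 10L, cancer = 30L))
}

#' Per-class area fractions of a mask window
#'
#' @param mask a [label_mask()].
#' @param origin 0-based `c(row, col)` of the window's top-left corner; the
#'   window is half-open, covering rows `origin[1] .. origin[1] +
#'   patch_size - 1`.
#' @param patch_size square window side in pixels.
#' @return Named fractions `c(background, benign, cancer)` summing to 1.
#' @export
patch_composition <- function(mask, origin, patch_size) {
  d <- dim(mask)
  r <- origin[1L]; cc <- origin[2L]
  if (r < 0 || cc < 0 || r + patch_size > d[1] || cc + patch_size > d[2])
    stop("window out of bounds", call. = FALSE)
  win <- unclass(mask)[(r + 1L):(r + patch_size), (cc + 1L):(cc + patch_size)]
  counts <- tabulate(as.integer(win) + 1L, nbins = 3L)
  stats::setNames(counts / (patch_size^2), c("background", "benign", "cancer"))
}

#' Classify a window's eligibility under patch criteria
#'
#' @param fractions named fractions from [patch_composition()].
#' @param criteria a [patch_criteria()] object.
#' @return `"cancer"`, `"non-cancer"` or `"none"`.
#' @export
eligible_class <- function(fractions, criteria) {
  stopifnot(inherits(criteria, "patch_criteria"))
  bg <- fractions[["background"]]; be <- fractions[["benign"]]
  ca <- fractions[["cancer"]]
  if (!(bg < criteria$max_background_fraction)) return("none")
  if (ca >= criteria$cancer_min_cancer_fraction) return("cancer")
  if (ca < criteria$noncancer_max_cancer_fraction &&
      be >= criteria$noncancer_min_benign_fraction) return("non-cancer")
  "none"
}

#' Conditional class-aware patch extraction
#'
#' Attempts to extract `targets_per_class` eligible, pairwise non-overlapping
#' square patches per class from an image/mask pair. All candidate top-left
#' positions are enumerated (window compositions come from per-class
#' summed-area tables, so eligibility is exact, not sampled); cancer patches
#' are placed first, then non-cancer ones, each phase avoiding every patch
#' already placed. Placement order is a seeded random permutation of the
#' eligible positions with greedy rejection of overlaps; if that falls short
#' of the target, a deterministic row-major repacking pass recovers a maximal
#' disjoint set, which realizes the iteratively reduced target. Only when a
#' class yields *zero* non-overlapping patches (e.g. every eligible window is
#' blocked by the other class) is the non-overlap constraint lifted:
#' overlapping -- but still eligible -- patches are drawn and flagged
#' `overlap_allowed`. Identical inputs and seed give identical output.
#'
#' @param img an [rgb_image()] aligned with `mask` (may be `NULL` to extract
#'   coordinates only).
#' @param mask a [label_mask()].
#' @param criteria a [patch_criteria()] object.
#' @param seed integer seed controlling placement order.
#' @return A list of `patch_record` objects, each with fields `pixels` (or
#'   `NULL`), `label`, `origin` (0-based `c(row, col)`), `overlap_allowed`
#'   and `fractions`. Every record satisfies [eligible_class()] for its
#'   label; the composition of each returned window is re-audited against
#'   the mask before returning.
#' @export
extract_patches <- function(img, mask, criteria, seed = 1L) {
  stopifnot(inherits(mask, "label_mask"), inherits(criteria, "patch_criteria"))
  if (!is.null(img)) {
    stopifnot(inherits(img, "rgb_image"))
    if (!all(dim(img)[1:2] == dim(mask)))
      stop("image and mask dimensions differ", call. = FALSE)
  }
  s <- criteria$patch_size
  d <- dim(mask)
  if (s > min(d)) stop("patch does not fit in the image", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  elig <- eligible_positions(mask, criteria)
  kept <- list()
  class_order <- c("cancer", "non-cancer")
  present <- c(cancer = any(unclass(mask) == 2L),
               `non-cancer` = any(unclass(mask) == 1L))
  for (cls in class_order) {
    if (!present[[cls]]) next
    pos <- elig[elig$class == cls, , drop = FALSE]
    if (nrow(pos) == 0L) {
      warning("no eligible location for class '", cls, "'")
      next
    }
    target <- criteria$targets_per_class[[
      if (cls == "cancer") "cancer" else "noncancer"]]
    picked <- place_disjoint(pos, kept, s, target)
    if (nrow(picked) == 0L) {
      # non-overlap phase exhausted (target reduced to zero): permit overlap
      take <- head(sample.int(nrow(pos)), target)
      picked <- pos[take, , drop = FALSE]
      picked$overlap <- TRUE
    } else {
      picked$overlap <- FALSE
    }
    for (i in seq_len(nrow(picked))) {
      kept[[length(kept) + 1L]] <- make_patch_record(
        img, mask, cls, c(picked$r[i], picked$c[i]), s, picked$overlap[i],
        criteria)
    }
  }
  kept
}

# enumerate eligible top-left positions (0-based) with summed-area tables
eligible_positions <- function(mask, criteria) {
  s <- criteria$patch_size
  d <- dim(mask)
  m <- unclass(mask)
  sat_for <- function(lbl) {
    ind <- matrix(0, d[1] + 1L, d[2] + 1L)
    ind[-1L, -1L] <- (m == lbl) * 1
    t(apply(apply(ind, 2L, cumsum), 1L, cumsum))
  }
  sat0 <- sat_for(0L); sat1 <- sat_for(1L); sat2 <- sat_for(2L)
  nr <- d[1] - s + 1L; nc <- d[2] - s + 1L
  r <- rep(seq_len(nr), times = nc); cc <- rep(seq_len(nc), each = nr)
  wsum <- function(sat) {
    sat[cbind(r + s, cc + s)] - sat[cbind(r, cc + s)] -
      sat[cbind(r + s, cc)] + sat[cbind(r, cc)]
  }
  tot <- s^2
  fbg <- wsum(sat0) / tot; fbe <- wsum(sat1) / tot; fca <- wsum(sat2) / tot
  pass_bg <- fbg < criteria$max_background_fraction
  is_cancer <- pass_bg & (fca >= criteria$cancer_min_cancer_fraction)
  is_nc <- pass_bg & !is_cancer &
    (fca < criteria$noncancer_max_cancer_fraction) &
    (fbe >= criteria$noncancer_min_benign_fraction)
  cls <- rep(NA_character_, length(r))
  cls[is_cancer] <- "cancer"; cls[is_nc] <- "non-cancer"
  keep <- !is.na(cls)
  data.frame(r = r[keep] - 1L, c = cc[keep] - 1L, class = cls[keep],
             stringsAsFactors = FALSE)
}

# greedy disjoint placement: seeded random order first, row-major repack if
# the random order falls short of the target
place_disjoint <- function(pos, kept, s, target) {
  blocked <- vapply(kept, function(p) p$origin, numeric(2))
  disjoint <- function(r1, c1, rs, cs) {
    if (length(rs) == 0L) return(TRUE)
    all(r1 + s <= rs | rs + s <= r1 | c1 + s <= cs | cs + s <= c1)
  }
  greedy <- function(order) {
    rs <- if (length(blocked)) blocked[1L, ] else numeric()
    cs <- if (length(blocked)) blocked[2L, ] else numeric()
    take <- integer()
    for (i in order) {
      if (disjoint(pos$r[i], pos$c[i], rs, cs)) {
        take <- c(take, i)
        rs <- c(rs, pos$r[i]); cs <- c(cs, pos$c[i])
        if (length(take) >= target) break
      }
    }
    take
  }
  take <- greedy(sample.int(nrow(pos)))
  if (length(take) < target) {
    det <- greedy(order(pos$r, pos$c))
    if (length(det) > length(take)) take <- det
  }
  pos[take, , drop = FALSE]
}

make_patch_record <- function(img, mask, cls, origin, s, overlap, criteria) {
  fr <- patch_composition(mask, origin, s)
  if (eligible_class(fr, criteria) != cls)
    stop("internal error: extracted patch fails its own eligibility audit")
  px <- NULL
  if (!is.null(img)) {
    a <- as_array(img)
    px <- a[(origin[1] + 1L):(origin[1] + s),
            (origin[2] + 1L):(origin[2] + s), , drop = FALSE]
  }
  structure(list(pixels = px, label = cls, origin = as.integer(origin),
                 overlap_allowed = overlap, fractions = fr),
            class = "patch_record")
}

#' @export
print.patch_record <- function(x, ...) {
  cat(sprintf("<patch_record %s at (%d, %d)%s>\n", x$label, x$origin[1],
              x$origin[2], if (x$overlap_allowed) ", overlap allowed" else ""))
  invisible(x)
}

#' Balance class lists by flip augmentation
#'
#' Expands minority classes by adding horizontal, vertical and combined flips
#' of each patch (at most a four-fold expansion; flips identical to an array
#' already in the class are never added, so symmetric patches contribute
#' nothing). In `"flips-then-duplicate"` mode, classes still short of the
#' majority count are topped up by seeded resampling with replacement to
#' exactly the majority count.
#'
#' @param patches named list of per-class lists of arrays (patch pixels).
#' @param mode `"flips-only"` or `"flips-then-duplicate"`.
#' @param seed seed for the duplicate top-up draw.
#' @return A list like `patches` with minority classes expanded.
#' @examples
#' # class sizes 1 and 4: the singleton grows to 4 by flips + duplication
#' p <- list(a = list(matrix(runif(16), 4, 4)),
#'           b = replicate(4, matrix(runif(16), 4, 4), simplify = FALSE))
#' lengths(balance_by_flips(p, "flips-then-duplicate"))
#' @export
balance_by_flips <- function(patches, mode = c("flips-only",
                                               "flips-then-duplicate"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (any(lengths(patches) == 0L))
    stop("every class must contain at least one patch", call. = FALSE)
  majority <- max(lengths(patches))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  out <- lapply(patches, function(cls) {
    if (length(cls) >= majority) return(cls)
    aug <- cls
    for (p in cls) {
      for (f in list(flip_h(p), flip_v(p), flip_h(flip_v(p)))) {
        if (!any(vapply(aug, identical, logical(1), y = f)))
          aug[[length(aug) + 1L]] <- f
      }
    }
    aug
  })
  if (mode == "flips-then-duplicate") {
    majority <- max(lengths(out))
    out <- lapply(out, function(cls) {
      if (length(cls) >= majority) return(cls[seq_len(majority)])
      c(cls, cls[sample.int(length(cls), majority - length(cls),
                            replace = TRUE)])
    })
  }
  out
}

flip_h <- function(x) {  # reverse columns
  if (length(dim(x)) == 2L) x[, rev(seq_len(ncol(x))), drop = FALSE]
  else x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
}

flip_v <- function(x) {  # reverse rows
  if (length(dim(x)) == 2L) x[rev(seq_len(nrow(x))), , drop = FALSE]
  else x[rev(seq_len(dim(x)[1L])), , , drop = FALSE]
}
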
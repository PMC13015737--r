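test_that("otsu threshold separates bimodal images like exhaustive search", {
  two <- gray_image(matrix(rep(c(0.2, 0.8), 50), 10, 10))
  th <- otsu_threshold(two)
  expect_gt(th, 0.2)
  expect_lt(th, 0.8)

  extreme <- gray_image(matrix(rep(c(0, 1), 32), 8, 8))
  th2 <- otsu_threshold(extreme)
  expect_gt(th2, 0)
  expect_lt(th2, 1)

  set.seed(8)
  mix <- pmin(pmax(c(rnorm(300, 0.25, 0.05), rnorm(200, 0.75, 0.07)), 0), 1)
  g <- gray_image(matrix(mix, 20, 25))
  expect_lte(abs(otsu_threshold(g) - search_otsu(g)), 1 / 256 + 1e-12)

  expect_error(otsu_threshold(gray_image(matrix(0.5, 4, 4))), "constant")
})

test_that("tissue localization finds dark components above min_area", {
  canvas <- array(0.97, dim = c(120, 120, 3))
  canvas[30:79, 40:89, ] <- 0.3   # one dark 50x50 square
  loc <- localize_tissue(rgb_image(canvas), min_area = 100,
                         closing_radius = 0)
  expect_equal(nrow(loc$boxes), 1L)
  expect_equal(unlist(loc$boxes[1, c("rmin", "rmax", "cmin", "cmax")],
                      use.names = FALSE), c(29L, 78L, 39L, 88L))
  expect_equal(loc$boxes$area, 2500L)

  # second square below min_area disappears
  canvas[100:104, 10:14, ] <- 0.3  # 25 px
  loc2 <- localize_tissue(rgb_image(canvas), min_area = 100,
                          closing_radius = 0)
  expect_equal(nrow(loc2$boxes), 1L)

  blank <- rgb_image(array(0.97, dim = c(50, 50, 3)))
  expect_equal(nrow(localize_tissue(blank)$boxes), 0L)
})

test_that("component labeling is 8-connected", {
  fg <- matrix(FALSE, 5, 5)
  fg[1, 1] <- TRUE; fg[2, 2] <- TRUE; fg[3, 3] <- TRUE  # diagonal chain
  fg[5, 5] <- TRUE                                      # isolated
  lab <- histogray:::label_components8(fg)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
})

test_that("window compositions match direct pixel counting", {
  set.seed(21)
  mask <- label_mask(matrix(sample(0:2, 400, replace = TRUE), 20, 20))
  for (i in 1:10) {
    org <- c(sample(0:12, 1), sample(0:12, 1))
    fr <- patch_composition(mask, org, 8)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_equal(unname(fr), count_composition(mask, org, 8))
  }
  expect_error(patch_composition(mask, c(15, 0), 8), "bounds")

  all_cancer <- label_mask(matrix(2L, 4, 4))
  expect_equal(unname(patch_composition(all_cancer, c(0, 0), 4)),
               c(0, 0, 1))
  half <- label_mask(rbind(matrix(0L, 2, 4), matrix(1L, 2, 4)))
  expect_equal(unname(patch_composition(half, c(0, 0), 4)),
               c(0.5, 0.5, 0))
})

test_that("eligibility rules apply strict and inclusive bounds as printed", {
  crit <- panda_criteria()
  frac <- function(bg, be, ca) c(background = bg, benign = be, cancer = ca)
  expect_equal(eligible_class(frac(0.4, 0.1, 0.5), crit), "cancer")
  expect_equal(eligible_class(frac(0.5, 0.5, 0), crit), "none")   # bg not < .5
  expect_equal(eligible_class(frac(0.2, 0.55, 0.25), crit), "non-cancer")
  # boundary: cancer exactly at 0.30 is inclusive
  expect_equal(eligible_class(frac(0.2, 0.5, 0.3), crit), "cancer")
  # boundary: benign exactly at 0.50 is inclusive; cancer 0.30 would win first
  expect_equal(eligible_class(frac(0.3, 0.5, 0.2), crit), "non-cancer")
  # cancer exactly at noncancer_max (0.3) goes to cancer branch anyway
  crit16 <- camelyon16_criteria()
  expect_equal(eligible_class(frac(0.69, 0.11, 0.2), crit16), "none")
  expect_equal(eligible_class(frac(0.5, 0.31, 0.19), crit16), "non-cancer")
  expect_equal(eligible_class(frac(0.7, 0.1, 0.2), crit16), "none")
})

test_that("extraction matches the exhaustive disjoint-packing oracle", {
  # left half cancer, right half benign; exactly two disjoint windows per
  # class exist (the published 448 x 448 / 224-patch geometry, scaled by 8
  # so the brute-force oracle stays affordable)
  mask <- label_mask(cbind(matrix(2L, 56, 28), matrix(1L, 56, 28)))
  crit <- panda_criteria(28)
  recs <- extract_patches(NULL, mask, crit, seed = 5)
  labels <- vapply(recs, `[[`, character(1), "label")
  expect_equal(sum(labels == "cancer"), 2L)
  expect_equal(sum(labels == "non-cancer"), 2L)
  expect_false(any(vapply(recs, `[[`, logical(1), "overlap_allowed")))

  # brute-force eligibility enumeration agrees with the implementation
  pos_oracle <- enum_eligible(mask, crit)
  pos <- histogray:::eligible_positions(mask, crit)
  expect_equal(pos[order(pos$r, pos$c), ],
               pos_oracle[order(pos_oracle$r, pos_oracle$c), ],
               ignore_attr = TRUE)
  expect_equal(max_disjoint(pos_oracle[pos_oracle$class == "cancer", ], 28),
               2L)
  expect_equal(max_disjoint(pos_oracle[pos_oracle$class == "non-cancer", ],
                            28), 2L)

  # pairwise disjoint
  for (i in seq_along(recs)) for (j in seq_along(recs)) {
    if (i >= j) next
    oi <- recs[[i]]$origin; oj <- recs[[j]]$origin
    expect_true(oi[1] + 28 <= oj[1] || oj[1] + 28 <= oi[1] ||
                  oi[2] + 28 <= oj[2] || oj[2] + 28 <= oi[2])
  }

  # every record satisfies its own eligibility rule on the mask
  for (rec in recs) {
    fr <- patch_composition(mask, rec$origin, 28)
    expect_equal(eligible_class(fr, crit), rec$label)
  }
})

test_that("extraction is deterministic and degrades gracefully", {
  mask <- label_mask(cbind(matrix(2L, 448, 224), matrix(1L, 448, 224)))
  crit <- panda_criteria(224)
  r1 <- extract_patches(NULL, mask, crit, seed = 9)
  r2 <- extract_patches(NULL, mask, crit, seed = 9)
  expect_identical(r1, r2)

  # all-background mask yields zero records
  bg <- label_mask(matrix(0L, 300, 300))
  expect_length(extract_patches(NULL, bg, panda_criteria(224), seed = 1), 0L)
})

test_that("overlap fallback keeps eligibility but lifts disjointness", {
  # single row of candidate positions; every non-cancer window overlaps any
  # cancer window, so the non-cancer class must fall back to overlap mode
  mask <- label_mask(cbind(matrix(2L, 224, 112), matrix(1L, 224, 168)))
  crit <- panda_criteria(224)
  recs <- extract_patches(NULL, mask, crit, seed = 4)
  labels <- vapply(recs, `[[`, character(1), "label")
  overlaps <- vapply(recs, `[[`, logical(1), "overlap_allowed")
  expect_equal(sum(labels == "cancer"), 1L)       # only one disjoint fits
  expect_false(any(overlaps[labels == "cancer"]))
  expect_equal(sum(labels == "non-cancer"), 10L)  # full target via overlap
  expect_true(all(overlaps[labels == "non-cancer"]))
  for (rec in recs) {
    expect_equal(eligible_class(patch_composition(mask, rec$origin, 224),
                                crit), rec$label)
  }
})

test_that("flip balancing expands minorities as promised", {
  set.seed(33)
  mk <- function(n) replicate(n, matrix(runif(16), 4, 4), simplify = FALSE)
  classes <- list(c0 = mk(23), c1 = mk(222), c2 = mk(52))
  flips <- balance_by_flips(classes, "flips-only")
  expect_equal(unname(lengths(flips)), c(92L, 222L, 208L))
  topped <- balance_by_flips(classes, "flips-then-duplicate", seed = 2)
  expect_equal(unname(lengths(topped)), c(222L, 222L, 222L))

  # symmetric patches contribute no flip duplicates
  sym <- matrix(0.5, 4, 4)
  out <- balance_by_flips(list(a = list(sym), b = mk(3)), "flips-only")
  expect_length(out$a, 1L)
  expect_error(balance_by_flips(list(a = list(), b = mk(2))), "at least one")
})
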
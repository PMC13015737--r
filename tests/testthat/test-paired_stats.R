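test_that("contingency tables tabulate joint outcomes", {
  same <- build_contingency(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$n10, 0); expect_equal(same$n01, 0)
  allsplit <- build_contingency(rep(1, 5), rep(0, 5))
  expect_equal(unlist(allsplit[c("n11", "n10", "n01", "n00")],
                      use.names = FALSE), c(0, 5, 0, 0))

  set.seed(6)
  a <- rbinom(30, 1, 0.7); b <- rbinom(30, 1, 0.6)
  tab <- build_contingency(a, b)
  expect_equal(tab$n11, sum(a == 1 & b == 1))
  expect_equal(tab$n00, sum(a == 0 & b == 0))
  expect_equal(attr(tab, "n"), 30)
  expect_error(build_contingency(1:3, 1:4), "length")
  expect_error(contingency_table(1, -1, 0, 0), "non-negative")
})

test_that("exact McNemar agrees with binomial enumeration and its symmetries", {
  # champion comparisons with small discordant counts
  expect_equal(mcnemar_test(contingency_table(13, 1, 11, 13),
                            variant = "exact")$p.value, enum_mcnemar(1, 11))
  expect_lt(mcnemar_test(contingency_table(13, 1, 11, 13))$p.value, 0.05)
  expect_equal(mcnemar_test(contingency_table(1, 2, 5, 14),
                            variant = "exact")$p.value, enum_mcnemar(2, 5))
  expect_gt(mcnemar_test(contingency_table(1, 2, 5, 14))$p.value, 0.05)

  for (bc in list(c(0, 7), c(3, 9), c(6, 6), c(12, 4))) {
    p <- mcnemar_test(contingency_table(0, bc[1], bc[2], 0),
                      variant = "exact")$p.value
    expect_equal(p, enum_mcnemar(bc[1], bc[2]))
    # two-tailed symmetry in (b, c)
    expect_equal(p, mcnemar_test(contingency_table(0, bc[2], bc[1], 0),
                                 variant = "exact")$p.value)
  }
  # closed form for one-sided extremes: p(0, k) = 2^(1 - k)
  for (k in 1:8)
    expect_equal(mcnemar_test(contingency_table(5, 0, k, 5),
                              variant = "exact")$p.value, min(1, 2^(1 - k)))
  # independent library cross-check of the chi-square variant
  got <- mcnemar_test(contingency_table(262, 64, 147, 61),
                      variant = "chi2-cc")
  ref <- stats::mcnemar.test(matrix(c(262, 64, 147, 61), 2), correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value)
})

test_that("chi-square variant clamps at b = c and auto switches at 25", {
  eq <- mcnemar_test(contingency_table(10, 7, 7, 10), variant = "chi2-cc")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  none <- mcnemar_test(contingency_table(20, 0, 0, 5))
  expect_true(none$no_discordance)
  expect_equal(none$p.value, 1)
  expect_equal(mcnemar_test(contingency_table(0, 12, 12, 0))$variant,
               "exact")      # b + c = 24 < 25
  expect_equal(mcnemar_test(contingency_table(0, 13, 12, 0))$variant,
               "chi2-cc")    # b + c = 25
})

test_that("exact Wilcoxon equals full sign-pattern enumeration", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), rep(1, 5), mode = "exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 2 / 32)

  set.seed(12)
  for (i in 1:6) {
    m <- sample(5:12, 1)
    a <- runif(m); b <- runif(m)
    if (i %% 2 == 0) a <- round(a, 1)  # force ties in |d|
    got <- wilcoxon_signed_rank(a, b, mode = "exact")
    expect_equal(got$p.value, enum_wilcoxon(a - b), tolerance = 1e-12)
  }
  # independent library cross-check (tie-free case has a reference exact p)
  a <- c(0.31, 0.27, 0.88, 0.41, 0.60, 0.15, 0.74, 0.52)
  b <- c(0.26, 0.34, 0.70, 0.45, 0.51, 0.23, 0.60, 0.49)
  expect_equal(wilcoxon_signed_rank(a, b, mode = "exact")$p.value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})

test_that("normal mode, zero policies and degenerate inputs behave", {
  x <- c(1, 2, 3); expect_equal(wilcoxon_signed_rank(x, x)$p.value, 1)
  expect_true(wilcoxon_signed_rank(x, x)$no_signal)

  set.seed(3)
  a <- runif(40); b <- a + rnorm(40, 0.05, 0.1)
  norm <- wilcoxon_signed_rank(a, b, mode = "normal")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(norm$p.value, ref$p.value, tolerance = 1e-9)

  withz <- c(0.5, 0.6, 0.7, 0.8); basez <- c(0.5, 0.4, 0.5, 0.6)
  disc <- wilcoxon_signed_rank(withz, basez, zero_policy = "discard",
                               mode = "exact")
  expect_equal(disc$m, 3L)
  pratt <- wilcoxon_signed_rank(withz, basez, zero_policy = "pratt",
                                mode = "exact")
  expect_equal(pratt$m, 3L)
  expect_gte(pratt$p.value, disc$p.value)  # zero rank inflates the null
})

test_that("significance matrix applies a strict alpha and counts cells", {
  p <- matrix(c(0.01, 0.05, 0.9, 0.049), 2)
  sig <- significance_matrix(p)
  expect_equal(as.vector(sig), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(sig, "n_significant"), 2L)
  expect_equal(attr(significance_matrix(rep(1, 4)), "n_significant"), 0L)
  # optional Holm correction is stricter than per-comparison calls
  ph <- c(0.01, 0.04, 0.2)
  expect_equal(attr(significance_matrix(ph), "n_significant"), 2L)
  expect_equal(attr(significance_matrix(ph, adjust = "holm"),
                    "n_significant"), 1L)

  # the three cross-scanner Luster/ResNet50 class comparisons: 2 of 3
  tab <- reference_mcnemar_tables()
  luster <- tab[tab$grayscale == "Luster" & tab$architecture == "ResNet50", ]
  ps <- vapply(seq_len(nrow(luster)), function(i)
    mcnemar_test(contingency_table(luster$n11[i], luster$n10[i],
                                   luster$n01[i], luster$n00[i]))$p.value,
    numeric(1))
  expect_equal(attr(significance_matrix(ps), "n_significant"), 2L)
})
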
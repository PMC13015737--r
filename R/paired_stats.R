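#' Paired-outcome contingency table for two models
#'
#' Two classifiers evaluated on the same samples reduce to a 2x2 table of
#' joint correct/incorrect outcomes; McNemar's test is driven by its
#' discordant cells.
#'
#' @param n11 both models correct.
#' @param n10 only model A correct.
#' @param n01 only model B correct.
#' @param n00 both models incorrect.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  structure(as.list(cells), n = sum(cells), class = "contingency_table")
}

#' @rdname contingency_table
#' @param outcomes_a,outcomes_b equal-length binary vectors
#'   (correct = 1/TRUE).
#' @export
build_contingency <- function(outcomes_a, outcomes_b) {
  if (length(outcomes_a) != length(outcomes_b))
    stop("outcome vectors differ in length", call. = FALSE)
  a <- as.logical(outcomes_a); b <- as.logical(outcomes_b)
  contingency_table(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(paste0("<contingency_table n = %d: both correct %d, ",
                     "only A %d, only B %d, both incorrect %d>\n"),
              attr(x, "n"), x$n11, x$n10, x$n01, x$n00))
  invisible(x)
}

#' Two-tailed McNemar test for paired classifiers
#'
#' Tests marginal homogeneity of two classifiers evaluated on the same test
#' set, using only the discordant counts `b = n10` and `c = n01`.
#'
#' * `"exact"`: two-tailed binomial test of `b` successes in `b + c` trials
#'   at success probability 1/2: `p = min(1, 2 * P(X <= min(b, c)))`.
#' * `"chi2-cc"`: continuity-corrected chi-square statistic
#'   `(|b - c| - 1)^2 / (b + c)` (0 when `b = c`), with the p-value from the
#'   chi-square distribution on 1 degree of freedom.
#' * `"auto"` (default): exact when `b + c < 25`, else `chi2-cc`.
#'
#' With no discordant pairs (`b + c = 0`) the test carries no information:
#' `p = 1` with flag `no_discordance`.
#'
#' @param table a [contingency_table()], or `n11` as the first of four cell
#'   counts.
#' @param n10,n01,n00 remaining cells when `table` is a bare count.
#' @param variant `"auto"`, `"exact"` or `"chi2-cc"`.
#' @return A list with `statistic` (chi-square variant only, else `NA`),
#'   `p.value`, `variant` (the variant actually used), `b`, `c`, and
#'   `no_discordance`.
#' @examples
#' # 12 discordant pairs split 1 / 11: significant at alpha = 0.05
#' mcnemar_test(contingency_table(13, 1, 11, 13))$p.value
#' @export
mcnemar_test <- function(table, n10 = NULL, n01 = NULL, n00 = NULL,
                         variant = c("auto", "exact", "chi2-cc")) {
  variant <- match.arg(variant)
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table, n10, n01, n00)
  b <- table$n10; cc <- table$n01
  if (b + cc == 0)
    return(list(statistic = NA_real_, p.value = 1, variant = variant,
                b = b, c = cc, no_discordance = TRUE))
  if (variant == "auto") variant <- if (b + cc < 25) "exact" else "chi2-cc"
  if (variant == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    stat <- NA_real_
  } else {
    stat <- if (b == cc) 0 else (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p.value = p, variant = variant, b = b, c = cc,
       no_discordance = FALSE)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-tailed paired test on per-sample score differences (e.g. per-patch
#' IoU from two segmentation models). Differences `d_i = a_i - b_i` are
#' ranked by absolute value with average ranks for ties;
#' `W = min(W+, W-)` where `W+`/`W-` are the positive/negative rank sums.
#'
#' * zero differences: `"discard"` (classic) drops them before ranking;
#'   `"pratt"` ranks them but excludes them from both rank sums.
#' * `"exact"` mode computes the full null distribution of `W+` over all
#'   `2^m` sign assignments (dynamic-programming convolution, equivalent to
#'   enumeration and valid under ties); `"normal"` uses the normal
#'   approximation with `Var(W+) = sum(r_i^2) / 4` (which embeds the tie
#'   correction) and a 0.5 continuity correction. `"auto"` picks exact for
#'   `m <= 20`.
#'
#' @param a,b equal-length numeric score vectors; alternatively `a` may be a
#'   two-column object from [simulate_paired_ious()] with `b` omitted.
#' @param zero_policy `"discard"` or `"pratt"`.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list with `statistic` (W), `p.value`, `m` (effective sample
#'   size), `mode` (the mode actually used) and `no_signal` (all differences
#'   zero).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1),
#'                      mode = "exact")$p.value  # 2/32
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 zero_policy = c("discard", "pratt"),
                                 mode = c("auto", "exact", "normal")) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  if (is.null(b)) {
    if (NCOL(a) != 2L)
      stop("provide two score vectors or a two-column pair object",
           call. = FALSE)
    b <- a[[2L]]; a <- a[[1L]]
  }
  if (length(a) != length(b))
    stop("paired score vectors differ in length", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, m = 0L, mode = mode,
                no_signal = TRUE))
  if (zero_policy == "discard") d <- d[d != 0]
  r <- rank(abs(d))
  nz <- d != 0
  wplus <- sum(r[d > 0]); wminus <- sum(r[d < 0])
  w <- min(wplus, wminus)
  m <- sum(nz)
  if (mode == "auto") mode <- if (m <= 20L) "exact" else "normal"
  rnz <- r[nz]
  if (mode == "exact") {
    # null distribution of 2*W+ over all 2^m sign assignments
    ri <- as.integer(round(2 * rnz))
    tot <- sum(ri)
    prob <- c(1, numeric(tot))
    for (k in ri) {
      shifted <- c(numeric(k), prob[seq_len(tot + 1L - k)])
      prob <- (prob + shifted) / 2
    }
    lo <- as.integer(round(2 * w))
    hi <- tot - lo
    p <- min(1, sum(prob[seq_len(lo + 1L)]) + sum(prob[(hi + 1L):(tot + 1L)]))
  } else {
    mu <- sum(rnz) / 2
    sigma <- sqrt(sum(rnz^2) / 4)
    z <- max(0, abs(wplus - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(statistic = w, p.value = p, m = m, mode = mode, no_signal = FALSE)
}

#' Significance calls for a grid of paired comparisons
#'
#' @param p a vector, matrix or data frame of p-values.
#' @param alpha significance level; a cell is significant iff `p < alpha`
#'   (strict, so `p = alpha` is not significant).
#' @param adjust multiple-testing adjustment applied across all cells before
#'   thresholding; `"none"` (default, per-comparison reporting) or `"holm"`.
#' @return Logical structure shaped like `p`, with attribute
#'   `n_significant`.
#' @export
significance_matrix <- function(p, alpha = 0.05,
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  pv <- if (is.data.frame(p)) as.matrix(p) else p
  if (adjust == "holm") pv[] <- stats::p.adjust(as.vector(pv), "holm")
  sig <- pv < alpha
  structure(sig, n_significant = sum(sig, na.rm = TRUE))
}
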
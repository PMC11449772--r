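#' @name stat-tests
#' @title Nonparametric test battery
#' @description
#' Thin, contract-specified wrappers used by the reporting stage: paired
#' Wilcoxon signed rank, Kruskal-Wallis with Bonferroni-corrected pairwise
#' follow-ups, Spearman rank correlation, and a two-way random
#' absolute-agreement single-measure intraclass correlation. Each returns
#' a `test_result` list: `statistic`, `p_value`, `n`, `method`,
#' `adjusted`, plus method-specific extras.
NULL

test_result <- function(statistic, p_value, n, method, adjusted = FALSE,
                        ...) {
  structure(c(list(statistic = unname(statistic),
                   p_value = unname(p_value),
                   n = n, method = method, adjusted = adjusted),
              list(...)),
            class = "test_result")
}

#' Paired Wilcoxon signed rank test
#'
#' Two-sided signed-rank test of paired measurements with Wilcoxon's
#' original zero-discard convention (exact-tie pairs are removed before
#' ranking) and midranks for tied absolute differences.
#'
#' @param x,y paired numeric vectors, equal length; at least 5 non-tied
#'   pairs must remain after discarding zeros.
#' @return a `test_result` (statistic V).
#' @rdname stat-tests
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    stop("all paired differences are zero: degenerate test", call. = FALSE)
  }
  if (length(d) < 5L) {
    stop("need at least 5 nonzero paired differences", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  )
  test_result(ht$statistic, ht$p.value, length(d),
              "Wilcoxon signed rank (paired, zero-discard)")
}

#' Kruskal-Wallis omnibus test with Bonferroni pairwise follow-ups
#'
#' Tie-corrected Kruskal-Wallis H across >= 2 nonempty groups, followed by
#' all pairwise two-sided rank-sum comparisons whose p-values are
#' multiplied by the number of pairs and capped at 1.
#'
#' @param groups named list of numeric vectors.
#' @return a `test_result` for the omnibus H, with a `pairwise` data.frame
#'   (group1, group2, p_raw, p_adjusted).
#' @rdname stat-tests
#' @export
kruskal_wallis_bonferroni <- function(groups) {
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2L) {
    stop("need at least 2 nonempty groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  x <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (length(unique(x)) == 1L) {
    # no variation anywhere: H is 0 by convention (base R returns NaN)
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0), p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, f)
  }

  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  p_raw <- vapply(seq_len(m), function(j) {
    suppressWarnings(stats::wilcox.test(groups[[pairs[1, j]]],
                                        groups[[pairs[2, j]]],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p_raw = p_raw,
                         p_adjusted = pmin(p_raw * m, 1),
                         stringsAsFactors = FALSE)
  test_result(kw$statistic, kw$p.value, length(x),
              "Kruskal-Wallis H (tie-corrected)", adjusted = FALSE,
              pairwise = pairwise)
}

#' Spearman rank correlation
#'
#' Midrank-based rank correlation with a two-sided p-value (exact where
#' base R provides it, i.e. small n without ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `test_result` with `estimate` = r_s.
#' @rdname stat-tests
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  test_result(ht$statistic, ht$p.value, length(x),
              "Spearman rank correlation",
              estimate = unname(ht$estimate))
}

#' Intraclass correlation, two-way random, absolute agreement, single
#'
#' ICC(A,1) from the two-way mean-squares decomposition of an n x k
#' ratings matrix (subjects x raters/occasions):
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with the F test of between-subject against residual mean squares for
#' the p-value. `type = "consistency"` switches to ICC(C,1), which drops
#' the rater variance term.
#'
#' @param ratings numeric matrix or data.frame, subjects in rows, >= 2
#'   columns, >= 5 complete rows, no missing values.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return a `test_result` with `estimate` = ICC.
#' @rdname stat-tests
#' @export
icc <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  stopifnot(is.numeric(ratings), ncol(ratings) >= 2L, nrow(ratings) >= 5L,
            !anyNA(ratings))
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (ms_r <= 0 || ss_r == 0) {
    stop("zero between-subject variance: ICC undefined", call. = FALSE)
  }
  est <- if (type == "agreement") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  } else {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  }
  f <- ms_r / ms_e
  p <- if (ms_e == 0) 0 else
    stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  if (ms_e == 0) { est <- 1; f <- Inf }
  test_result(f, p, n, sprintf("ICC (two-way random, %s, single)", type),
              estimate = est)
}
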
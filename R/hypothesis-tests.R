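# Rank-based comparisons of grouped distances: Kruskal-Wallis across the
# three distance groupings with a Dunn posttest, and the two-group
# Wilcoxon/Mann-Whitney rank-sum test for the birth-mode and
# reproductive-stage contrasts.

#' Kruskal-Wallis test with Dunn's posttest
#'
#' The omnibus H statistic (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's pairwise z comparisons on the joint midranks with
#' tie-corrected variance. Pairwise p-values are reported both unadjusted
#' and Holm-adjusted.
#'
#' @param data A data frame (e.g. a [group_distances()] result).
#' @param value,group Column names (tidy-eval) of the response and the
#'   grouping factor.
#' @return An object of class `kw_dunn`; see [tidy.kw_dunn()] and
#'   [glance.kw_dunn()].
#' @export
kruskal_dunn <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- rlang::eval_tidy(value, data)
  g <- factor(rlang::eval_tidy(group, data))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("kruskal_dunn needs at least 2 non-empty groups")

  if (length(unique(x)) == 1) {
    kw_stat <- 0; kw_p <- 1; df <- nlevels(g) - 1
  } else {
    kw <- stats::kruskal.test(x, g)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
    df <- unname(kw$parameter)
  }

  # Dunn z on joint midranks with tie correction
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(g)
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  combs <- utils::combn(lv, 2)
  z <- p_unadj <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    a <- combs[1, k]; b <- combs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[k] <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p_unadj[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  posttest <- tibble(group1 = combs[1, ], group2 = combs[2, ], z = z,
                     p_value = p_unadj,
                     p_value_holm = stats::p.adjust(p_unadj, "holm"))
  structure(list(statistic = kw_stat, df = df, p_value = kw_p,
                 method = "Kruskal-Wallis with Dunn posttest",
                 posttest = posttest, group_sizes = as.integer(n_g)),
            class = "kw_dunn")
}

#' @method print kw_dunn
#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("%s\nH = %.4g, df = %d, p = %.4g\n", x$method, x$statistic,
              x$df, x$p_value))
  print(x$posttest)
  invisible(x)
}

#' Tidy the Dunn posttest table
#'
#' @param x A `kw_dunn` object.
#' @param ... Unused.
#' @return Tibble with one row per pairwise comparison.
#' @method tidy kw_dunn
#' @export
tidy.kw_dunn <- function(x, ...) x$posttest

#' One-row summary of a Kruskal-Wallis test
#'
#' @inheritParams tidy.kw_dunn
#' @method glance kw_dunn
#' @export
glance.kw_dunn <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = x$method)
}

# exact two-sided rank-sum p-value by enumeration of all C(n, n_a)
# assignments of the joint sample to group a; valid only without ties.
rank_sum_exact_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  combs <- utils::combn(n, length(a))
  w_all <- colSums(matrix(r[combs], nrow = length(a)))
  mu <- length(a) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Two-sided. When the combined sample size is at most `exact_threshold`
#' and there are no ties, the p-value is exact, by complete enumeration of
#' group assignments; otherwise the normal approximation with midranks and
#' tie-corrected variance is used (via [stats::wilcox.test()], without
#' continuity correction so it matches the tie-corrected z exactly). The
#' method actually used is recorded in the result.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_threshold Combined-size bound for exact enumeration
#'   (default 12).
#' @return An object of class `rank_sum_test` with `statistic` (rank sum of
#'   `a`), `p_value` and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_threshold = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  n <- length(a) + length(b)
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (n <= exact_threshold && !has_ties) {
    p <- rank_sum_exact_p(a, b)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    p <- wt$p.value
    method <- "normal approximation, tie-corrected"
  }
  w <- sum(rank(c(a, b))[seq_along(a)])
  structure(list(statistic = w, p_value = min(p, 1), method = method,
                 n = c(length(a), length(b))),
            class = "rank_sum_test")
}

#' @method print rank_sum_test
#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' @rdname glance.kw_dunn
#' @method glance rank_sum_test
#' @export
glance.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method,
         n1 = x$n[1], n2 = x$n[2])
}

#' @rdname tidy.kw_dunn
#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) glance.rank_sum_test(x)
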
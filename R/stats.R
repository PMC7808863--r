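#' Exact Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-group rank-sum comparison with mid-ranks for ties. For small samples
#' (`n1 + n2 <= exact_max_n`, default 16, which covers cohorts of six per
#' group) the two-sided p-value is computed by complete enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the observed (mid-)ranks —
#' exact whether or not there are ties. Larger samples use the normal
#' approximation with tie correction and continuity correction. The
#' two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))` under the
#' enumeration null.
#'
#' @param a,b Numeric vectors of finite values, one per sampling unit.
#' @param exact_max_n Largest combined sample size for which full
#'   enumeration is used.
#' @return An object of class `rank_sum`: list with `U` (Mann-Whitney
#'   statistic of `a`), `p_two_sided`, `method` (one of
#'   `exact_enumeration`, `exact_with_ties`, `normal_approx`), `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))   # p = 2/20 = 0.10
#' @export
rank_sum_test <- function(a, b, exact_max_n = 16) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  stop_unless(length(a) >= 1 && length(b) >= 1, "both groups must be non-empty")
  stop_unless(all(is.finite(a)) && all(is.finite(b)),
              "values must be finite")
  n1 <- length(a)
  n2 <- length(b)
  n <- n1 + n2
  rk <- rank(c(a, b))                 # mid-ranks for ties
  w_obs <- sum(rk[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0

  if (n <= exact_max_n) {
    sums <- utils::combn(n, n1, function(ix) sum(rk[ix]))
    eps <- 1e-9
    p_le <- mean(sums <= w_obs + eps)
    p_ge <- mean(sums >= w_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- if (ties) "exact_with_ties" else "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(U = u_obs, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2),
            class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): U = %.1f, n = %d + %d, p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Compare locomotion metrics between two groups
#'
#' Runs one rank-sum test per metric (total distance, median moving speed,
#' median bout duration, bout count), per experiment and pooled across
#' experiments, flagging significance at the 0.05 and 0.01 levels. Larvae
#' with an undefined metric (e.g. no bouts) are dropped from that metric's
#' comparison. No multiple-testing correction is applied.
#'
#' @param metrics Metrics data frame from [cohort_metrics()] (needs `group`
#'   and `experiment` columns; groups compared in alphabetical order of
#'   label, first vs second).
#' @param metric_cols Metric columns to compare.
#' @return Data frame `metric,experiment,n1,n2,U,p_two_sided,sig_0.05,
#'   sig_0.01` with one row per metric x (experiment levels + "pooled").
#' @export
compare_groups <- function(metrics,
                           metric_cols = c("total_distance_px",
                                           "median_speed_px_per_interval",
                                           "median_bout_duration_windows",
                                           "bout_count")) {
  stop_unless(all(c("group", "experiment") %in% names(metrics)),
              "metrics need group and experiment columns")
  stop_unless(all(metric_cols %in% names(metrics)),
              "missing metric columns")
  g <- sort(unique(metrics$group))
  stop_unless(length(g) == 2, "exactly two groups are required")
  exps <- unique(as.character(metrics$experiment))
  blocks <- c(as.list(exps), list(exps))
  names(blocks) <- c(exps, "pooled")
  if (length(exps) == 1) blocks <- blocks[1]

  rows <- list()
  for (bn in names(blocks)) {
    sub <- metrics[metrics$experiment %in% blocks[[bn]], ]
    for (m in metric_cols) {
      va <- sub[[m]][sub$group == g[1]]
      vb <- sub[[m]][sub$group == g[2]]
      va <- va[is.finite(va)]
      vb <- vb[is.finite(vb)]
      rs <- rank_sum_test(va, vb)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, experiment = bn, n1 = rs$n1, n2 = rs$n2, U = rs$U,
        p_two_sided = rs$p_two_sided,
        sig_0.05 = rs$p_two_sided < 0.05,
        sig_0.01 = rs$p_two_sided < 0.01,
        check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
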
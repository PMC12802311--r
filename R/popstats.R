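# population statistics over grouped cell tables

#' Per-group distribution summaries with bootstrap variance CIs
#'
#' For each group: sample size, type-7 quartiles, min/max, unbiased sample
#' variance with a seeded nonparametric bootstrap percentile confidence
#' interval, and the fraction of long (> `split` um) cells. Groups with
#' fewer than two observations are omitted with a warning.
#'
#' @param records `cell_records`-style data.frame.
#' @param group_key name of the grouping column (e.g. `"hour"`).
#' @param feature one of `"length"`, `"width"`, `"mean_intensity"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param split long/short boundary in um for `long_fraction` (default 4,
#'   computed on the `length` column regardless of `feature`).
#' @return data.frame of class `population_summary`, one row per group:
#'   `group, n, median, q1, q3, min, max, variance, var_lo, var_hi,
#'   long_fraction`.
#' @export
summarize_population <- function(records, group_key = "group",
                                 feature = c("length", "width",
                                             "mean_intensity"),
                                 n_boot = 1000, seed = 1L, conf = 0.95,
                                 split = 4) {
  feature <- match.arg(feature)
  if (!group_key %in% names(records))
    abort("summarize_population: no column '%s'", group_key)
  if (!feature %in% names(records))
    abort("summarize_population: no column '%s'", feature)
  groups <- sort(unique(records[[group_key]]))
  alpha <- (1 - conf) / 2
  rows <- list()
  with_seed(seed, {
    for (g in groups) {
      x <- records[[feature]][records[[group_key]] == g]
      x <- x[!is.na(x)]
      if (length(x) < 2) {
        warning(sprintf("group '%s' has < 2 observations; omitted", g))
        next
      }
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      v <- stats::var(x)
      bv <- vapply(seq_len(n_boot), function(i)
        stats::var(x[sample.int(length(x), replace = TRUE)]), numeric(1))
      ci <- stats::quantile(bv, c(alpha, 1 - alpha), names = FALSE)
      lens <- records$length[records[[group_key]] == g]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
        min = min(x), max = max(x), variance = v,
        var_lo = ci[1], var_hi = ci[2],
        long_fraction = mean(lens > split, na.rm = TRUE))
    }
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group = character(0), n = integer(0), median = numeric(0),
               q1 = numeric(0), q3 = numeric(0), min = numeric(0),
               max = numeric(0), variance = numeric(0), var_lo = numeric(0),
               var_hi = numeric(0), long_fraction = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("population_summary", "data.frame")
  out
}

# two-sided rank-sum test; exact enumeration when both groups are small,
# tie-corrected normal approximation (with continuity correction) otherwise
#' @noRd
ranksum_test <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  s <- sum(r[seq_len(n1)])           # rank sum of the first group
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(s - mu) - 1e-9)
  } else {
    ties <- table(r)
    tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * ((n + 1) - tiecorr)
    z <- (abs(s - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(statistic = s, p = p)
}

#' Pairwise Wilcoxon rank-sum tests across groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test for every unordered pair
#' of groups, with multiplicity adjustment across all pairs. The null
#' distribution is enumerated exhaustively when both groups have at most
#' 10 observations (valid under ties); larger pairs use the tie-corrected
#' normal approximation with continuity correction. Chosen because cell
#' length and intensity distributions are non-parametric and the groups
#' unmatched.
#'
#' @param records data.frame with the feature and grouping columns.
#' @param group_key grouping column name.
#' @param feature feature column name (default `"length"`).
#' @param adjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return data.frame of class `pairwise_tests`: `group_a, group_b,
#'   statistic` (rank sum of group_a), `p_raw, p_adjusted, method`. Pairs
#'   where a group has < 2 observations are skipped with a warning.
#' @export
pairwise_wilcoxon <- function(records, group_key = "group",
                              feature = "length", adjust = "holm") {
  if (!group_key %in% names(records) || !feature %in% names(records))
    abort("pairwise_wilcoxon: missing column")
  groups <- sort(unique(records[[group_key]]))
  if (length(groups) < 2)
    abort("pairwise_wilcoxon: need at least 2 groups")
  pairs <- utils::combn(length(groups), 2)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    ga <- groups[pairs[1, k]]; gb <- groups[pairs[2, k]]
    x <- records[[feature]][records[[group_key]] == ga]
    y <- records[[feature]][records[[group_key]] == gb]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("pair (%s, %s) skipped: group with < 2 observations",
                      ga, gb))
      next
    }
    t <- ranksum_test(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      group_a = ga, group_b = gb, statistic = t$statistic, p_raw = t$p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("pairwise_wilcoxon: no testable pairs")
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out$method <- paste0("wilcoxon_ranksum_", adjust)
  rownames(out) <- NULL
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

#' Ordinary least squares of mean fluorescence on cell length
#'
#' Fits `mean_intensity ~ length` and reports slope (a.u./um), intercept
#' (a.u.), adjusted R-squared, n, and the slope's t-test p-value.
#'
#' @param records table with `length` and `mean_intensity` columns.
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared_adjusted`, `n`, `p_value`.
#' @export
regress_intensity_on_length <- function(records) {
  ok <- !is.na(records$mean_intensity) & !is.na(records$length)
  x <- records$length[ok]; y <- records$mean_intensity[ok]
  if (length(x) < 3)
    abort("regress_intensity_on_length: need n >= 3 with intensity")
  if (stats::var(x) == 0)
    abort("regress_intensity_on_length: zero length variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared_adjusted = sm$adj.r.squared,
                 n = length(x),
                 p_value = unname(sm$coefficients[2, 4])),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(paste0("<regression_result> y = %.4gx + %.5g, adjusted R^2 ",
                     "= %.4f, n = %d, p = %.3g\n"),
              x$slope, x$intercept, x$r_squared_adjusted, x$n, x$p_value))
  invisible(x)
}

#' Subpopulation fractions per group
#'
#' @param summaries a `population_summary` table.
#' @return data.frame `group, long_fraction, short_fraction`; the two
#'   fractions sum to 1 per group.
#' @export
subpopulation_trajectory <- function(summaries) {
  stopifnot(inherits(summaries, "population_summary") ||
              all(c("group", "long_fraction") %in% names(summaries)))
  data.frame(group = summaries$group,
             long_fraction = summaries$long_fraction,
             short_fraction = 1 - summaries$long_fraction)
}

#' Box-and-whisker and variance-CI plots
#'
#' Box-and-whisker convention: boxes span the 1st-3rd quartile with the
#' median line; whiskers span minimum to maximum; points beyond 1.5 IQR of
#' the box are additionally drawn as dots. The variance plot shows the
#' per-group variance with its bootstrap 95% CI as vertical bars.
#'
#' @param records cell table (for the box plot).
#' @param summaries `population_summary` table (for the variance plot).
#' @param group_key,feature columns to plot.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the plotted statistics.
#' @export
plot_population_boxes <- function(records, group_key = "group",
                                  feature = "length", file = NULL) {
  groups <- sort(unique(records[[group_key]]))
  stats_list <- lapply(groups, function(g) {
    x <- records[[feature]][records[[group_key]] == g]
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    out <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
    list(stats = c(min(x), q, max(x)), out = out)
  })
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  bx <- list(stats = vapply(stats_list, `[[`, numeric(5), "stats"),
             n = vapply(groups, function(g)
               sum(records[[group_key]] == g), numeric(1)),
             conf = NULL, out = unlist(lapply(stats_list, `[[`, "out")),
             group = rep(seq_along(groups), vapply(stats_list, function(s)
               length(s$out), integer(1))),
             names = as.character(groups))
  graphics::bxp(bx, outline = TRUE, xlab = group_key, ylab = feature,
                main = sprintf("%s by %s", feature, group_key))
  invisible(bx)
}

#' @rdname plot_population_boxes
#' @export
plot_variance_ci <- function(summaries, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  x <- seq_len(nrow(summaries))
  graphics::plot(x, summaries$variance, ylim = range(c(summaries$var_lo,
                                                       summaries$var_hi)),
                 pch = 19, xaxt = "n", xlab = "group",
                 ylab = "variance (um^2)", main = "variance with 95% CI")
  graphics::axis(1, at = x, labels = summaries$group)
  graphics::arrows(x, summaries$var_lo, x, summaries$var_hi, angle = 90,
                   code = 3, length = 0.05)
  invisible(summaries)
}
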
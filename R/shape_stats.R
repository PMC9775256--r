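# Inferential statistics for the accuracy study, written out as explicit
# formulas (distribution functions from base R: pt, pf, ptukey) so every
# number in a study report is auditable.

#' Two-sample t-test (Welch or pooled)
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param variant \code{"welch"} (default) or \code{"pooled"}.
#' @return list of class \code{t_test_result}: \code{t}, \code{df} (possibly
#'   fractional for Welch), two-sided \code{p}, \code{mean_diff} =
#'   \code{mean(x) - mean(y)}, \code{variant}.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  mean_diff <- mean(x) - mean(y)
  if (variant == "welch") {
    if (vx == 0 && vy == 0) stop("degenerate: both samples have zero variance")
    se2x <- vx / nx; se2y <- vy / ny
    t_stat <- mean_diff / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 == 0) stop("degenerate: pooled variance is zero")
    t_stat <- mean_diff / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  structure(list(t = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df),
                 mean_diff = mean_diff, variant = variant),
            class = "t_test_result")
}

# Paired t on per-target differences; emitted as a supplementary column of
# the study report (the distances compared are paired per target even though
# the primary analysis uses the two-sample form).
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2L) stop("need n >= 2 pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("degenerate: zero variance of differences")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * stats::pt(-abs(t_stat), n - 1))
}

#' One-way ANOVA
#'
#' \code{F = MS_between / MS_within} with \code{df} = (g - 1, N - g).
#'
#' @param groups list of g >= 2 numeric samples with total N > g.
#' @return list of class \code{anova_result}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, plus \code{ms_within} and group summaries
#'   used by \code{\link{tukey_hsd}}.
#' @export
one_way_anova <- function(groups) {
  g <- length(groups)
  if (g < 2L) stop("need at least 2 groups")
  ns <- lengths(groups)
  N <- sum(ns)
  if (N <= g) stop("total N must exceed the number of groups")
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(gr) sum((gr - mean(gr))^2),
                          numeric(1)))
  df_b <- g - 1L; df_w <- N - g
  ms_w <- ss_within / df_w
  if (ms_w == 0) stop("degenerate: zero within-group variance (F undefined)")
  F_stat <- (ss_between / df_b) / ms_w
  structure(list(F = F_stat, df_between = df_b, df_within = df_w,
                 p = stats::pf(F_stat, df_b, df_w, lower.tail = FALSE),
                 ms_within = ms_w, group_means = means, group_ns = ns),
            class = "anova_result")
}

#' Tukey honestly-significant-difference test
#'
#' All pairwise mean differences with p-values from the studentized-range
#' distribution with (g, N - g) (Tukey--Kramer standard errors for
#' unbalanced groups).
#'
#' @param groups named list of g >= 2 numeric samples.
#' @return data frame with one row per unordered pair: \code{pair},
#'   \code{diff} (mean of first minus mean of second), \code{p}.
#' @export
tukey_hsd <- function(groups) {
  aov_res <- one_way_anova(groups)
  g <- length(groups)
  nms <- names(groups) %||% paste0("group", seq_len(g))
  means <- aov_res$group_means; ns <- aov_res$group_ns
  out <- NULL
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      diff <- means[j] - means[i]
      se <- sqrt(aov_res$ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = g, df = aov_res$df_within,
                         lower.tail = FALSE)
      out <- rbind(out, data.frame(pair = paste(nms[j], nms[i], sep = "-"),
                                   diff = diff, p = p,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
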
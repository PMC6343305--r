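# Cohort statistics: per-group summaries and the comparison of every CBCT
# group against the micro-CT reference (paired t-tests and Pearson
# correlations, two-sided, alpha = 0.05, no multiple-testing correction).

PARAM_COLS <- c(bv_tv = "bv_tv_pct", tb_th = "tb_th_mm",
                tb_n = "tb_n_per_mm", tb_sp = "tb_sp_mm")

#' Paired t-test
#'
#' Differences `d = y - x`; `t = mean(d) / (sd(d) / sqrt(n))` with the sample
#' SD (n-1 denominator) and a two-sided p-value from Student's t with n-1
#' degrees of freedom. Zero-variance differences are flagged: p is 1 when the
#' differences are all zero and 0 when they are a nonzero constant.
#'
#' @param x,y paired per-specimen values of equal length n >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`, `zero_variance`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need n >= 2 pairs")
  d <- y - x
  s <- sd(d)
  if (s == 0) {
    all_zero <- all(d == 0)
    return(list(t = if (all_zero) 0 else sign(mean(d)) * Inf,
                p = if (all_zero) 1 else 0, df = n - 1L,
                mean_diff = mean(d), zero_variance = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1), df = n - 1L,
       mean_diff = mean(d), zero_variance = FALSE)
}

#' Pearson correlation
#'
#' Product-moment correlation with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n-2 degrees of freedom. `|r| = 1`
#' reports p = 0.
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Summarize a cohort of morphometry results
#'
#' One row per (group, parameter) with mean, sample SD, min, max, n —
#' the per-group "Mean ± SD" / "Range" summary of a cohort table.
#'
#' @param results data.frame of morphometry rows with columns `specimen_id`,
#'   `group`, `bv_tv_pct`, `tb_th_mm`, `tb_n_per_mm`, `tb_sp_mm`.
#' @return data.frame with columns `group`, `parameter`, `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
summarize_cohort <- function(results) {
  stopifnot(is.data.frame(results))
  groups <- sort(unique(results$group))
  rows <- list()
  for (g in groups) {
    sub <- results[results$group == g, ]
    if (nrow(sub) < 2L) stop("need >= 2 specimens per group (group ", g, ")")
    for (p in names(PARAM_COLS)) {
      v <- sub[[PARAM_COLS[[p]]]]
      if (all(is.na(v))) next
      if (anyNA(v)) stop("missing ", p, " values in group ", g)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, mean = mean(v), sd = sd(v),
        min = min(v), max = max(v), n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare CBCT groups against the micro-CT reference
#'
#' For each parameter and each pair (G0, Gk), k = 1..4: Pearson r with
#' p-value, paired t with p-value, and a significance flag at alpha = 0.05.
#' Specimens are matched by `specimen_id`.
#'
#' @param results data.frame as in [summarize_cohort()], containing G0 and at
#'   least one of G1-G4.
#' @param alpha significance level.
#' @return data.frame with columns `parameter`, `group_pair`, `r`, `r_p`, `t`,
#'   `t_p`, `significant` (flag on the paired-test p).
#' @export
compare_groups <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  ref <- results[results$group == "G0", ]
  if (nrow(ref) == 0L) stop("no G0 reference rows")
  others <- setdiff(sort(unique(results$group)), "G0")
  rows <- list()
  for (gk in others) {
    sub <- results[results$group == gk, ]
    if (!setequal(ref$specimen_id, sub$specimen_id))
      stop("specimen sets differ between G0 and ", gk)
    sub <- sub[match(ref$specimen_id, sub$specimen_id), ]
    for (p in names(PARAM_COLS)) {
      x <- ref[[PARAM_COLS[[p]]]]
      y <- sub[[PARAM_COLS[[p]]]]
      if (all(is.na(x)) || all(is.na(y))) next
      pc <- pearson_correlation(x, y)
      tt <- paired_t_test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, group_pair = paste0("G0_vs_", gk),
        r = pc$r, r_p = pc$p, t = tt$t, t_p = tt$p,
        significant = tt$p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
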
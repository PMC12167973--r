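#' Per-day activity-state fractions
#'
#' Fractions of tracked cells that are silent, active, and (of all cells)
#' classified as place cells on one day.
#'
#' @param states character matrix (tracks x days), "silent"/"active".
#' @param day day index.
#' @param labels optional per-track classification labels for that day
#'   ("place" counts toward place_frac); NA place_frac when absent.
#' @return list(silent_frac, active_frac, place_frac, n).
#' @export
session_fractions <- function(states, day, labels = NULL) {
  n <- nrow(states)
  if (n == 0L) fail("no tracked cells")
  s <- mean(states[, day] == "silent")
  list(silent_frac = s, active_frac = 1 - s,
       place_frac = if (is.null(labels)) NA_real_
       else mean(labels == "place"),
       n = n)
}

#' Mean unsilencing rate over consecutive day pairs
#'
#' For each consecutive day pair, the fraction of day-k silent cells that
#' are active on day k+1; the summary is the unweighted mean over pairs
#' (pairs with no silent cells are skipped). The transition-pooled
#' estimate is also reported.
#'
#' @param states character matrix (tracks x days).
#' @return list(u, per_pair, pooled).
#' @export
unsilencing_rate <- function(states) {
  n_days <- ncol(states)
  if (n_days < 2L) fail("need at least 2 days")
  per_pair <- rep(NA_real_, n_days - 1L)
  num <- den <- 0L
  for (k in seq_len(n_days - 1L)) {
    sil <- states[, k] == "silent"
    if (!any(sil)) next
    un <- sum(states[sil, k + 1L] == "active")
    per_pair[k] <- un / sum(sil)
    num <- num + un; den <- den + sum(sil)
  }
  if (all(is.na(per_pair))) fail("no day pair with silent cells")
  list(u = mean(per_pair, na.rm = TRUE), per_pair = per_pair,
       pooled = num / den)
}

#' Theoretical persistently-silent decay
#'
#' Under memoryless day-to-day unsilencing at rate u, the expected count of
#' cells silent on every day 1..k, normalized to day 1, is (1-u)^(k-1).
#' A persistently silent subpopulation makes the empirical curve sit above
#' this prediction from day 2 on.
#'
#' @param u unsilencing rate in [0, 1].
#' @param n_days number of days.
#' @return numeric vector of length n_days, first element 1.
#' @export
theoretical_decay <- function(u, n_days) {
  if (u < 0 || u > 1) fail("u must lie in [0, 1]")
  (1 - u)^(seq_len(n_days) - 1L)
}

#' Bootstrap confidence interval for a group difference
#'
#' Resamples each group with replacement, recomputes the difference of the
#' group statistic (a minus b), and reports the 2.5th and 97.5th
#' percentiles of the bootstrap distribution as the 95 percent CI.
#'
#' @param group_a,group_b numeric samples.
#' @param statistic "mean" or "median".
#' @param n_resamples bootstrap draws. Default 5000.
#' @param conf confidence level. Default 0.95.
#' @param seed integer seed.
#' @return object of class \code{effect_size_ci}: list(observed, ci_low,
#'   ci_high, statistic, n_resamples, boot).
#' @export
bootstrap_diff_ci <- function(group_a, group_b,
                              statistic = c("mean", "median"),
                              n_resamples = 5000L, conf = 0.95,
                              seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(group_a) == 0L || length(group_b) == 0L)
    fail("both groups must be non-empty")
  if (statistic == "median" &&
      (length(group_a) == 1L || length(group_b) == 1L))
    warning("median bootstrap on a single observation is degenerate")
  st <- match.fun(statistic)
  obs <- st(group_a) - st(group_b)
  boot <- with_seed_(seed, {
    ra <- matrix(sample(group_a, length(group_a) * n_resamples,
                        replace = TRUE), ncol = n_resamples)
    rb <- matrix(sample(group_b, length(group_b) * n_resamples,
                        replace = TRUE), ncol = n_resamples)
    if (statistic == "mean") colMeans(ra) - colMeans(rb)
    else apply(ra, 2, st) - apply(rb, 2, st)
  })
  alpha <- (1 - conf) / 2
  structure(list(observed = obs, ci_low = pctl(boot, alpha),
                 ci_high = pctl(boot, 1 - alpha), statistic = statistic,
                 n_resamples = n_resamples, boot = boot),
            class = "effect_size_ci")
}

## Dunn's rank-based post-hoc z tests after Kruskal-Wallis, with tie
## correction and multiplicity adjustment
dunn_posthoc <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  gl <- levels(groups)
  cmb <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- (mr[[i]] - mr[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = cmb[1, ], group_b = cmb[2, ], z = z,
             p = p, p_adj = stats::p.adjust(p, p_adjust))
}

#' Standard group comparisons
#'
#' Thin adapter over the comparison tests the analysis uses: two-sample
#' Kolmogorov-Smirnov, Kruskal-Wallis with Dunn's post-hoc z tests,
#' Mann-Whitney U, and paired/unpaired t tests. Significance is read at
#' p < 0.05.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param paired logical; paired t test for two equal-length groups.
#' @return list with per-test statistic and p (ks/mwu/t for two groups;
#'   kruskal + dunn for three or more), and \code{alpha}.
#' @export
group_tests <- function(samples, paired = FALSE) {
  if (length(samples) < 2L) fail("need at least 2 groups")
  if (any(vapply(samples, length, 0L) == 0L)) fail("empty group")
  out <- list(alpha = 0.05)
  if (length(samples) == 2L) {
    a <- samples[[1]]; b <- samples[[2]]
    ks <- suppressWarnings(stats::ks.test(a, b))
    out$ks <- list(statistic = unname(ks$statistic), p = ks$p.value)
    mw <- suppressWarnings(stats::wilcox.test(a, b))
    out$mwu <- list(statistic = unname(mw$statistic), p = mw$p.value)
    tt <- stats::t.test(a, b, paired = paired)
    out$t <- list(statistic = unname(tt$statistic), p = tt$p.value,
                  paired = paired)
  }
  values <- unlist(samples, use.names = FALSE)
  groups <- rep(names(samples), vapply(samples, length, 0L))
  kw <- stats::kruskal.test(values, factor(groups))
  out$kruskal <- list(statistic = unname(kw$statistic), p = kw$p.value)
  if (length(samples) > 2L)
    out$dunn <- dunn_posthoc(values, groups)
  out
}
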
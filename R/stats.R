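# Statistical comparison machinery: bootstrap CIs, paired t-test, exact
# Wilcoxon signed-rank, Holm-Bonferroni correction, and per-image pairing
# on a common subset.

#' Percentile bootstrap CI of the mean
#'
#' Resamples with replacement and reports the percentile interval of the
#' resampled means.  Reproducible per seed.  `exhaustive = TRUE`
#' enumerates all `n^n` resamples (only for very small samples).
#'
#' @param sample non-empty numeric vector.
#' @param n_boot number of bootstrap replicates.
#' @param alpha two-sided miscoverage (0.05 for a 95% CI).
#' @param seed RNG seed.
#' @param exhaustive enumerate every resample instead of sampling
#'   (requires `length(sample)^length(sample) <= 1e6`).
#' @return list `(mean, low, high)`.
#' @export
bootstrap_mean_ci <- function(sample, n_boot = 10000L, alpha = 0.05,
                              seed = 1L, exhaustive = FALSE) {
  if (length(sample) == 0) stop("sample must be non-empty")
  n <- length(sample)
  if (exhaustive) {
    if (n^n > 1e6) stop("exhaustive enumeration limited to n^n <= 1e6")
    # count through all n^n index tuples in base n
    total <- n^n
    means <- numeric(total)
    idx <- rep(1L, n)
    for (r in seq_len(total)) {
      means[r] <- mean(sample[idx])
      for (pos in seq_len(n)) {
        idx[pos] <- idx[pos] + 1L
        if (idx[pos] <= n) break
        idx[pos] <- 1L
      }
    }
  } else {
    means <- withr::with_seed(as.integer(seed), {
      ii <- sample.int(n, n * n_boot, replace = TRUE)
      colMeans(matrix(sample[ii], n, n_boot))
    })
  }
  q <- stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(mean = mean(sample), low = q[1], high = q[2])
}

#' Paired t-test with confidence interval
#'
#' Two-sided paired t-test on `a - b`, with the `1 - alpha` CI for the
#' mean difference from the t-distribution with `n - 1` degrees of
#' freedom.  Zero-variance differences are a degenerate-input error.
#'
#' @param a,b equal-length numeric vectors (length >= 2).
#' @param conf_level confidence level for the interval.
#' @return list `(delta, ci_low, ci_high, t, df, p)`.
#' @export
paired_t_test <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) < 1e-14 * max(1, max(abs(d))))
    stop("degenerate input: all paired differences are identical to machine precision")
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
  list(delta = mean(d), ci_low = unname(tt$conf.int[1]),
       ci_high = unname(tt$conf.int[2]), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Paired signed-rank test on `a - b`: zero differences are dropped
#' (Wilcoxon's original treatment), tied absolute differences get
#' mid-ranks, and for `n <= 25` retained pairs the p-value comes from the
#' exact null distribution of the rank sum (computed by dynamic
#' programming over doubled ranks, so mid-ranks stay exact).  Above 25 a
#' normal approximation with tie correction and continuity correction is
#' used.  With all five differences of the same sign at n = 5 the exact
#' two-sided p is 2/2^5 = 0.0625, the smallest attainable value.
#'
#' @param a,b equal-length numeric vectors.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) stop("degenerate input: all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))                      # mid-ranks for ties
  w_plus <- sum(r[d > 0])
  if (n <= 25L) {
    # doubled ranks are integers even with .5 mid-ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    freq <- numeric(tot + 1L)            # freq[w+1] = #subsets with sum w
    freq[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), freq[seq_len(tot + 1L - rk)])
      freq <- freq + shifted
    }
    freq <- freq / 2^n
    obs <- as.integer(round(2 * w_plus))
    p_le <- sum(freq[seq_len(obs + 1L)])
    p_ge <- sum(freq[(obs + 1L):(tot + 1L)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusts a family of p-values by the Holm step-down rule (sort
#' ascending, multiply the i-th smallest by `m - i + 1`, enforce a
#' cumulative maximum, cap at 1) and returns them in the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Pair two per-image result sets on their common subset
#'
#' Keeps only image ids present in both result sets (intersection by id),
#' ordered consistently, for paired per-image testing.
#'
#' @param results_a,results_b data frames with an `image_id` column
#'   (unique within each input), e.g. from [evaluate_faithfulness()].
#' @return list with `ids`, `a`, `b` (row-aligned data frames) and `n`.
#' @export
common_subset_pairing <- function(results_a, results_b) {
  ida <- results_a$image_id; idb <- results_b$image_id
  if (anyDuplicated(ida) || anyDuplicated(idb))
    stop("image_ids must be unique within each result set")
  common <- intersect(ida, idb)
  if (length(common) == 0) stop("empty intersection of image ids")
  common <- common[order(common)]
  list(ids = common,
       a = results_a[match(common, ida), , drop = FALSE],
       b = results_b[match(common, idb), , drop = FALSE],
       n = length(common))
}

#' Paired model-vs-model comparison table
#'
#' Convenience wrapper producing, for one family of contrasts (shared
#' Holm correction), the mean difference, t-based CI, paired t-test and
#' Wilcoxon signed-rank p-values, and Holm-adjusted t-test p-values.
#'
#' @param pairs named list; each element `list(a = , b = )` of
#'   equal-length paired score vectors (e.g. per-fold accuracies).
#' @param conf_level CI level.
#' @return data frame with one row per contrast.
#' @export
paired_comparison_table <- function(pairs, conf_level = 0.95) {
  rows <- lapply(names(pairs), function(nm) {
    pr <- pairs[[nm]]
    tt <- paired_t_test(pr$a, pr$b, conf_level)
    data.frame(comparison = nm, n = length(pr$a), delta = tt$delta,
               ci_low = tt$ci_low, ci_high = tt$ci_high,
               p_t = tt$p, p_wilcoxon = wilcoxon_signed_rank(pr$a, pr$b))
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_t)
  out
}
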
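#' Bootstrap convergence check of the realization ensemble
#'
#' Assesses convergence of the mean fracture count as a function of the
#' number of realizations. For each prefix length `k >= 2`, `b` bootstrap
#' resamples are drawn from the first `k` counts and, paired with them, from
#' the first `k - 1` counts; the relative difference at `k` is the mean over
#' resample pairs of `|M_k* - M_{k-1}*| / M_{k-1}*` (pairs with a zero-mean
#' shorter resample are skipped). The ensemble is declared converged at the
#' first `k` whose relative difference drops to the threshold (1% by
#' default). Plain (non-bootstrap) cumulative-mean relative differences are
#' reported alongside.
#'
#' @param counts Integer vector of per-realization fracture counts
#'   (length >= 2).
#' @param threshold Relative-difference convergence threshold, default 0.01.
#' @param b Number of bootstrap resamples, default 10000.
#' @param seed Optional seed for the bootstrap; `NULL` uses the current
#'   stream.
#' @return A tibble of class `hf_convergence` with columns `k`,
#'   `cumulative_mean`, `plain_rel_diff`, `bootstrap_rel_diff` (rows
#'   `k = 2..length(counts)`), and attributes `converged_at` (first
#'   converged `k`, or `NA`) and `threshold`.
#' @export
#' @examples
#' convergence_check(c(12, 12, 12, 12), seed = 1)
convergence_check <- function(counts, threshold = 0.01, b = 10000, seed = NULL) {
  stopifnot(length(counts) >= 2, all(counts >= 0), threshold > 0, threshold < 1)
  run <- function() {
    r <- length(counts)
    cmean <- cumsum(counts) / seq_along(counts)
    ks <- 2:r
    plain <- abs(cmean[ks] - cmean[ks - 1]) /
      ifelse(cmean[ks - 1] > 0, cmean[ks - 1], NA_real_)
    plain[cmean[ks - 1] == 0 & cmean[ks] == 0] <- 0
    boot <- vapply(ks, function(k) {
      if (all(counts[1:k] == 0)) return(0)
      # resample by index so length-one prefixes and scaled counts behave
      mk <- rowMeans(matrix(counts[sample.int(k, b * k, replace = TRUE)], b, k))
      mk1 <- rowMeans(matrix(counts[sample.int(k - 1, b * (k - 1), replace = TRUE)],
                             b, k - 1))
      ok <- mk1 > 0
      if (!any(ok)) return(0)
      mean(abs(mk[ok] - mk1[ok]) / mk1[ok])
    }, numeric(1))
    conv <- ks[boot <= threshold]
    out <- tibble::tibble(k = ks, cumulative_mean = cmean[ks],
                          plain_rel_diff = plain, bootstrap_rel_diff = boot)
    class(out) <- c("hf_convergence", class(out))
    attr(out, "converged_at") <- if (length(conv)) conv[1] else NA_integer_
    attr(out, "threshold") <- threshold
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Pooled two-sample t-test
#'
#' Equal-variance (pooled) two-sample t statistic with a two-sided p-value
#' from the t distribution on `n_a + n_b - 2` degrees of freedom, used to
#' verify that a virtual cohort's aBMD or BMI distribution is not
#' significantly different from a reference sample. Degenerate inputs with
#' zero pooled variance return `t = 0, p = 1` when the means agree and
#' `p = 0` (flagged) when they do not.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return A one-row tibble with columns `statistic`, `p_value`, `df`,
#'   `degenerate`.
#' @export
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
two_sample_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(a)), all(is.finite(b)))
  df <- length(a) + length(b) - 2
  pooled_var <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(tibble::tibble(statistic = 0, p_value = 1, df = df, degenerate = TRUE))
    }
    return(tibble::tibble(statistic = sign(mean(a) - mean(b)) * Inf,
                          p_value = 0, df = df, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), degenerate = FALSE)
}

#' Test a cohort's aBMD distribution against its Gaussian target
#'
#' Draws a Gaussian reference sample of the same size as the cohort from the
#' target distribution and applies the pooled two-sample t-test to the
#' cohort's total-hip aBMD values.
#'
#' @param cohort An `hf_cohort`.
#' @param target A [cohort_target()]; defaults to the target the cohort was
#'   built against.
#' @param seed Seed for the reference draw.
#' @return A one-row tibble as from [two_sample_ttest()].
#' @export
cohort_equivalence <- function(cohort, target = attr(cohort, "target"), seed = 1) {
  stopifnot(inherits(cohort, "hf_cohort"), inherits(target, "hf_cohort_target"))
  ref <- with_seed(seed,
                   stats::rnorm(nrow(cohort), target$abmd_mean, target$abmd_sd))
  two_sample_ttest(cohort$total_hip_abmd, ref)
}
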
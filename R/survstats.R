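#' Kaplan-Meier product-limit estimate
#'
#' @param surv a `survival_table` (time in days, event 0/1).
#' @return object of class `km_curve`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` at each observed time.
#' @export
km_estimate <- function(surv) {
  if (!nrow(surv)) stop("empty survival table")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-or-more-group log-rank test
#'
#' Standard (unweighted) log-rank with hypergeometric variance; the p-value
#' is taken from the upper tail of the chi-squared distribution with
#' (number of groups - 1) degrees of freedom.
#'
#' @param surv a `survival_table`.
#' @param groups named vector patient -> group label.
#' @return object of class `logrank_result`: list with `chisq`, `df`, `p`,
#'   and per-group `observed` / `expected` event counts.
#' @export
logrank_test <- function(surv, groups) {
  surv <- surv[surv$patient_id %in% names(groups), , drop = FALSE]
  g <- factor(groups[surv$patient_id])
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) == 0)) stop("a group has zero patients")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- nlevels(g) - 1
  structure(list(
    chisq = unname(sd$chisq), df = df,
    p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    observed = setNames(sd$obs, levels(g)),
    expected = setNames(sd$exp, levels(g))
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' Exclusion-resampling robustness of the two-group stratification
#'
#' For each `k`, repeatedly excludes `k` randomly chosen patients, re-runs
#' the phi/Ward two-group clustering on the remainder, and records the
#' log-rank p-value between the re-derived groups.  Replicates whose subset
#' yields a degenerate clustering or survival comparison (e.g. a constant
#' mutation profile) are resampled so every p-vector has length `reps`; the
#' number of such resampled draws is logged per `k`.
#'
#' @param M binary mutation matrix (patients x genes).
#' @param surv a `survival_table` covering the patients.
#' @param k_list numbers of patients to exclude (default `c(2,4,6,8,10)`;
#'   `k = 0` degenerates to the full-data test).
#' @param reps replicates per `k` (default 10000).
#' @param seed integer seed.
#' @return object of class `robustness_result`: per-`k` list with `k`,
#'   `p_values` (length `reps`), `failed` (resampled draw count) and summary
#'   `quantiles`.
#' @export
robustness_resampling <- function(M, surv, k_list = c(2, 4, 6, 8, 10),
                                  reps = 10000, seed = 1) {
  n <- nrow(M)
  if (max(k_list) >= n - 2) stop("max(k_list) must be smaller than n - 2")
  set.seed(seed)
  res <- lapply(k_list, function(k) {
    p <- numeric(reps)
    failed <- 0L
    for (r in seq_len(reps)) {
      repeat {
        keep <- if (k > 0) sample.int(n, n - k) else seq_len(n)
        pr <- tryCatch({
          sub <- M[keep, , drop = FALSE]
          grp <- cut_k_groups(ward_cluster(phi_distance_matrix(sub)), 2)
          logrank_test(surv, grp)$p
        }, error = function(e) NA_real_)
        if (!is.na(pr)) break
        failed <- failed + 1L
      }
      p[r] <- pr
    }
    list(k = k, p_values = p, failed = failed,
         quantiles = stats::quantile(p, c(0.25, 0.5, 0.75)))
  })
  names(res) <- paste0("k", k_list)
  structure(res, class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("Exclusion-resampling robustness of the two-group split\n")
  for (r in x)
    cat(sprintf("  k = %2d: median p = %.4g (IQR %.4g-%.4g), %d resampled\n",
                r$k, r$quantiles[[2]], r$quantiles[[1]], r$quantiles[[3]],
                r$failed))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @param yates apply the Yates continuity correction (default `TRUE`, the
#'   conventional default for 2x2 tables).
#' @return list with `statistic` and `p`.
#' @export
chi2_2x2 <- function(t, yates = TRUE) {
  t <- as.matrix(t)
  if (!all(dim(t) == 2)) stop("expected a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) stop("zero margin in 2x2 table")
  ct <- stats::chisq.test(t, correct = yates)
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities not larger
#' than that of the observed table at fixed margins.
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` (conditional MLE) and `p`.
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == 2)) stop("expected a 2x2 table")
  ft <- stats::fisher.test(t)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration when `m + n <= 20` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (statistic for `x`) and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}
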
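#' Filter lowly expressed features by counts per million
#'
#' Keeps a feature iff its CPM is at least 1 in strictly more than one-third
#' of the patients, i.e. removes features with CPM < 1 in two-thirds or more
#' of the patients.  CPM = count * 1e6 / library size (column sum).
#'
#' @param counts non-negative raw count matrix (features x patients).
#' @return the filtered count matrix.
#' @export
cpm_filter <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("zero library size column")
  cpm <- edgeR::cpm(counts)
  keep <- rowMeans(cpm >= 1) > 1 / 3
  counts[keep, , drop = FALSE]
}

#' Cyclic-loess normalization of log2 expression
#'
#' For each sample pair, a loess curve of M = x_i - x_j on
#' A = (x_i + x_j)/2 is fitted and half the fitted difference is subtracted
#' from one sample and added to the other; the full cycle over all pairs is
#' repeated `iterations` times (limma's `"pairs"` method).
#'
#' @param logexpr log2-scale matrix (features x patients).
#' @param iterations number of full cycles (default 3).
#' @param span loess span (default 0.7).
#' @return the normalized matrix (dimnames preserved).
#' @export
cyclic_loess_normalize <- function(logexpr, iterations = 3, span = 0.7) {
  if (ncol(logexpr) < 2) stop("need at least two samples to normalize")
  out <- limma::normalizeCyclicLoess(logexpr, span = span,
                                     iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(logexpr)
  attr(out, "scale") <- "log2"
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Empirical-Bayes moderated t-test for two groups
#'
#' Per-feature two-group comparison on log2 expression with
#' empirical-Bayes-moderated variances: residual variances with pooled
#' degrees of freedom d are shrunk toward a prior variance s0^2 with prior
#' degrees of freedom d0, both estimated by moment matching on the
#' distribution of log residual variances (the scaled-F model of the
#' standard moderated-t workflow).  The moderated statistic is
#' t = logFC / (s_tilde * sqrt(1/n1 + 1/n2)) with s_tilde^2 =
#' (d0 s0^2 + d s^2) / (d0 + d), referred to a t distribution on d0 + d
#' degrees of freedom.  logFC is oriented short-lived minus long-lived.
#'
#' @param expr log2 expression matrix (features x patients).
#' @param groups named vector patient -> group; if the values are
#'   `"short-lived"`/`"long-lived"` that orientation is used, otherwise the
#'   first factor level minus the second.
#' @param prior_df optional override for d0; `0` switches moderation off
#'   (ordinary equal-variance t), `Inf` fixes all variances at s0^2.
#' @return object of class `de_result`: data frame with columns `feature`,
#'   `logFC`, `t`, `p`, `q`, `mean_1`, `mean_2`; the estimated moderation
#'   parameters are in `attr(, "moderation")` (`d0`, `s0_2`, `df_residual`,
#'   posterior variances).
#' @export
moderated_t_test <- function(expr, groups, prior_df = NULL) {
  groups <- groups[colnames(expr)]
  if (anyNA(groups)) stop("groups must cover every patient column")
  lv <- if (all(c("short-lived", "long-lived") %in% groups))
    c("short-lived", "long-lived") else unique(groups)
  if (length(unique(groups)) != 2) stop("expected exactly two groups")
  g1 <- groups == lv[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("need at least two patients per group")

  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, !g1, drop = FALSE])
  rss <- rowSums((expr[, g1, drop = FALSE] - m1)^2) +
         rowSums((expr[, !g1, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- rss / d
  logFC <- m1 - m2

  ok <- s2 > 0
  if (!all(ok))
    warning(sum(!ok), " zero-variance feature(s); p set to 1")
  mod <- .fit_fdist_moments(s2[ok], d)
  d0 <- if (!is.null(prior_df)) prior_df else mod$d0
  s0_2 <- mod$s0_2

  if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }

  tt <- logFC / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tt), df_total, lower.tail = FALSE)
  tt[!ok] <- 0
  p[!ok] <- 1

  out <- data.frame(feature = rownames(expr), logFC = logFC, t = tt,
                    p = p, q = bh_adjust(p), mean_1 = m1, mean_2 = m2,
                    row.names = NULL)
  attr(out, "moderation") <- list(d0 = d0, s0_2 = s0_2, df_residual = d,
                                  s2_post = s2_post)
  attr(out, "groups") <- lv
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, n = 6, ...) {
  lv <- attr(x, "groups")
  mod <- attr(x, "moderation")
  cat(sprintf("Moderated-t differential expression (%d features, %s vs %s)\n",
              nrow(x), lv[1], lv[2]))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.3g\n",
              mod$d0, mod$s0_2))
  cat(sprintf("  %d features at q < 0.1\n", sum(x$q < 0.1)))
  print(utils::head(as.data.frame(x)[order(x$p), ], n))
  invisible(x)
}

# Moment estimation of the scaled-F prior (d0, s0^2) from residual variances:
# z = log(s^2) has mean log(s0^2) + digamma(d0/2) - log(d0/2)
#                 - digamma(d/2) + log(d/2)
# and variance trigamma(d/2) + trigamma(d0/2).
.fit_fdist_moments <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(ebar)
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Cluster patients on signature-gene expression
#'
#' Rows (features) are z-scored, patients are clustered with 1 - Pearson
#' distance between patient columns and Ward.D2 linkage (the same machinery
#' as the mutation clustering), and the tree is cut into `k` groups.
#' Constant rows are dropped with a warning (z-score undefined).
#'
#' @param signature_expr log2 expression of the signature features
#'   (features x patients).
#' @param k number of expression groups (default 4).
#' @return named integer vector patient -> group in `1..k`.
#' @export
expression_group_clustering <- function(signature_expr, k = 4) {
  v <- apply(signature_expr, 1, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant feature(s) dropped before z-scoring")
    signature_expr <- signature_expr[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  z <- (signature_expr - rowMeans(signature_expr)) / v
  if (k == 1)
    return(setNames(rep(1L, ncol(z)), colnames(z)))
  D <- 1 - stats::cor(z)
  diag(D) <- 0
  cut_k_groups(ward_cluster(D), k)
}

#' Fisher enrichment of annotation categories in the DE signature
#'
#' For each annotation category and each direction of change (up- and
#' downregulated counted separately), a 2x2 Fisher exact test of category
#' membership against signature membership within the background gene set,
#' with BH adjustment across all category/direction combinations.
#'
#' @param de a `de_result`.
#' @param annotations data frame with `gene` and `category` columns.
#' @param background character vector of background genes (must contain the
#'   signature).
#' @param q_cut signature cut-off on the DE q-value (default 0.1).
#' @return data frame with columns `category`, `direction`, `overlap`,
#'   `signature_size`, `category_size`, `background_size`, `p`, `q`.
#' @export
category_enrichment <- function(de, annotations, background, q_cut = 0.1) {
  sig_up <- de$feature[de$q < q_cut & de$logFC > 0]
  sig_down <- de$feature[de$q < q_cut & de$logFC < 0]
  if (!all(c(sig_up, sig_down) %in% background))
    stop("background must contain the signature genes")
  cats <- unique(annotations$category)
  rows <- list()
  for (cat_i in cats) {
    members <- intersect(annotations$gene[annotations$category == cat_i],
                         background)
    if (!length(members)) {
      warning("category '", cat_i, "' absent from background; skipped")
      next
    }
    for (dir in c("up", "down")) {
      sig <- if (dir == "up") sig_up else sig_down
      if (!length(sig)) next
      a <- length(intersect(sig, members))
      b <- length(sig) - a
      c_ <- length(members) - a
      d_ <- length(background) - length(sig) - c_
      ft <- fisher_exact_2x2(matrix(c(a, b, c_, d_), 2, byrow = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        category = cat_i, direction = dir, overlap = a,
        signature_size = length(sig), category_size = length(members),
        background_size = length(background), p = ft$p)
    }
  }
  if (!length(rows))
    return(data.frame(category = character(), direction = character(),
                      overlap = integer(), signature_size = integer(),
                      category_size = integer(), background_size = integer(),
                      p = numeric(), q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), ]
}
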
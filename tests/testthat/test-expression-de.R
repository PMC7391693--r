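test_that("CPM filter applies the more-than-one-third rule", {
  # library sizes make CPM easy to control: 3 patients
  counts <- rbind(
    zero = c(0, 0, 0),
    keep = c(15, 15, 2),    # CPM 1.5, 1.5, 0.2 at lib size 1e7
    drop = c(15, 2, 2)      # CPM 1.5, 0.2, 0.2
  )
  filler <- matrix(round(1e7 / 10) , 10, 3)  # dominates library size
  rownames(filler) <- paste0("f", 1:10)
  m <- rbind(counts, filler)
  out <- cpm_filter(m)
  expect_false("zero" %in% rownames(out))
  expect_true("keep" %in% rownames(out))
  expect_false("drop" %in% rownames(out))

  expect_error(cpm_filter(cbind(c(1, 2), c(0, 0))), "library")
})

test_that("cyclic loess leaves identical columns alone and centers offsets", {
  set.seed(1)
  base <- rnorm(300, 8, 2)
  same <- cbind(a = base, b = base, c = base)
  expect_equal(cyclic_loess_normalize(same), same, tolerance = 1e-9,
               ignore_attr = TRUE)

  # constant offset: post-normalization median M near zero
  off <- cbind(a = base, b = base + 1)
  norm <- cyclic_loess_normalize(off)
  expect_lt(abs(median(norm[, 1] - norm[, 2])), 1e-6)
  expect_lt(abs(mean(colMeans(norm)) - mean(base) - 0.5), 0.05)

  # contraction: a second pass adjusts far less than the first
  set.seed(2)
  noisy <- matrix(rnorm(2000 * 4, 8, 2), 2000, 4) +
    outer(rep(1, 2000), c(0, 0.4, -0.3, 0.2))
  n1 <- cyclic_loess_normalize(noisy)
  n2 <- cyclic_loess_normalize(n1)
  rms1 <- sqrt(mean((n1 - noisy)^2))
  rms2 <- sqrt(mean((n2 - n1)^2))
  expect_lt(rms2, 0.5 * rms1)

  expect_error(cyclic_loess_normalize(matrix(1:3, 3, 1)), "two samples")
})

test_that("moderated t reduces to the ordinary t when moderation is off", {
  set.seed(3)
  expr <- matrix(rnorm(200 * 12), 200, 12,
                 dimnames = list(paste0("g", 1:200), paste0("P", 1:12)))
  grp <- setNames(rep(c("short-lived", "long-lived"), each = 6),
                  colnames(expr))
  de0 <- moderated_t_test(expr, grp, prior_df = 0)
  oracle <- apply(expr, 1, function(x) {
    n1 <- 6; n2 <- 6
    sp2 <- (sum((x[1:6] - mean(x[1:6]))^2) +
            sum((x[7:12] - mean(x[7:12]))^2)) / (n1 + n2 - 2)
    (mean(x[1:6]) - mean(x[7:12])) / sqrt(sp2 * (1 / n1 + 1 / n2))
  })
  expect_equal(de0$t, unname(oracle), tolerance = 1e-10)
})

test_that("moderation parameters and statistics match the empirical-Bayes oracle", {
  set.seed(11)
  ng <- 2000; n <- 14
  s2 <- 0.6 * 8 / rchisq(ng, 8)   # scaled inverse chi-squared variances
  expr <- matrix(rnorm(ng * n, 0, sqrt(s2)), ng, n,
                 dimnames = list(paste0("g", 1:ng), paste0("P", 1:n)))
  expr[1:40, 1:7] <- expr[1:40, 1:7] + 2
  grp <- setNames(rep(c("short-lived", "long-lived"), each = 7),
                  colnames(expr))
  de <- moderated_t_test(expr, grp)
  design <- cbind(s = rep(c(1, 0), each = 7), l = rep(c(0, 1), each = 7))
  fit <- limma::eBayes(limma::contrasts.fit(limma::lmFit(expr, design),
                                            c(1, -1)))
  expect_equal(attr(de, "moderation")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "moderation")$s0_2, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 1]), tolerance = 1e-9)
  expect_equal(de$p, unname(fit$p.value[, 1]), tolerance = 1e-9)
  expect_equal(de$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-12)
})

test_that("degenerate features get t = 0, p = 1 with a warning", {
  expr <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("P", 1:10)))
  expr[2, ] <- 5
  grp <- setNames(rep(c("short-lived", "long-lived"), each = 5),
                  colnames(expr))
  expect_warning(de <- moderated_t_test(expr, grp), "zero-variance")
  expect_equal(de$t[2], 0)
  expect_equal(de$p[2], 1)
  # equal group means give t = 0, p = 1 even without degeneracy
  expr2 <- expr
  expr2[3, ] <- rep(c(1, 2, 3, 2, 1), 2)  # identical pattern in both groups
  de2 <- suppressWarnings(moderated_t_test(expr2, grp))
  expect_equal(de2$logFC[3], 0)
  expect_equal(de2$p[3], 1, tolerance = 1e-12)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand rule: q_i = min_{j >= i} p_(j) * m / j
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  m <- length(p)
  hand <- sapply(seq_len(m), function(i)
    min(sort(p)[i:m] * m / (i:m)))[rank(p)]
  expect_equal(bh_adjust(p), hand)
  expect_error(bh_adjust(c(0.1, NA)), "finite")
})

test_that("expression grouping separates constructed blocks", {
  set.seed(5)
  # gene-specific signed shifts between the blocks (a uniform shift would
  # vanish under the column-centering implicit in correlation distance)
  shift <- rep(c(4, -4), 10)
  blockA <- matrix(rnorm(20 * 6, 0, 0.5), 20, 6)
  blockB <- matrix(rnorm(20 * 6, 0, 0.5), 20, 6) + shift
  expr <- cbind(blockA, blockB)
  colnames(expr) <- paste0("P", 1:12)
  rownames(expr) <- paste0("g", 1:20)
  g <- expression_group_clustering(expr, k = 2)
  expect_equal(length(unique(g[1:6])), 1)
  expect_equal(length(unique(g[7:12])), 1)
  expect_true(g[1] != g[7])

  expect_equal(unname(expression_group_clustering(expr, k = 1)),
               rep(1L, 12))

  # duplicated patient columns land in the same group
  dup <- expr; dup[, 2] <- dup[, 1]
  gd <- expression_group_clustering(dup, k = 4)
  expect_equal(gd[[1]], gd[[2]])

  expr_const <- rbind(expr, const = rep(3, 12))
  expect_warning(expression_group_clustering(expr_const, k = 2), "constant")
})

test_that("category enrichment ranks a perfectly enriched category first", {
  set.seed(8)
  expr <- matrix(rnorm(300 * 12), 300, 12,
                 dimnames = list(paste0("g", 1:300), paste0("P", 1:12)))
  expr[1:25, 1:6] <- expr[1:25, 1:6] + 3   # upregulated signature
  grp <- setNames(rep(c("short-lived", "long-lived"), each = 6),
                  colnames(expr))
  de <- moderated_t_test(expr, grp)
  up <- de$feature[de$q < 0.1 & de$logFC > 0]
  ann <- rbind(
    data.frame(gene = up, category = "perfect"),
    data.frame(gene = paste0("g", 200:209), category = "unrelated"))
  enr <- category_enrichment(de, ann, background = rownames(expr))
  up_rows <- enr[enr$direction == "up", ]
  expect_equal(up_rows$category[which.min(up_rows$p)], "perfect")
  expect_gt(up_rows$p[up_rows$category == "unrelated"], 0.1)

  # category absent from background is skipped with a warning
  ann2 <- rbind(ann, data.frame(gene = "NOT_THERE", category = "ghost"))
  expect_warning(category_enrichment(de, ann2, background = rownames(expr)),
                 "ghost")

  # empty signature direction emits no rows for that direction
  de_null <- moderated_t_test(
    matrix(rnorm(50 * 12), 50, 12,
           dimnames = list(paste0("h", 1:50), paste0("P", 1:12))), grp)
  enr_null <- category_enrichment(
    de_null, data.frame(gene = "h1", category = "c"),
    background = paste0("h", 1:50))
  expect_equal(nrow(enr_null), 0)
})

test_that("null expression data yields calibrated p-values and no discoveries", {
  set.seed(13)
  expr <- matrix(rnorm(10000 * 16), 10000, 16,
                 dimnames = list(paste0("g", 1:10000), paste0("P", 1:16)))
  grp <- setNames(rep(c("short-lived", "long-lived"), each = 8),
                  colnames(expr))
  de <- moderated_t_test(expr, grp)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.01)
  expect_lte(sum(de$q < 0.1), 5)
})

test_that("planted signature genes are recovered at the stated effect size", {
  # effect_size = 2 * noise_sd, groups of 24 and 27
  cfg <- cohort_config(n_patients = 51, group_proportion = 24 / 51,
                       n_genes = 100, background_rate = 0.05,
                       n_expr_genes = 400, n_signature = 40,
                       effect_size = 1, noise_sd = 0.5,
                       n_mirnas = 4, n_host_coupled = 0,
                       network_density = 0.02, seed = 21)
  co <- generate_cohort(cfg)
  de <- moderated_t_test(co$expression, co$true_labels)
  planted <- co$network$regulators  # genes carrying the planted group shift
  hit <- de$feature[de$q < 0.1]
  expect_gte(mean(planted %in% hit), 0.9)
  # logFC on log2 data equals the difference of group means exactly
  g1 <- names(co$true_labels)[co$true_labels == "short-lived"]
  g2 <- names(co$true_labels)[co$true_labels == "long-lived"]
  expect_equal(de$logFC,
               unname(rowMeans(co$expression[, g1]) -
                      rowMeans(co$expression[, g2])),
               tolerance = 1e-12)
})
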
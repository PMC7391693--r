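test_that("lasso path equals soft thresholding under an orthonormal design", {
  set.seed(42)
  n <- 40; p <- 10
  X0 <- matrix(rnorm(n * p), n, p)
  X0 <- scale(X0, center = TRUE, scale = FALSE)
  X <- qr.Q(qr(X0))           # orthonormal columns, still centered
  beta <- c(3, -2, 1.5, rep(0, p - 3))
  y <- drop(X %*% beta) + rnorm(n, 0, 0.2)
  yc <- y - mean(y)
  path <- amlsig:::.lars_lasso(X, yc)
  b <- drop(crossprod(X, yc))
  for (lam in c(0.05, 0.3, 1, 2)) {
    soft <- sign(b) * pmax(abs(b) - lam, 0)
    expect_equal(amlsig:::.lasso_coef_at(path, lam), soft, tolerance = 1e-8)
  }
})

test_that("noiseless single-predictor model is recovered exactly", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 * x[, 1]
  path <- amlsig:::.lars_lasso(scale(x, scale = FALSE), y - mean(y))
  expect_equal(path$final_beta, 2, tolerance = 1e-10)
  ct <- covariance_test(x, y, sigma2 = 1e-6)
  expect_lt(ct$p[1], 1e-10)
})

test_that("lasso path handles drops and correlated designs sanely", {
  set.seed(9)
  n <- 50; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  X[, 2] <- X[, 1] + rnorm(n, 0, 0.3)     # correlated pair
  X <- scale(X)
  y <- drop(X[, 1] - X[, 2] + rnorm(n, 0, 0.5))
  path <- amlsig:::.lars_lasso(scale(X, scale = FALSE), y - mean(y))
  # knots decrease monotonically
  expect_true(all(diff(path$lambda) < 1e-10))
  # the interpolated solution satisfies the KKT bound |x_j' r| <= lambda
  for (lam in c(path$lambda[2] * 0.99, path$lambda[length(path$lambda)] * 1.5)) {
    b <- amlsig:::.lasso_coef_at(path, lam)
    r <- y - mean(y) - drop(scale(X, scale = FALSE) %*% b)
    expect_lte(max(abs(crossprod(scale(X, scale = FALSE), r))),
               lam * (1 + 1e-6))
  }
})

test_that("prepare_predictors excludes the target and zero-fills miRNAs", {
  co <- generate_cohort(small_cohort_config(seed = 4))
  sig <- co$expression[c(co$network$regulators, co$network$targets), ]
  g <- rownames(sig)[3]
  pp <- prepare_predictors(sig, g)
  expect_false(g %in% colnames(pp$X))
  expect_equal(ncol(pp$X), nrow(sig) - 1)

  ppm <- prepare_predictors(sig, g, co$mirna, co$mirna_missing)
  miss <- names(which(co$mirna_missing))
  expect_true(all(ppm$X[miss, rownames(co$mirna)] == 0))
  expect_false(all(ppm$X[!rownames(ppm$X) %in% miss,
                         rownames(co$mirna)] == 0))
})

test_that("training standardization never sees test rows", {
  set.seed(5)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("v", 1:8)))
  train <- 1:45
  std <- amlsig:::.standardize_train(X, train)
  expect_equal(unname(colMeans(std$X[train, ])), rep(0, 8),
               tolerance = 1e-12)
  expect_equal(unname(apply(std$X[train, ], 2, sd)), rep(1, 8),
               tolerance = 1e-12)
  # altering test rows does not change the transform parameters
  X2 <- X; X2[46:60, ] <- X2[46:60, ] + 100
  std2 <- amlsig:::.standardize_train(X2, train)
  expect_equal(std$mu, std2$mu)
  expect_equal(std$sd, std2$sd)
  expect_equal(std$X[train, ], std2$X[train, ])
})

test_that("subsampled network fits are deterministic under a fixed seed", {
  co <- generate_cohort(cohort_config(
    n_patients = 40, group_proportion = 0.5, n_genes = 50,
    background_rate = 0.05, n_expr_genes = 30, n_signature = 8,
    n_mirnas = 4, n_host_coupled = 0, network_density = 0.1, seed = 6))
  sig <- co$expression[c(co$network$regulators, co$network$targets), ]
  nc <- network_config(B = 2, nlambda = 40, seed = 11)
  f1 <- subsample_networks(sig, config = nc)
  f2 <- subsample_networks(sig, config = nc)
  expect_equal(f1[[1]]$links, f2[[1]]$links)
  expect_equal(f1[[2]]$test_r, f2[[2]]$test_r)
})

test_that("consensus thresholding, signs and monotonicity behave", {
  mk_fit <- function(q) list(
    links = data.frame(source = "A", target = "B", coef = 1, p = q, q = q),
    test_r = c(B = 0.9))
  empty_fit <- list(links = data.frame(source = character(),
                                       target = character(),
                                       coef = numeric(), p = numeric(),
                                       q = numeric()),
                    test_r = c(B = NA_real_))
  cfg <- network_config(B = 100)

  # 67 of 100 supporting networks passes, 66 fails (ceiling(200/3) = 67)
  fits67 <- structure(c(replicate(67, mk_fit(0.01), simplify = FALSE),
                        replicate(33, empty_fit, simplify = FALSE)),
                      class = "network_fits", config = cfg, targets = "B")
  expect_equal(nrow(build_consensus(fits67)), 1)
  fits66 <- structure(c(replicate(66, mk_fit(0.01), simplify = FALSE),
                        replicate(34, empty_fit, simplify = FALSE)),
                      class = "network_fits", config = cfg, targets = "B")
  expect_equal(nrow(build_consensus(fits66)), 0)

  # support counts only networks where the link is significant
  fits_q <- structure(c(replicate(66, mk_fit(0.01), simplify = FALSE),
                        replicate(34, mk_fit(0.5), simplify = FALSE)),
                      class = "network_fits", config = cfg, targets = "B")
  expect_equal(nrow(build_consensus(fits_q)), 0)

  # sign = sign of the median coefficient over supporting networks
  mk_coef <- function(co) list(
    links = data.frame(source = "A", target = "B", coef = co, p = 0.01,
                       q = 0.01), test_r = c(B = 0.9))
  fits_sign <- structure(
    c(replicate(40, mk_coef(1), simplify = FALSE),
      replicate(40, mk_coef(1), simplify = FALSE),
      replicate(20, mk_coef(-1), simplify = FALSE)),
    class = "network_fits", config = cfg, targets = "B")
  net <- build_consensus(fits_sign)
  expect_equal(net$sign, "+")
  expect_equal(net$median_coef, 1)

  # raising the consensus fraction never adds links
  cfg_lo <- network_config(B = 100, consensus_fraction = 0.5)
  cfg_hi <- network_config(B = 100, consensus_fraction = 0.9)
  n_lo <- nrow(build_consensus(fits67, cfg_lo))
  n_hi <- nrow(build_consensus(fits67, cfg_hi))
  expect_gte(n_lo, n_hi)

  # empty fits give an empty network
  fits_none <- structure(replicate(5, empty_fit, simplify = FALSE),
                         class = "network_fits",
                         config = network_config(B = 5), targets = "B")
  expect_equal(nrow(build_consensus(fits_none)), 0)
})

test_that("prediction summary covers the degenerate and perfect cases", {
  cfg <- network_config(B = 2)
  empty_fit <- list(links = data.frame(source = character(),
                                       target = character(),
                                       coef = numeric(), p = numeric(),
                                       q = numeric()),
                    test_r = c(g1 = NA_real_, g2 = NA_real_))
  fits_none <- structure(list(empty_fit, empty_fit),
                         class = "network_fits", config = cfg,
                         targets = c("g1", "g2"))
  ps0 <- prediction_summary(fits_none)
  expect_equal(ps0$mean_fraction, 0)
  expect_true(is.na(ps0$mean_correlation))

  perfect <- list(
    links = data.frame(source = c("g2", "g1"), target = c("g1", "g2"),
                       coef = 1, p = 0.001, q = 0.001),
    test_r = c(g1 = 1, g2 = 1))
  fits_all <- structure(list(perfect, perfect), class = "network_fits",
                        config = cfg, targets = c("g1", "g2"))
  ps1 <- prediction_summary(fits_all)
  expect_equal(ps1$mean_fraction, 1)
  expect_equal(ps1$mean_correlation, 1)
})

test_that("modules and regulators are extracted from the link list", {
  net <- structure(
    data.frame(source = c("A", "C"), target = c("B", "D"),
               support = c(70, 70), median_coef = c(1, -1),
               sign = c("+", "-")),
    nodes = c("A", "B", "C", "D"), B = 100,
    class = c("consensus_network", "data.frame"))
  mr <- extract_modules_and_regulators(net)
  expect_length(mr$modules, 2)

  star <- structure(
    data.frame(source = "A", target = c("B", "C", "D"),
               support = 70, median_coef = 1, sign = "+"),
    nodes = c("A", "B", "C", "D"), B = 100,
    class = c("consensus_network", "data.frame"))
  mrs <- extract_modules_and_regulators(star)
  expect_equal(mrs$regulators$node[1], "A")
  expect_equal(mrs$regulators$out_degree[1], 3L)
  expect_length(mrs$modules, 1)

  empty <- structure(
    data.frame(source = character(), target = character(),
               support = integer(), median_coef = numeric(),
               sign = character()),
    nodes = character(), B = 100,
    class = c("consensus_network", "data.frame"))
  expect_length(extract_modules_and_regulators(empty)$modules, 0)
})

test_that("planted sparse networks are recovered by the consensus", {
  cfg <- cohort_config(n_patients = 80, group_proportion = 0.5,
                       n_expr_genes = 60, n_signature = 20,
                       n_mirnas = 5, n_host_coupled = 0, noise_sd = 0.5,
                       network_density = 0.05, seed = 31)
  co <- generate_cohort(cfg)
  sig <- co$expression[c(co$network$regulators, co$network$targets), ]
  fits <- subsample_networks(sig, config = network_config(B = 30,
                                                          nlambda = 50,
                                                          seed = 31))
  net <- build_consensus(fits)
  truth <- planted_edges(co$network)
  tkey <- c(paste(truth$source, truth$target),
            paste(truth$target, truth$source))   # direction unidentifiable
  ikey <- paste(net$source, net$target)
  precision <- mean(ikey %in% tkey)
  recall <- mean(paste(truth$source, truth$target) %in%
                   c(ikey, paste(net$target, net$source)))
  expect_gte(precision, 0.8)
  expect_gte(recall, 0.5)
  # recovered signs match the planted signs
  hit <- net[ikey %in% tkey, ]
  planted_sign <- function(s, t) {
    i <- which((truth$source == s & truth$target == t) |
                 (truth$source == t & truth$target == s))
    sign(truth$weight[i[1]])
  }
  signs_ok <- mapply(function(s, t, sg) sg == ifelse(
    planted_sign(s, t) >= 0, "+", "-"), hit$source, hit$target, hit$sign)
  expect_gte(mean(signs_ok), 0.95)

  ps <- prediction_summary(fits)
  expect_gt(ps$mean_correlation, 0.5)
  expect_lt(ps$wilcoxon_p, 0.001)
})
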
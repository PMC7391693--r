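#' Network-inference configuration
#'
#' @param B number of subsampled networks (default 100).
#' @param train_fraction fraction of patients in each training split
#'   (default 3/4).
#' @param consensus_fraction fraction of the B networks a link must appear
#'   in, with q <= `q_cut`, to enter the consensus (default 2/3).
#' @param q_cut per-network BH q-value cut-off on link significance
#'   (default 0.1).
#' @param nlambda lambda grid size for the cross-validated lasso
#'   (default 100).
#' @param nfolds folds of the inner cross-validation choosing the operating
#'   lambda (default 10).
#' @param include_mirnas add miRNA expression rows as additional predictors
#'   (never as targets).
#' @param sigma_rule tag for the residual-variance rule used by the
#'   covariance test; the single implemented rule estimates sigma^2 from
#'   the residuals of the CV-selected lasso model with df = number of
#'   selected predictors.
#' @param seed integer seed for the subsampling splits.
#' @return object of class `network_config`.
#' @export
network_config <- function(B = 100, train_fraction = 3 / 4,
                           consensus_fraction = 2 / 3, q_cut = 0.1,
                           nlambda = 100, nfolds = 10,
                           include_mirnas = FALSE,
                           sigma_rule = "cv-lasso-residual", seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (consensus_fraction <= 0 || consensus_fraction > 1)
    stop("consensus_fraction must be in (0, 1]")
  if (q_cut <= 0 || q_cut >= 1) stop("q_cut must be in (0, 1)")
  structure(list(B = B, train_fraction = train_fraction,
                 consensus_fraction = consensus_fraction, q_cut = q_cut,
                 nlambda = nlambda, nfolds = nfolds,
                 include_mirnas = include_mirnas, sigma_rule = sigma_rule,
                 seed = as.integer(seed)),
            class = "network_config")
}

# ---------------------------------------------------------------------------
# LASSO path by least-angle regression with the lasso modification.
#
# X: n x p with centered columns; y: centered response.  The path is
# piecewise linear in lambda = max_j |x_j' r|.  Returns the knots (lambda,
# action: +j entry / -j drop), the coefficient matrix at each knot, and the
# active set before each knot's action.
.lars_lasso <- function(X, y, max_steps = 8 * min(dim(X)), eps = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  cvec <- drop(crossprod(X, y))
  lambda_k <- max(abs(cvec))
  out_lambda <- numeric(0); out_action <- integer(0)
  out_beta <- NULL; out_active <- list()
  if (lambda_k < eps)
    return(list(lambda = numeric(0), action = integer(0),
                beta = matrix(0, 0, p), active_before = list(),
                final_lambda = 0, final_beta = beta))
  A <- integer(0)
  rank_cap <- min(n - 1, p)
  step <- 0L
  j_new <- which.max(abs(cvec))

  record <- function(lambda, action, beta, active) {
    out_lambda <<- c(out_lambda, lambda)
    out_action <<- c(out_action, action)
    out_beta <<- rbind(out_beta, beta)
    out_active[[length(out_active) + 1]] <<- active
  }
  record(lambda_k, j_new, beta, A)
  A <- j_new

  while (step < max_steps && lambda_k > eps) {
    step <- step + 1L
    s <- sign(cvec[A])
    G <- crossprod(X[, A, drop = FALSE])
    dA <- tryCatch(solve(G, s), error = function(e) NULL)
    if (is.null(dA)) break
    inact <- setdiff(seq_len(p), A)
    # candidate lambdas where an inactive variable's correlation catches up
    lam_enter <- rep(-Inf, p)
    if (length(inact) && length(A) < rank_cap) {
      a <- drop(crossprod(X[, inact, drop = FALSE],
                          X[, A, drop = FALSE] %*% dA))
      cj <- cvec[inact]
      l1 <- (cj - lambda_k * a) / (1 - a)
      l2 <- (lambda_k * a - cj) / (1 + a)
      l1[!is.finite(l1) | l1 >= lambda_k - eps | l1 < 0] <- -Inf
      l2[!is.finite(l2) | l2 >= lambda_k - eps | l2 < 0] <- -Inf
      lam_enter[inact] <- pmax(l1, l2)
    }
    # candidate lambdas where an active coefficient crosses zero
    lam_drop <- rep(-Inf, p)
    ld <- lambda_k + beta[A] / dA
    ld[!is.finite(ld) | ld >= lambda_k - eps | ld < 0] <- -Inf
    lam_drop[A] <- ld

    lam_next <- max(c(lam_enter, lam_drop, 0))
    # advance the solution to lam_next
    beta[A] <- beta[A] + (lambda_k - lam_next) * dA
    resid <- y - X %*% beta
    cvec <- drop(crossprod(X, resid))
    if (lam_next <= eps) {
      lambda_k <- 0
      break
    }
    if (max(lam_drop) >= max(lam_enter)) {
      j <- which.max(lam_drop)
      record(lam_next, -j, beta, A)
      beta[j] <- 0
      A <- setdiff(A, j)
    } else {
      j <- which.max(lam_enter)
      record(lam_next, j, beta, A)
      A <- c(A, j)
    }
    lambda_k <- lam_next
    if (!length(A)) break
  }
  list(lambda = out_lambda, action = out_action, beta = out_beta,
       active_before = out_active, final_lambda = lambda_k,
       final_beta = beta)
}

# Coefficients of the lasso path at an arbitrary lambda (piecewise-linear
# interpolation between knots; above the first knot the solution is zero).
.lasso_coef_at <- function(path, lambda) {
  p <- ncol(path$beta)
  ks <- c(path$lambda, path$final_lambda)
  B <- rbind(path$beta, path$final_beta)
  if (!length(path$lambda) || lambda >= ks[1]) return(numeric(p))
  if (lambda <= ks[length(ks)]) return(B[nrow(B), ])
  k <- max(which(ks >= lambda))
  w <- (ks[k] - lambda) / (ks[k] - ks[k + 1])
  (1 - w) * B[k, ] + w * B[k + 1, ]
}

#' Covariance test for predictors entering the lasso path
#'
#' The covariance statistic of Lockhart-style path significance testing:
#' for the predictor entering at knot k with next knot lambda_{k+1},
#' `T_k = ( <y, X b(lambda_{k+1})> - <y, X_A b_A(lambda_{k+1})> ) / sigma^2`,
#' where `b` is the full lasso solution, `A` the active set before the
#' entry, and `b_A` the lasso solution restricted to `A`.  Under the null
#' that all signal variables are already active, the statistic of the next
#' entry is asymptotically Exp(1), so `p = exp(-T)`.
#'
#' @param X predictor matrix with centered columns.
#' @param y centered response.
#' @param sigma2 residual variance; if `NULL`, estimated from the
#'   least-squares fit on the largest active set reached by the path.
#' @param max_entries compute statistics for at most this many entry events
#'   (default all).
#' @param max_steps cap on the number of path knots to trace (default full
#'   path; lowering it saves time when only early entries are needed).
#' @return data frame with one row per entry event: `step`, `predictor`
#'   (column index), `lambda`, `statistic`, `p`.
#' @export
covariance_test <- function(X, y, sigma2 = NULL, max_entries = Inf,
                            max_steps = 8 * min(dim(X))) {
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- y - mean(y)
  path <- .lars_lasso(X, y, max_steps = max_steps)
  if (!length(path$lambda))
    return(data.frame(step = integer(), predictor = integer(),
                      lambda = numeric(), statistic = numeric(),
                      p = numeric()))
  if (is.null(sigma2)) {
    A_fin <- which(path$final_beta != 0)
    if (!length(A_fin)) A_fin <- abs(path$action[1])
    fit <- stats::lm.fit(X[, A_fin, drop = FALSE], y)
    df <- max(1, nrow(X) - length(A_fin) - 1)
    sigma2 <- sum(fit$residuals^2) / df
  }
  entries <- which(path$action > 0)
  if (is.finite(max_entries)) entries <- utils::head(entries, max_entries)
  ks <- c(path$lambda, path$final_lambda)
  rows <- lapply(seq_along(entries), function(ii) {
    k <- entries[ii]
    lam_next <- ks[k + 1]
    b_full <- .lasso_coef_at(path, lam_next)
    term_full <- sum(y * (X %*% b_full))
    A <- path$active_before[[k]]
    term_sub <- 0
    if (length(A)) {
      sub <- .lars_lasso(X[, A, drop = FALSE], y)
      b_sub <- .lasso_coef_at(sub, lam_next)
      term_sub <- sum(y * (X[, A, drop = FALSE] %*% b_sub))
    }
    Tk <- (term_full - term_sub) / sigma2
    data.frame(step = ii, predictor = path$action[k], lambda = path$lambda[k],
               statistic = Tk, p = min(1, exp(-max(Tk, 0))))
  })
  do.call(rbind, rows)
}

#' Assemble the predictor matrix for one signature-gene target
#'
#' Predictors are all other signature genes plus, optionally, all miRNAs.
#' miRNA predictor entries are set to zero for patients without an available
#' miRNA profile (miRNAs are only ever predictors, never targets).
#'
#' @param signature_expr signature genes x patients log2 matrix.
#' @param target row name of the target gene.
#' @param mirna_expr optional miRNAs x patients matrix.
#' @param mirna_missing optional named logical vector of patients lacking
#'   the miRNA layer.
#' @return list with `y` (target expression) and `X`
#'   (patients x predictors).
#' @export
prepare_predictors <- function(signature_expr, target, mirna_expr = NULL,
                               mirna_missing = NULL) {
  stopifnot(target %in% rownames(signature_expr))
  patients <- colnames(signature_expr)
  X <- t(signature_expr[setdiff(rownames(signature_expr), target), ,
                        drop = FALSE])
  if (!is.null(mirna_expr)) {
    Xm <- t(mirna_expr[, patients, drop = FALSE])
    if (!is.null(mirna_missing))
      Xm[mirna_missing[patients], ] <- 0
    X <- cbind(X, Xm)
  }
  list(y = signature_expr[target, ], X = X)
}

# Standardize columns using training-row statistics only; constant training
# columns are dropped (returned in `dropped`).
.standardize_train <- function(X, train) {
  mu <- colMeans(X[train, , drop = FALSE])
  sd_ <- apply(X[train, , drop = FALSE], 2, stats::sd)
  keep <- sd_ > 0
  Xs <- sweep(X[, keep, drop = FALSE], 2, mu[keep], "-")
  Xs <- sweep(Xs, 2, sd_[keep], "/")
  list(X = Xs, mu = mu[keep], sd = sd_[keep], dropped = colnames(X)[!keep])
}

#' Fit one sparse gene model with link significance
#'
#' Lasso regression of a signature gene on its predictors: the lasso path
#' is computed, the operating lambda is chosen by inner k-fold
#' cross-validation (minimum CV error), coefficients are reported at that
#' lambda, and each selected predictor receives a covariance-test p-value
#' from its entry step on the path.  The residual variance for the
#' covariance statistic is estimated from the CV-selected model's residuals
#' with df = number of selected predictors.
#'
#' @param y target expression over the training patients.
#' @param X training predictor matrix (columns already standardized).
#' @param config a `network_config`.
#' @return object of class `gene_model_fit`: list with `coefficients`
#'   (named, standardized scale), `pvalues` (named), `intercept`,
#'   `lambda`, `sigma2`, `flagged` (degenerate-target flag).
#' @export
fit_gene_model <- function(y, X, config = network_config()) {
  n <- nrow(X)
  if (stats::sd(y) == 0)
    return(structure(list(coefficients = numeric(0), pvalues = numeric(0),
                          intercept = mean(y), lambda = NA_real_,
                          sigma2 = NA_real_, flagged = TRUE),
                     class = "gene_model_fit"))
  nfolds <- min(config$nfolds, n)
  cv <- glmnet::cv.glmnet(X, y, nfolds = nfolds, nlambda = config$nlambda,
                          standardize = FALSE)
  co <- drop(stats::coef(cv, s = "lambda.min"))
  sel <- which(co[-1] != 0)
  pred <- drop(stats::predict(cv, X, s = "lambda.min"))
  df <- length(sel)
  sigma2 <- sum((y - pred)^2) / max(1, n - df)

  pvals <- setNames(rep(1, length(sel)), colnames(X)[sel])
  if (length(sel)) {
    # the selected set is small; tracing the path a few knots past its size
    # reaches every selected predictor's entry in practice
    ct <- covariance_test(X, y - mean(y), sigma2 = sigma2,
                          max_steps = 3 * length(sel) + 10)
    first_entry <- ct[!duplicated(ct$predictor), ]
    hit <- match(sel, first_entry$predictor)
    pvals[!is.na(hit)] <- first_entry$p[hit[!is.na(hit)]]
  }
  structure(list(coefficients = setNames(co[-1][sel], colnames(X)[sel]),
                 pvalues = pvals, intercept = co[1],
                 lambda = cv$lambda.min, sigma2 = sigma2, flagged = FALSE),
            class = "gene_model_fit")
}

#' Repeated random-subsampling network inference
#'
#' Repeats `B` times: split the patients into a training set
#' (`train_fraction`, default three-quarters) and a test set; standardize
#' predictors on the training split only; fit a sparse lasso model for
#' every signature gene on the training set; predict the test set and
#' record the per-gene Pearson correlation of predicted and measured
#' expression; adjust the covariance-test p-values of all selected links in
#' the network by BH.
#'
#' @param signature_expr signature genes x patients log2 matrix.
#' @param mirna_expr optional miRNAs x patients matrix (used when
#'   `config$include_mirnas`).
#' @param mirna_missing optional named logical of patients lacking the
#'   miRNA layer (their miRNA predictor entries are zero-filled).
#' @param config a `network_config`.
#' @return object of class `network_fits`: list of `B` elements, each with
#'   `links` (data frame `source`, `target`, `coef`, `p`, `q`) and
#'   `test_r` (named per-gene test correlation); attributes `config` and
#'   `targets`.
#' @export
subsample_networks <- function(signature_expr, mirna_expr = NULL,
                               mirna_missing = NULL,
                               config = network_config()) {
  patients <- colnames(signature_expr)
  n <- length(patients)
  n_train <- round(config$train_fraction * n)
  if (n_train < 5) stop("training split would have fewer than 5 patients")
  if (n_train >= n) stop("test split is empty")
  targets <- rownames(signature_expr)
  if (!config$include_mirnas) mirna_expr <- NULL

  prepared <- lapply(targets, function(g)
    prepare_predictors(signature_expr, g, mirna_expr, mirna_missing))
  names(prepared) <- targets

  set.seed(config$seed)
  fits <- vector("list", config$B)
  for (b in seq_len(config$B)) {
    train <- sort(sample.int(n, n_train))
    test <- setdiff(seq_len(n), train)
    links <- list()
    test_r <- setNames(rep(NA_real_, length(targets)), targets)
    for (g in targets) {
      y <- prepared[[g]]$y
      std <- .standardize_train(prepared[[g]]$X, train)
      if (!ncol(std$X)) next
      fit <- fit_gene_model(y[train], std$X[train, , drop = FALSE], config)
      if (length(fit$coefficients)) {
        links[[g]] <- data.frame(
          source = names(fit$coefficients), target = g,
          coef = unname(fit$coefficients), p = unname(fit$pvalues))
        pred <- fit$intercept +
          drop(std$X[test, names(fit$coefficients), drop = FALSE] %*%
                 fit$coefficients)
        if (stats::sd(pred) > 0 && stats::sd(y[test]) > 0)
          test_r[g] <- stats::cor(pred, y[test])
      }
    }
    links <- if (length(links)) do.call(rbind, links) else
      data.frame(source = character(), target = character(),
                 coef = numeric(), p = numeric())
    links$q <- if (nrow(links)) bh_adjust(links$p) else numeric(0)
    rownames(links) <- NULL
    fits[[b]] <- list(links = links, test_r = test_r)
  }
  structure(fits, class = "network_fits", config = config, targets = targets)
}

#' Build the consensus network from subsampled fits
#'
#' A link enters the consensus iff it was selected with q <= `q_cut` in at
#' least `ceiling(consensus_fraction * B)` of the B networks.  The link sign
#' is the sign of the median coefficient over its supporting networks.
#' Links can represent direct or indirect regulatory dependencies or may
#' only reflect correlations; the method is correlation-based.
#'
#' @param fits a `network_fits` object.
#' @param config a `network_config` (defaults to the one stored in `fits`).
#' @return object of class `consensus_network`: data frame with columns
#'   `source`, `target`, `support`, `median_coef`, `sign`; attribute
#'   `nodes`.
#' @export
build_consensus <- function(fits, config = attr(fits, "config")) {
  B <- length(fits)
  need <- ceiling(config$consensus_fraction * B)
  all_links <- do.call(rbind, lapply(fits, function(f)
    f$links[f$links$q <= config$q_cut, , drop = FALSE]))
  if (is.null(all_links) || !nrow(all_links)) {
    out <- data.frame(source = character(), target = character(),
                      support = integer(), median_coef = numeric(),
                      sign = character())
    attr(out, "nodes") <- character(0)
    attr(out, "B") <- B
    class(out) <- c("consensus_network", "data.frame")
    return(out)
  }
  key <- paste(all_links$source, all_links$target, sep = "\r")
  support <- table(key)
  keep <- names(support)[support >= need]
  rows <- lapply(keep, function(k) {
    sub <- all_links[key == k, ]
    med <- stats::median(sub$coef)
    data.frame(source = sub$source[1], target = sub$target[1],
               support = as.integer(support[[k]]), median_coef = med,
               sign = if (med >= 0) "+" else "-")
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               support = integer(), median_coef = numeric(),
               sign = character())
  out <- out[order(-out$support), ]
  rownames(out) <- NULL
  attr(out, "nodes") <- unique(c(out$source, out$target))
  attr(out, "B") <- B
  class(out) <- c("consensus_network", "data.frame")
  out
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("Consensus regulatory network: %d links among %d nodes (B = %d)\n",
              nrow(x), length(attr(x, "nodes")), attr(x, "B")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Prediction-accuracy summary over the subsampled networks
#'
#' A gene counts as predictable in a network iff its model retains at least
#' one link at q <= `q_cut`.  Reports the per-network fraction of
#' predictable genes (and its mean), the test-set correlations of
#' predictable gene-network pairs (and their mean), and a one-sample
#' Wilcoxon signed-rank test of those correlations against zero.
#'
#' @param fits a `network_fits` object.
#' @param config a `network_config` (defaults to the one stored in `fits`).
#' @return object of class `prediction_accuracy`: list with
#'   `fraction_predictable` (per network), `mean_fraction`,
#'   `correlations`, `mean_correlation` (`NA` if no gene was ever
#'   predictable), `wilcoxon_p`.
#' @export
prediction_summary <- function(fits, config = attr(fits, "config")) {
  targets <- attr(fits, "targets")
  frac <- numeric(length(fits))
  cors <- numeric(0)
  for (b in seq_along(fits)) {
    f <- fits[[b]]
    ok <- unique(f$links$target[f$links$q <= config$q_cut])
    frac[b] <- length(ok) / length(targets)
    cors <- c(cors, f$test_r[ok])
  }
  cors <- cors[!is.na(cors)]
  wp <- if (length(cors) >= 1 && stats::sd(cors) > 0)
    suppressWarnings(stats::wilcox.test(cors, mu = 0,
                                        alternative = "greater")$p.value)
  else NA_real_
  structure(list(fraction_predictable = frac, mean_fraction = mean(frac),
                 correlations = cors,
                 mean_correlation = if (length(cors)) mean(cors) else NA_real_,
                 wilcoxon_p = wp),
            class = "prediction_accuracy")
}

#' @export
print.prediction_accuracy <- function(x, ...) {
  cat(sprintf("Predictable genes: %.1f%% of targets on average\n",
              100 * x$mean_fraction))
  cat(sprintf("Mean test correlation of predictable genes: %s (Wilcoxon p = %.3g)\n",
              ifelse(is.na(x$mean_correlation), "NA",
                     sprintf("%.3f", x$mean_correlation)), x$wilcoxon_p))
  invisible(x)
}

#' Modules and major regulators of a consensus network
#'
#' Weakly connected components are the network modules; regulators are
#' nodes with out-degree > 0, ranked by out-degree (descending).
#'
#' @param net a `consensus_network`.
#' @return list with `modules` (list of node-id vectors, largest first) and
#'   `regulators` (data frame `node`, `out_degree`).
#' @export
extract_modules_and_regulators <- function(net) {
  if (!nrow(net))
    return(list(modules = list(),
                regulators = data.frame(node = character(),
                                        out_degree = integer())))
  g <- igraph::graph_from_data_frame(net[, c("source", "target")],
                                     directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  modules <- split(names(comp$membership), comp$membership)
  modules <- modules[order(-vapply(modules, length, 1L))]
  names(modules) <- NULL
  outd <- igraph::degree(g, mode = "out")
  regulators <- data.frame(node = names(outd), out_degree = as.integer(outd),
                           row.names = NULL)
  regulators <- regulators[regulators$out_degree > 0, ]
  regulators <- regulators[order(-regulators$out_degree), ]
  rownames(regulators) <- NULL
  list(modules = modules, regulators = regulators)
}
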
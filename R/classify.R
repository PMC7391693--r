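#' Nearest-neighbor classification on binary mutation profiles
#'
#' Each query patient is assigned the subgroup label of the reference
#' patient with the smallest Hamming mismatch count over the shared gene
#' panel.  Ties among co-minimal references are resolved by the majority
#' label; a residual tie is assigned `long-lived` (the conservative choice,
#' avoiding inflation of the poor-prognosis group) with the tie flag set.
#'
#' @param queries binary mutation matrix of the patients to classify
#'   (patients x genes).
#' @param reference binary mutation matrix of the labeled reference cohort.
#' @param labels named vector reference patient ->
#'   `"short-lived"`/`"long-lived"`.
#' @param panel non-empty character vector of genes present in both
#'   matrices (the distance support).
#' @return object of class `classification_result`: data frame with
#'   `patient_id`, `label`, `distance`, `tie`.
#' @export
mutation_nn_classify <- function(queries, reference, labels, panel) {
  if (!length(panel)) stop("empty gene panel")
  if (!all(panel %in% colnames(queries)) ||
      !all(panel %in% colnames(reference)))
    stop("panel genes missing from query or reference matrix")
  if (length(unique(labels[rownames(reference)])) < 2)
    stop("reference must contain both labels")
  Q <- unclass(queries)[, panel, drop = FALSE]
  R <- unclass(reference)[, panel, drop = FALSE]
  # mismatch count: q(1-r) + (1-q)r
  D <- Q %*% t(1 - R) + (1 - Q) %*% t(R)
  out <- lapply(seq_len(nrow(Q)), function(i) {
    d <- D[i, ]
    nn <- which(d == min(d))
    lab <- labels[rownames(R)[nn]]
    tab <- table(lab)
    tie <- length(tab) > 1 && length(unique(tab)) == 1
    label <- if (tie) "long-lived" else names(which.max(tab))
    data.frame(patient_id = rownames(Q)[i], label = label,
               distance = min(d), tie = tie)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("classification_result", "data.frame")
  out
}

#' Kendall-tau nearest-centroid classification on the expression signature
#'
#' The short- and long-lived centroids are the per-gene mean signature
#' expression over the labeled reference patients.  Each query patient is
#' assigned the label of the centroid with the larger Kendall tau-b rank
#' correlation to its signature profile (tie-corrected tau, invariant to
#' strictly increasing per-patient transforms).  Queries must cover at
#' least `min_coverage` of the signature genes.
#'
#' @param queries expression matrix of the patients to classify
#'   (genes x patients; any subset of the signature genes in rows).
#' @param reference signature expression matrix of the labeled reference
#'   cohort (signature genes x patients).
#' @param labels named vector reference patient ->
#'   `"short-lived"`/`"long-lived"`.
#' @param min_coverage minimum fraction of signature genes the queries must
#'   cover (default 0.8).
#' @return object of class `classification_result`: data frame with
#'   `patient_id`, `label`, `tau_short`, `tau_long`, `tie`.
#' @export
expression_centroid_classify <- function(queries, reference, labels,
                                         min_coverage = 0.8) {
  signature <- rownames(reference)
  shared <- intersect(signature, rownames(queries))
  if (length(shared) < min_coverage * length(signature))
    stop("queries cover only ", length(shared), " of ", length(signature),
         " signature genes; missing: ",
         paste(utils::head(setdiff(signature, shared), 10), collapse = ", "))
  labels <- labels[colnames(reference)]
  if (length(unique(labels)) < 2) stop("reference must contain both labels")
  cen_short <- rowMeans(reference[shared, labels == "short-lived",
                                  drop = FALSE])
  cen_long <- rowMeans(reference[shared, labels == "long-lived",
                                 drop = FALSE])
  out <- lapply(colnames(queries), function(pid) {
    prof <- queries[shared, pid]
    ts <- stats::cor(prof, cen_short, method = "kendall")
    tl <- stats::cor(prof, cen_long, method = "kendall")
    tie <- isTRUE(all.equal(ts, tl))
    label <- if (tie || tl > ts) "long-lived" else "short-lived"
    data.frame(patient_id = pid, label = label, tau_short = ts,
               tau_long = tl, tie = tie)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("classification_result", "data.frame")
  out
}

#' @export
print.classification_result <- function(x, ...) {
  n <- table(x$label)
  cat("Transfer classification of", nrow(x), "patients:",
      paste(sprintf("%s = %d", names(n), n), collapse = ", "), "\n")
  if (any(x$tie)) cat(" ", sum(x$tie), "tie(s) resolved to long-lived\n")
  invisible(x)
}

#' Survival validation of a transfer classification
#'
#' Log-rank test of the assigned labels against the independent cohort's
#' survival.
#'
#' @param result a `classification_result`.
#' @param surv a `survival_table` for the classified patients.
#' @return a `logrank_result`.
#' @export
validate_by_survival <- function(result, surv) {
  labels <- setNames(result$label, result$patient_id)
  if (length(unique(labels)) < 2)
    stop("all patients assigned to a single group; no survival comparison")
  logrank_test(surv, labels)
}

#' Substratification of ELN risk categories by assigned labels
#'
#' Within each ELN risk category, tests (log-rank) whether the assigned
#' short-/long-lived labels further separate survival.  Categories with
#' fewer than `min_n` patients, or without at least one event per assigned
#' label, are reported descriptively without a test.
#'
#' @param result a `classification_result`.
#' @param surv a `survival_table` with an `eln_category` column.
#' @param min_n minimum category size for testing (default 5).
#' @return named list per category: either a `logrank_result` (plus counts)
#'   or a descriptive summary with `tested = FALSE`.
#' @export
eln_substratify <- function(result, surv, min_n = 5) {
  if (!"eln_category" %in% names(surv))
    stop("survival table lacks an eln_category column")
  labels <- setNames(result$label, result$patient_id)
  surv <- surv[surv$patient_id %in% names(labels), , drop = FALSE]
  cats <- sort(unique(surv$eln_category))
  out <- lapply(cats, function(cc) {
    sub <- surv[surv$eln_category == cc, , drop = FALSE]
    lab <- labels[sub$patient_id]
    counts <- table(factor(lab, c("short-lived", "long-lived")))
    events <- tapply(sub$event, factor(lab, c("short-lived", "long-lived")),
                     sum)
    testable <- nrow(sub) >= min_n && all(counts > 0) &&
      all(!is.na(events)) && all(events >= 1)
    if (testable) {
      lr <- logrank_test(sub, lab)
      list(category = cc, n = nrow(sub), counts = counts, events = events,
           tested = TRUE, logrank = lr, p = lr$p)
    } else {
      list(category = cc, n = nrow(sub), counts = counts, events = events,
           tested = FALSE, p = NA_real_)
    }
  })
  names(out) <- cats
  out
}
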
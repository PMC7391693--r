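#' Phi-coefficient distance between binary mutation profiles
#'
#' Pairwise distance `1 - phi` between patient rows of a binary mutation
#' matrix, where phi is the Pearson correlation of two binary variables.
#' Distances range from 0 (identical profiles) to 2 (complementary profiles).
#' A patient whose profile is constant (all 0 or all 1) has no defined
#' correlation and raises an error naming the patient.
#'
#' @param M binary matrix, patients in rows.
#' @return symmetric numeric matrix of distances with zero diagonal.
#' @export
phi_distance_matrix <- function(M) {
  M <- unclass(M)
  if (!all(M %in% c(0, 1))) stop("mutation matrix must be binary 0/1")
  if (nrow(M) < 2) stop("need at least two patients")
  v <- apply(M, 1, stats::sd)
  if (any(v == 0)) {
    who <- rownames(M)[v == 0]
    if (is.null(who)) who <- which(v == 0)
    stop("constant mutation profile (correlation undefined) for patient(s): ",
         paste(who, collapse = ", "))
  }
  D <- 1 - stats::cor(t(M))
  diag(D) <- 0
  D
}

#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward.D2 criterion: the Lance-Williams
#' recurrence applied to squared dissimilarities, with merge heights reported
#' on the original scale.  Thin wrapper over [stats::hclust()] kept as the
#' single clustering entry point so mutation and expression grouping share
#' one code path.
#'
#' @param D symmetric distance matrix or `dist` object.
#' @return an `hclust` tree.
#' @export
ward_cluster <- function(D) {
  d <- stats::as.dist(D)
  if (any(!is.finite(d))) stop("non-finite distances")
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into k groups
#'
#' Returns the k clusters present immediately below the (k-1) highest merges.
#'
#' @param dend an `hclust` tree.
#' @param k number of groups, `1 <= k <= n`.
#' @return named integer vector patient -> group in `1..k`.
#' @export
cut_k_groups <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of patients (", n, ")")
  stats::cutree(dend, k = k)
}

#' Label two patient groups as short-/long-lived by survival
#'
#' The group with the smaller Kaplan-Meier restricted-mean survival time
#' (restricted to the latest observed time) is labeled `short-lived`.  An
#' exact tie is broken toward the smaller group index and flagged in the
#' provenance.
#'
#' @param groups named vector patient -> group index (two groups).
#' @param surv a `survival_table` covering at least part of each group.
#' @return object of class `subgroup_assignment`: list with `labels` (named
#'   character vector patient -> `"short-lived"`/`"long-lived"`) and
#'   `provenance` (distance, linkage, cut level, per-group RMST, tie flag).
#' @export
label_by_survival <- function(groups, surv) {
  idx <- sort(unique(groups))
  if (length(idx) != 2) stop("expected exactly two groups")
  surv <- surv[surv$patient_id %in% names(groups), , drop = FALSE]
  g <- groups[surv$patient_id]
  if (!all(idx %in% g))
    stop("missing survival data for an entire group")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ g)
  tab <- summary(fit, rmean = max(surv$time))$table
  rmean <- tab[, grep("rmean$", colnames(tab))[1]]
  names(rmean) <- sub("^g=", "", rownames(tab))
  rmean <- rmean[as.character(idx)]
  tie <- isTRUE(all.equal(rmean[[1]], rmean[[2]]))
  short <- if (tie) idx[1] else idx[which.min(rmean)]
  labels <- ifelse(groups == short, "short-lived", "long-lived")
  names(labels) <- names(groups)
  structure(list(
    labels = labels,
    provenance = list(distance = "1 - phi", linkage = "ward.D2", k = 2,
                      rmst = rmean, short_group = short, tie = tie)
  ), class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  n <- table(x$labels)
  cat("Subgroup assignment (", x$provenance$distance, ", ",
      x$provenance$linkage, ")\n", sep = "")
  cat("  short-lived:", n[["short-lived"]],
      " long-lived:", n[["long-lived"]], "\n")
  cat("  restricted-mean survival:",
      paste(sprintf("group %s = %.1f", names(x$provenance$rmst),
                    x$provenance$rmst), collapse = ", "), "days\n")
  if (x$provenance$tie) cat("  (tie broken toward smaller group index)\n")
  invisible(x)
}

#' Summarize subgroup mutation composition
#'
#' Per-group gene mutation counts, per-patient mutated-gene counts and their
#' group medians, and (when hotspot status is supplied) the hotspot
#' composition of each subgroup.
#'
#' @param M binary mutation matrix (patients x genes).
#' @param assignment a `subgroup_assignment` (or named label vector).
#' @param surv optional `survival_table`, carried through for reporting.
#' @param r882_status optional named vector from [extract_r882_status()].
#' @return list with `gene_counts` (gene x group matrix), `patient_counts`,
#'   `median_mutated` (per group) and optionally `r882_composition`.
#' @export
subgroup_summary <- function(M, assignment, surv = NULL, r882_status = NULL) {
  labels <- if (inherits(assignment, "subgroup_assignment"))
    assignment$labels else assignment
  labels <- labels[rownames(M)]
  if (anyNA(labels)) stop("assignment does not cover all patients in the matrix")
  groups <- sort(unique(labels))
  gene_counts <- sapply(groups, function(g)
    colSums(M[labels == g, , drop = FALSE]))
  patient_counts <- rowSums(M)
  median_mutated <- sapply(groups, function(g)
    stats::median(patient_counts[labels == g]))
  out <- list(gene_counts = gene_counts, patient_counts = patient_counts,
              median_mutated = median_mutated, group_sizes = table(labels))
  if (!is.null(r882_status))
    out$r882_composition <- table(labels, r882_status[names(labels)])
  out
}
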
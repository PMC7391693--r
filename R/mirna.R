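#' Differential miRNA expression between subgroups
#'
#' Delegates to [moderated_t_test()] after excluding patients lacking the
#' miRNA layer.
#'
#' @param mirna_expr log2 miRNA expression matrix (miRNAs x patients).
#' @param groups named vector patient -> subgroup label.
#' @param missing optional named logical vector flagging patients without a
#'   usable miRNA profile; flagged patients are excluded.
#' @return a `de_result` over the profiled patients.
#' @export
mirna_de <- function(mirna_expr, groups, missing = NULL) {
  if (!is.null(missing)) {
    keep <- colnames(mirna_expr)[!missing[colnames(mirna_expr)]]
    mirna_expr <- mirna_expr[, keep, drop = FALSE]
  }
  moderated_t_test(mirna_expr, groups)
}

#' miRNA to host-gene coexpression categorization
#'
#' Pearson correlation of each miRNA with its host gene over the shared
#' patients, tested one-sided for positive association (t transform on n - 2
#' degrees of freedom) with BH adjustment across the miRNAs that have a host.
#' Hostless (intergenic) miRNAs are reported with r = 0 and category
#' `no-host` as a display convention; they are not part of the testing
#' family.  A miRNA is `host-coexpressed` iff q < `q_cut`, otherwise
#' `independent`.
#'
#' @param mirna_expr miRNAs x patients log2 matrix.
#' @param gene_expr genes x patients log2 matrix.
#' @param host_map named character vector miRNA -> host gene (`NA` for
#'   intergenic miRNAs).
#' @param missing optional named logical vector of patients lacking the
#'   miRNA layer (excluded from the correlation).
#' @param q_cut coexpression cut-off on the BH q-value (default 0.1).
#' @param alternative `"greater"` (default, positive coexpression) or
#'   `"two.sided"`.
#' @return data frame with columns `mirna`, `host`, `r`, `p`, `q`,
#'   `category`.
#' @export
host_correlation <- function(mirna_expr, gene_expr, host_map, missing = NULL,
                             q_cut = 0.1,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  shared <- intersect(colnames(mirna_expr), colnames(gene_expr))
  if (!is.null(missing))
    shared <- shared[!missing[shared]]
  if (!length(shared)) stop("no shared patients between miRNA and gene layers")
  n <- length(shared)

  mirnas <- rownames(mirna_expr)
  host <- host_map[mirnas]
  r <- rep(0, length(mirnas))
  p <- rep(NA_real_, length(mirnas))
  category <- rep("no-host", length(mirnas))
  testable <- !is.na(host) & host %in% rownames(gene_expr)
  lost <- !is.na(host) & !testable
  if (any(lost))
    warning(sum(lost), " miRNA host gene(s) absent from the expression",
            " matrix; reported as no-host")
  for (i in which(testable)) {
    ri <- stats::cor(mirna_expr[mirnas[i], shared], gene_expr[host[i], shared])
    tstat <- ri * sqrt(n - 2) / sqrt(1 - ri^2)
    pi <- stats::pt(tstat, n - 2, lower.tail = FALSE)
    if (alternative == "two.sided") pi <- 2 * min(pi, 1 - pi)
    r[i] <- ri
    p[i] <- pi
  }
  q <- rep(NA_real_, length(mirnas))
  q[testable] <- bh_adjust(p[testable])
  category[testable] <- ifelse(q[testable] < q_cut, "host-coexpressed",
                               "independent")
  data.frame(mirna = mirnas, host = ifelse(testable, host, NA_character_),
             r = r, p = p, q = q, category = category, row.names = NULL)
}
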
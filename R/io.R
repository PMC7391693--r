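#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

# Column-name synonyms accepted for MAF-lite input.
.maf_synonyms <- c(
  Tumor_Sample_Barcode = "patient_id",
  Hugo_Symbol          = "gene",
  Variant_Classification = "variant_class",
  HGVSp_Short          = "protein_change",
  Protein_Change       = "protein_change"
)

#' Read a mutation table (MAF-lite TSV)
#'
#' Reads a tab-separated table of somatic mutation calls with one row per
#' (patient, gene, variant) record.  Canonical column names are
#' `patient_id`, `gene`, `variant_class` and `protein_change`; the common MAF
#' spellings (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`,
#' `HGVSp_Short`/`Protein_Change`) are mapped automatically.  Duplicate
#' (patient, gene) rows are retained; they collapse on binarization.
#'
#' @param path path to a TSV file with a header row.
#' @return a data frame of class `mutation_table` with columns `patient_id`,
#'   `gene`, `variant_class`, `protein_change` (missing optional columns are
#'   filled with `NA`).
#' @seealso [binarize_mutations()], [extract_r882_status()]
#' @export
read_mutation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  hit <- names(df) %in% names(.maf_synonyms)
  names(df)[hit] <- .maf_synonyms[names(df)[hit]]
  as_mutation_table(df)
}

#' Construct a mutation table from a data frame
#'
#' @param df data frame with at least `patient_id` and `gene` columns.
#' @return a `mutation_table` data frame.
#' @export
as_mutation_table <- function(df) {
  need <- c("patient_id", "gene")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("mutation table lacks mandatory column(s): ",
         paste(missing, collapse = ", "),
         " (expected headers: patient_id, gene, variant_class, protein_change",
         " or their MAF synonyms)")
  for (opt in c("variant_class", "protein_change"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  df <- df[, c("patient_id", "gene", "variant_class", "protein_change")]
  df$patient_id <- as.character(df$patient_id)
  df$gene <- as.character(df$gene)
  if (any(!nzchar(df$patient_id)) || any(!nzchar(df$gene)))
    stop("mutation table contains empty patient_id or gene values")
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Write a mutation table as TSV
#'
#' @param table a `mutation_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (features x patients TSV)
#'
#' The first column holds feature identifiers; remaining columns are patients.
#' Missing values are a hard error: the pipeline has no imputation step (the
#' only zero-fill is the miRNA predictor convention in network inference).
#'
#' @param path TSV file path.
#' @param scale `"log2"` for normalized log2 expression, `"counts"` for raw
#'   counts; stored as the `"scale"` attribute.
#' @return numeric matrix (features x patients) with a `scale` attribute.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicated feature ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicated patient columns in ", path)
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (anyNA(m)) stop("missing values in expression matrix ", path,
                     " are not allowed")
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix as TSV
#'
#' @param m features x patients matrix with row and column names.
#' @param path output file path.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' @param path TSV with columns `patient_id`, `time` (days), `event` (0/1) and
#'   optionally `eln_category`.
#' @return data frame of class `survival_table`.
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_survival_table(df)
}

#' Construct a survival table from a data frame
#'
#' @param df data frame with `patient_id`, `time`, `event` and optional
#'   `eln_category` columns.
#' @return data frame of class `survival_table`.
#' @export
as_survival_table <- function(df) {
  need <- c("patient_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("survival table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$time < 0)) stop("negative follow-up times")
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0/1")
  df$patient_id <- as.character(df$patient_id)
  keep <- c(need, intersect("eln_category", names(df)))
  df <- df[, keep]
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write a survival table as TSV
#' @param table a `survival_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Many-to-many table mapping genes to functional categories (transcription
#' factors, oncogenes, pathway names, ...).
#'
#' @param path TSV with `gene` and `category` columns.
#' @return data frame with columns `gene`, `category`.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("gene", "category"), names(df))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  df[, c("gene", "category")]
}

#' Binarize mutation records into a patient x gene incidence matrix
#'
#' An entry is 1 iff at least one record exists for that (patient, gene) pair;
#' duplicate records collapse.  When `gene_panel` is given the matrix is
#' restricted to those genes; patients with no mutation on the panel are kept
#' as all-zero rows.
#'
#' @param table a `mutation_table`.
#' @param gene_panel optional character vector of genes to restrict to.
#' @return binary matrix (patients x genes) of class `aml_mutation_matrix`.
#' @export
binarize_mutations <- function(table, gene_panel = NULL) {
  if (!nrow(table)) stop("empty mutation table")
  patients <- sort(unique(table$patient_id))
  genes <- sort(unique(table$gene))
  if (!is.null(gene_panel)) {
    genes <- intersect(gene_panel, genes)
    if (!length(genes))
      stop("gene panel has no overlap with mutated genes in the table")
    table <- table[table$gene %in% genes, , drop = FALSE]
  }
  M <- matrix(0L, length(patients), length(genes),
              dimnames = list(patients, genes))
  M[cbind(match(table$patient_id, patients), match(table$gene, genes))] <- 1L
  class(M) <- c("aml_mutation_matrix", class(M))
  M
}

#' Align multiple data layers on their common patients
#'
#' Intersects the patient id sets of all layers and reorders every layer to
#' the same (sorted) patient order.  Layers may be: a `survival_table` or any
#' data frame with a `patient_id` column (rows subset), an
#' `aml_mutation_matrix` (patients in rows), or any other matrix
#' (patients in columns, the features-x-patients convention).
#'
#' @param ... named layers.
#' @return named list of aligned layers; attribute `"dropped"` lists the
#'   patient ids removed from each layer.
#' @export
align_cohort <- function(...) {
  layers <- list(...)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  ids <- lapply(layers, .patient_ids)
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no patients common to all layers")
  common <- sort(common)
  dropped <- lapply(ids, function(x) setdiff(x, common))
  out <- Map(.subset_patients, layers, list(common))
  attr(out, "dropped") <- dropped
  out
}

.patient_ids <- function(layer) {
  if (is.data.frame(layer)) {
    if (!"patient_id" %in% names(layer))
      stop("data-frame layer lacks a patient_id column")
    layer$patient_id
  } else if (inherits(layer, "aml_mutation_matrix")) {
    rownames(layer)
  } else if (is.matrix(layer)) {
    colnames(layer)
  } else stop("unsupported layer type: ", class(layer)[1])
}

.subset_patients <- function(layer, ids) {
  if (is.data.frame(layer)) {
    layer[match(ids, layer$patient_id), , drop = FALSE]
  } else if (inherits(layer, "aml_mutation_matrix")) {
    layer[ids, , drop = FALSE]
  } else {
    sc <- attr(layer, "scale")
    out <- layer[, ids, drop = FALSE]
    attr(out, "scale") <- sc
    out
  }
}

#' Classify patients by hotspot codon status of a gene
#'
#' Parses `protein_change` strings of the `<ref><codon><alt>` convention
#' (optional `p.` prefix; frameshift/splice suffixes tolerated; codon = first
#' integer run) and classifies each patient carrying the gene as `R882` if any
#' record hits codon 882, `non-R882` if mutated but never at 882, and
#' `wildtype` otherwise.  Records whose protein change cannot be parsed are
#' skipped with a warning, never silently classified.
#'
#' @param table a `mutation_table` covering the cohort.
#' @param gene gene symbol to inspect (default `"DNMT3A"`).
#' @param codon hotspot codon number (default 882).
#' @return named character vector patient -> `{"R882","non-R882","wildtype"}`
#'   over all patients in `table`.
#' @export
extract_r882_status <- function(table, gene = "DNMT3A", codon = 882L) {
  patients <- sort(unique(table$patient_id))
  status <- setNames(rep("wildtype", length(patients)), patients)
  rec <- table[table$gene == gene, , drop = FALSE]
  if (nrow(rec)) {
    codons <- .parse_codon(rec$protein_change)
    bad <- is.na(codons) & !is.na(rec$protein_change) & nzchar(rec$protein_change)
    if (any(bad))
      warning(sum(bad), " unparseable protein_change record(s) for ", gene,
              " skipped: ", paste(head(rec$protein_change[bad], 5), collapse = ", "))
    mutated <- unique(rec$patient_id)
    status[mutated] <- "non-R882"
    hot <- unique(rec$patient_id[!is.na(codons) & codons == codon])
    status[hot] <- paste0("R", codon)
  }
  status
}

.parse_codon <- function(pc) {
  pc <- sub("^p\\.", "", as.character(pc))
  m <- regmatches(pc, regexpr("[0-9]+", pc))
  out <- rep(NA_integer_, length(pc))
  out[regexpr("[0-9]+", pc) > 0] <- as.integer(m)
  out
}
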
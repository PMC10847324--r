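#' Construct a UMI count matrix
#'
#' The entry point of the pipeline: a genes x cells matrix of non-negative
#' integer UMI counts with unique gene and cell identifiers. Stored as a
#' sparse [Matrix::dgCMatrix] with dimnames.
#'
#' @param values numeric matrix or Matrix, genes in rows, cells in columns.
#'   All entries must be non-negative integers.
#' @param gene_ids,cell_ids character vectors of unique identifiers. Taken
#'   from `dimnames(values)` when omitted.
#' @return an object of class `CountMatrix` (a `dgCMatrix` subclassed by an
#'   S3 wrapper is avoided; we keep a plain sparse matrix with a class
#'   attribute-free contract and validate on construction).
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  m <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (as arguments or dimnames)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(m) || length(cell_ids) != ncol(m))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("validation error: duplicate gene_ids: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 3), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("validation error: duplicate cell_ids: ",
         paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  validate_counts(m)
  dimnames(m) <- list(gene_ids, cell_ids)
  m
}

# counts must be >= 0 and integral
validate_counts <- function(m) {
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x)) {
    if (any(x < 0))
      stop("validation error: negative counts present")
    if (any(x != round(x)))
      stop("validation error: non-integral counts present")
  }
  invisible(m)
}

#' Per-cell metadata table
#'
#' One row per cell: sample of origin, tumor site, histotype and the
#' enrichment protocol applied before profiling. Cluster, assigned cell type
#' and label columns (`cycle_phase`, `subtype`, `outcome`) are appended by
#' downstream stages and may hold `"NA"`/`NA`.
#'
#' @param cell_id,sample_id character vectors, one entry per cell.
#' @param site `"primary"` or `"metastatic"`, recycled if length 1.
#' @param histotype character, recycled if length 1.
#' @param enrichment one of `"none"`, `"cd45"`, `"tumor"`, `"non_tumor"`.
#' @return a `data.frame` of class `CellTable`.
#' @export
cell_table <- function(cell_id, sample_id, site = "primary",
                       histotype = "unknown", enrichment = "none") {
  n <- length(cell_id)
  tab <- data.frame(cell_id = as.character(cell_id),
                    sample_id = rep_len(as.character(sample_id), n),
                    site = rep_len(as.character(site), n),
                    histotype = rep_len(as.character(histotype), n),
                    enrichment = rep_len(as.character(enrichment), n),
                    stringsAsFactors = FALSE)
  validate_cell_table(tab)
}

validate_cell_table <- function(tab) {
  req <- c("cell_id", "sample_id", "site")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("schema error: missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$cell_id))
    stop("validation error: duplicate cell_id in cell table")
  if (!all(tab$site %in% c("primary", "metastatic")))
    stop("validation error: site must be 'primary' or 'metastatic'")
  if (!is.null(tab$enrichment) &&
      !all(tab$enrichment %in% c("none", "cd45", "tumor", "non_tumor")))
    stop("validation error: enrichment must be none/cd45/tumor/non_tumor")
  class(tab) <- c("CellTable", "data.frame")
  tab
}

#' Named gene signature set
#'
#' A collection of gene lists under one name, e.g. the three cell-cycle
#' phases or the four molecular subtypes.
#'
#' @param name character scalar naming the set.
#' @param signatures named list of character vectors (label -> gene ids).
#' @return object of class `GeneSignatureSet`.
#' @export
signature_set <- function(name, signatures) {
  if (is.null(names(signatures)) || any(names(signatures) == ""))
    stop("signatures must be a named list")
  for (lab in names(signatures)) {
    g <- signatures[[lab]]
    if (!length(g)) stop("signature '", lab, "' is empty")
    if (anyDuplicated(g)) stop("signature '", lab, "' has duplicate genes")
  }
  structure(list(name = name, signatures = lapply(signatures, as.character)),
            class = "GeneSignatureSet")
}

#' @export
print.GeneSignatureSet <- function(x, ...) {
  cat("GeneSignatureSet '", x$name, "': ", length(x$signatures),
      " signatures (", paste(names(x$signatures), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Template annotation
#'
#' Known cell-type labels for the cells of a template sample; the label set
#' defines the candidate types for template-based cluster annotation.
#'
#' @param cell_id character vector of template cell ids.
#' @param cell_type character vector of labels, same length.
#' @return object of class `TemplateAnnotation`: a named character vector
#'   (cell_id -> type).
#' @export
template_annotation <- function(cell_id, cell_type) {
  if (length(cell_id) != length(cell_type))
    stop("cell_id and cell_type lengths differ")
  if (anyDuplicated(cell_id)) stop("duplicate template cell ids")
  out <- stats::setNames(as.character(cell_type), as.character(cell_id))
  class(out) <- "TemplateAnnotation"
  out
}
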
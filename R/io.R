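#' Read a UMI count matrix from disk
#'
#' Supports the two common on-disk dialects: MatrixMarket triplets with
#' side-car gene and barcode lists, and a dense CSV with gene ids in the
#' first column and cell ids in the header.
#'
#' @param path path to the `.mtx` file or the CSV file.
#' @param format `"mtx"` or `"csv"`.
#' @param genes_path,barcodes_path side-car files for the mtx format; default
#'   `genes.tsv` / `barcodes.tsv` next to the matrix. One id per line (first
#'   column of a TSV is used).
#' @param cells_are_rows set `TRUE` when the on-disk orientation is
#'   cells x genes; the loader transposes to the internal genes x cells
#'   convention.
#' @return a validated count matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(path, format = c("mtx", "csv"),
                              genes_path = NULL, barcodes_path = NULL,
                              cells_are_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    for (p in c(genes_path, barcodes_path))
      if (!file.exists(p)) stop("file not found: ", p)
    m <- Matrix::readMM(path)
    genes <- utils::read.table(genes_path, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(barcodes_path, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    if (cells_are_rows) m <- Matrix::t(m)
    count_matrix(m, gene_ids = genes, cell_ids = cells)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    if (cells_are_rows) m <- t(m)
    count_matrix(m)
  }
}

#' Write a count matrix
#'
#' @param m count matrix (genes x cells).
#' @param path output `.mtx` or `.csv` path.
#' @param format `"mtx"` writes MatrixMarket plus `genes.tsv`/`barcodes.tsv`
#'   side-cars in the same directory; `"csv"` writes a dense table.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(m, path)
    writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  } else {
    df <- data.frame(gene_id = rownames(m), as.matrix(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# required columns per table schema
.schema_required <- list(
  cell_table  = c("cell_id", "sample_id", "site"),
  lr_pairs    = c("ligand", "receptor"),
  composition = c("sample_id")
)

#' Read a typed metadata table
#'
#' Reads a delimited file and validates it against one of the pipeline's
#' table schemas. Unknown columns are preserved but ignored.
#'
#' @param path CSV/TSV file with a header row.
#' @param schema one of `"cell_table"`, `"signature_set"`, `"lr_pairs"`,
#'   `"composition"`.
#' @param sep field separator, inferred from the extension by default.
#' @return a typed object: `CellTable`, `GeneSignatureSet` (file must have
#'   columns `label,gene`), `LRDatabase` or `CompositionTable`.
#' @export
read_table <- function(path, schema = c("cell_table", "signature_set",
                                        "lr_pairs", "composition"),
                       sep = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  switch(schema,
    cell_table = validate_cell_table(df),
    signature_set = {
      miss <- setdiff(c("label", "gene"), names(df))
      if (length(miss))
        stop("schema error: missing required column(s): ",
             paste(miss, collapse = ", "))
      signature_set(basename(path), split(df$gene, df$label))
    },
    lr_pairs = {
      miss <- setdiff(.schema_required$lr_pairs, names(df))
      if (length(miss))
        stop("schema error: missing required column(s): ",
             paste(miss, collapse = ", "))
      if (is.null(df$source)) df$source <- basename(path)
      build_lr_db(list(df))
    },
    composition = {
      miss <- setdiff(.schema_required$composition, names(df))
      if (length(miss))
        stop("schema error: missing required column(s): ",
             paste(miss, collapse = ", "))
      num <- vapply(df, is.numeric, logical(1))
      pct <- setdiff(names(df)[num], c("n_cells", "patient"))
      for (cn in pct) {
        v <- df[[cn]]
        if (any(!is.na(v) & (v < 0 | v > 100)))
          stop("validation error: column '", cn, "' outside [0, 100]")
      }
      class(df) <- c("CompositionTable", "data.frame")
      df
    })
}

#' The packaged per-sample composition and IHC reference table
#'
#' A 21-sample table of per-sample cell counts, major-cell-type percentages
#' from single-cell annotation, IHC positivity percentages (CK7, VIM, CD45),
#' tumor site and T-cell-infiltration category, shipped for regression tests
#' of the composition statistics.
#'
#' @return a `CompositionTable` with 21 rows.
#' @export
load_table2 <- function() {
  read_table(system.file("extdata", "table2.csv", package = "scTME",
                         mustWork = TRUE),
             schema = "composition")
}

#' Read a signature manifest
#'
#' A YAML manifest mapping label -> file, one gene id per line per file.
#'
#' @param path manifest YAML; file paths are resolved relative to it.
#' @param name name for the resulting set (default: manifest file name).
#' @return a `GeneSignatureSet`.
#' @export
read_signature_manifest <- function(path, name = basename(path)) {
  man <- yaml::read_yaml(path)
  sigs <- lapply(man, function(f) {
    fp <- if (file.exists(f)) f else file.path(dirname(path), f)
    readLines(fp)
  })
  signature_set(name, sigs)
}
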
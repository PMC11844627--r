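# Readers/writers for the expression-matrix formats the pipeline touches.

new_expression_matrix <- function(mat, unit, provenance = NULL) {
  stopifnot(is.matrix(mat))
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  }
  if (any(mat < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative")
  }
  attr(mat, "unit") <- unit
  attr(mat, "provenance") <- provenance
  mat
}

#' Unit tag of an expression matrix
#'
#' @param x A matrix produced by one of the readers or by
#'   [normalize_counts()].
#' @return The unit string (\code{"nTPM"}, \code{"normalized-count"},
#'   \code{"intensity"}, \code{"count"}, ...) or \code{NA} if untagged.
#' @export
expression_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) NA_character_ else u
}

#' Read a long-format tissue-consensus expression table
#'
#' Reads a TSV with one row per (gene, tissue) pair -- the layout of the
#' Human Protein Atlas consensus download -- and pivots it into a
#' gene-by-tissue matrix. Absent pairs become \code{NA} (missing is tracked,
#' never silently zero-filled); duplicate pairs are an error.
#'
#' @param path TSV path.
#' @param gene_col,sample_col,value_col Column names; defaults cover both the
#'   HPA dialect (\code{Gene name}, \code{Tissue}, \code{nTPM}) and a generic
#'   \code{gene}/\code{tissue}/\code{value} layout.
#' @param unit Unit tag attached to the result.
#' @return Numeric matrix (genes x tissues) with a \code{unit} attribute.
#' @export
read_long_consensus <- function(path, gene_col = NULL, sample_col = NULL,
                                value_col = NULL, unit = "nTPM") {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gi <- if (is.null(gene_col)) pick_column(tab, c("gene name", "gene")) else match(gene_col, names(tab))
  si <- if (is.null(sample_col)) pick_column(tab, c("tissue", "sample")) else match(sample_col, names(tab))
  vi <- if (is.null(value_col)) pick_column(tab, c("ntpm", "value", "expression")) else match(value_col, names(tab))
  if (is.na(gi) || is.na(si) || is.na(vi)) {
    stop("long-format file needs gene, tissue and value columns; found: ",
         paste(names(tab), collapse = ", "))
  }
  gene <- as.character(tab[[gi]]); tissue <- as.character(tab[[si]])
  value <- as.numeric(tab[[vi]])
  key <- paste(gene, tissue, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop("duplicate (gene, tissue) pair: ", d[1], " / ", d[2])
  }
  genes <- unique(gene); tissues <- unique(tissue)
  mat <- matrix(NA_real_, length(genes), length(tissues),
                dimnames = list(genes, tissues))
  mat[cbind(match(gene, genes), match(tissue, tissues))] <- value
  new_expression_matrix(mat, unit = unit, provenance = path)
}

#' Read a GCT-dialect count matrix
#'
#' Accepts GCT v1.2 (\code{#1.2} header, dimensions line, \code{Name} /
#' \code{Description} columns) and falls back to a plain delimited matrix if
#' the first line is not a GCT version tag. Declared dimensions must match
#' the parsed matrix.
#'
#' @param path File path.
#' @param unit Unit tag (\code{"count"} for raw reads).
#' @return Numeric matrix (genes x samples) with a \code{unit} attribute.
#' @export
read_gct <- function(path, unit = "count") {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#1.")) {
    return(read_matrix(path, unit = unit))
  }
  dims <- strsplit(readLines(path, n = 2L)[2], "\t")[[1]]
  dims <- suppressWarnings(as.integer(dims))
  if (length(dims) < 2L || any(is.na(dims[1:2]))) {
    stop("malformed GCT dimensions line in ", path)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, skip = 2L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- 1L
  desc <- tolower(names(tab)) %in% c("description", "desc")
  num <- tab[, setdiff(seq_along(tab), c(id_col, which(desc))), drop = FALSE]
  mat <- as.matrix(num)
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[id_col]])
  if (nrow(mat) != dims[1] || ncol(mat) != dims[2]) {
    stop("GCT header declares ", dims[1], "x", dims[2], " but file holds ",
         nrow(mat), "x", ncol(mat))
  }
  new_expression_matrix(mat, unit = unit, provenance = path)
}

#' Read / write a delimited gene-by-sample matrix
#'
#' \code{read_matrix} parses a TSV or CSV with gene ids in the first column
#' and one column per sample; \code{write_matrix} is its inverse. Negative
#' entries and duplicated ids are errors.
#'
#' @param path File path; \code{.csv} selects comma separation, anything else
#'   tab.
#' @param unit Unit tag supplied by the caller.
#' @return \code{read_matrix}: numeric matrix with a \code{unit} attribute.
#' @export
read_matrix <- function(path, unit = "intensity") {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1]])
  new_expression_matrix(mat, unit = unit, provenance = path)
}

#' @rdname read_matrix
#' @param mat Matrix to write (row names = gene ids).
#' @param id_name Header for the id column.
#' @export
write_matrix <- function(mat, path, id_name = "gene") {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata sidecar table
#'
#' Metadata (tissue, tissue group, donor, cell line, passage, treatment, ...)
#' is kept in a separate delimited file joined on sample id, mirroring how
#' GTEx and GEO distribute it.
#'
#' @param path TSV/CSV with a sample-id column (first column or one named
#'   \code{sample}/\code{sample_id}).
#' @param expr Optional expression matrix; if given, the table is checked and
#'   reordered to match its columns.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_sample_table <- function(path, expr = NULL) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  idc <- pick_column(tab, c("sample_id", "sample", "id"))
  if (is.na(idc)) idc <- 1L
  ids <- as.character(tab[[idc]])
  if (anyDuplicated(ids)) stop("duplicated sample id(s) in metadata")
  tab$sample_id <- ids
  if (!is.null(expr)) {
    miss <- setdiff(colnames(expr), ids)
    if (length(miss)) {
      stop("metadata lacks sample(s): ", paste(miss, collapse = ", "))
    }
    tab <- tab[match(colnames(expr), ids), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
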
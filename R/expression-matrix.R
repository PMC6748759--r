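#' Construct a gene-by-cell expression matrix
#'
#' Container for non-negative expression quantifications (CPM, FPKM or UMI
#' counts) with genes as rows and cells as columns. The object records
#' whether values are on the raw or the `log2(x + 1)` scale so that the
#' transform cannot be applied twice by accident.
#'
#' @param values Numeric matrix, genes x cells, no negative entries.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#'   Defaults to `rownames(values)`.
#' @param cell_ids Character vector of unique cell identifiers (columns).
#'   Defaults to `colnames(values)`.
#' @param units Quantification units, recorded as metadata (e.g. `"CPM"`,
#'   `"FPKM"`, `"UMI"`).
#' @param log_transformed Logical; `TRUE` when `values` are already on the
#'   `log2(x + 1)` scale.
#'
#' @return An object of class `"seg_matrix"`: a numeric matrix with
#'   `gene_ids`/`cell_ids` as dimnames and `units`/`log_transformed`
#'   attributes.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 4, 2, 2, 8, 0), 3, 2, byrow = TRUE),
#'                        gene_ids = c("g1", "g2", "g3"),
#'                        cell_ids = c("c1", "c2"))
#' m
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values), units = "CPM",
                              log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required when 'values' has no dimnames")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    stop("matrix dimensions (", nrow(values), " x ", ncol(values),
         ") do not match identifier lengths (", length(gene_ids), " genes, ",
         length(cell_ids), " cells)")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicated cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)])[1:3], collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative expression value at gene '", gene_ids[neg[1, 1]],
         "', cell '", cell_ids[neg[1, 2]], "'")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(values, units = units, log_transformed = isTRUE(log_transformed),
            class = c("seg_matrix", "matrix", "array"))
}

#' @export
print.seg_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x), " genes x ", ncol(x), " cells (",
      attr(x, "units"), if (attr(x, "log_transformed")) ", log2(x+1)" else
        ", raw", " scale)\n", sep = "")
  nz <- mean(x == 0)
  cat(sprintf("  overall zero fraction: %.3f\n", nz))
  invisible(x)
}

gene_ids <- function(m) rownames(m)
cell_ids <- function(m) colnames(m)

is_log_transformed <- function(m) isTRUE(attr(m, "log_transformed"))

## Subset keeping seg_matrix attributes (base "[" would drop them).
subset_seg_matrix <- function(m, genes = NULL, cells = NULL) {
  v <- unclass(m)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  expression_matrix(v, units = attr(m, "units"),
                    log_transformed = attr(m, "log_transformed"))
}

#' Read an expression matrix from disk
#'
#' Dense files are TSV/CSV with a header row of cell identifiers and a first
#' column of gene identifiers; `"mtx"` reads Matrix Market coordinate files
#' (genes as rows) with one-column sidecar files for gene and cell
#' identifiers. Absent sparse entries are zeros.
#'
#' @param path Path to the matrix file.
#' @param format `"dense"` (TSV or CSV, by extension) or `"mtx"`.
#' @param gene_file,cell_file Sidecar identifier files, required for
#'   `format = "mtx"`.
#' @param units Quantification units recorded in the result.
#' @return A [expression_matrix()] with `log_transformed = FALSE`, genes and
#'   cells in file order.
#' @export
read_expression <- function(path, format = c("dense", "mtx"),
                            gene_file = NULL, cell_file = NULL,
                            units = "CPM") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        colClasses = c("character"), quote = "\"",
                        comment.char = ""),
      error = function(e) stop("malformed dense matrix file '", path, "': ",
                               conditionMessage(e)))
    if (ncol(df) < 2) stop("malformed dense matrix file '", path,
                           "': expected gene id column plus >=1 cell column")
    gids <- df[[1]]
    vals <- suppressWarnings(
      vapply(df[-1], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(gids, colnames(df)[-1]))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric value in '", path, "' at line ", bad[1, 1] + 1L,
           " (gene '", gids[bad[1, 1]], "')")
    expression_matrix(vals, units = units, log_transformed = FALSE)
  } else {
    if (is.null(gene_file) || is.null(cell_file))
      stop("mtx format requires gene_file and cell_file sidecars")
    if (!file.exists(gene_file)) stop("file not found: ", gene_file)
    if (!file.exists(cell_file)) stop("file not found: ", cell_file)
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop("malformed Matrix Market file '",
                                            path, "': ",
                                            conditionMessage(e)))
    gids <- readLines(gene_file)
    cids <- readLines(cell_file)
    gids <- gids[nzchar(gids)]
    cids <- cids[nzchar(cids)]
    if (nrow(mm) != length(gids) || ncol(mm) != length(cids))
      stop("sidecar identifier counts (", length(gids), " genes, ",
           length(cids), " cells) do not match matrix dimensions (",
           nrow(mm), " x ", ncol(mm), ")")
    expression_matrix(as.matrix(mm), gene_ids = gids, cell_ids = cids,
                      units = units, log_transformed = FALSE)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]. Dense output uses 17 significant digits so
#' values round-trip exactly; `"mtx"` writes Matrix Market plus the two
#' identifier sidecars.
#'
#' @param m A `seg_matrix`.
#' @param path Output path for the matrix.
#' @param format `"dense"` or `"mtx"`.
#' @param gene_file,cell_file Sidecar paths, required for `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("dense", "mtx"),
                             gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(m, "seg_matrix"))
  if (format == "dense") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    chr <- matrix(sprintf("%.17g", m), nrow(m))
    out <- cbind(gene_id = gene_ids(m), chr)
    colnames(out) <- c("gene_id", cell_ids(m))
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    if (is.null(gene_file) || is.null(cell_file))
      stop("mtx format requires gene_file and cell_file sidecars")
    Matrix::writeMM(Matrix::Matrix(unclass(m), sparse = TRUE), path)
    writeLines(gene_ids(m), gene_file)
    writeLines(cell_ids(m), cell_file)
  }
  invisible(path)
}

#' Apply the log2(x + 1) transform
#'
#' @param m A raw-scale `seg_matrix`.
#' @return The matrix with every entry `x` replaced by `log2(x + 1)` and
#'   `log_transformed = TRUE`. Zeros map to zeros.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 7, 3), 2, 2), c("a", "b"),
#'                        c("c1", "c2"))
#' log_transform(m)[, 1]
log_transform <- function(m) {
  stopifnot(inherits(m, "seg_matrix"))
  if (is_log_transformed(m))
    stop("matrix is already log-transformed; refusing to transform twice")
  expression_matrix(log2(unclass(m) + 1), units = attr(m, "units"),
                    log_transformed = TRUE)
}

#' Remove genes with too many zeros
#'
#' Genes whose fraction of zero entries strictly exceeds `max_zero_fraction`
#' are removed; a gene exactly at the threshold is retained. The cell set is
#' unchanged.
#'
#' @param m A `seg_matrix`.
#' @param max_zero_fraction Maximum tolerated zero fraction, in `[0, 1]`.
#'   Default 0.8 (genes with more than 80% zeros are dropped).
#' @return The filtered `seg_matrix`.
#' @export
filter_genes_by_zeros <- function(m, max_zero_fraction = 0.8) {
  stopifnot(inherits(m, "seg_matrix"))
  if (!is.numeric(max_zero_fraction) || max_zero_fraction < 0 ||
      max_zero_fraction > 1)
    stop("max_zero_fraction must be in [0, 1]")
  zf <- rowMeans(unclass(m) == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep))
    stop("all ", nrow(m), " genes exceed a zero fraction of ",
         max_zero_fraction, "; relax the threshold")
  subset_seg_matrix(m, genes = which(keep))
}

#' Read and write plain-text gene lists
#'
#' One gene identifier per line. Duplicates are collapsed with a warning on
#' read; an empty file is an error.
#'
#' @param path File path.
#' @return `read_gene_list()`: character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0) stop("gene list file '", path, "' is empty")
  if (anyDuplicated(x)) {
    warning("gene list '", path, "' contains duplicated identifiers; ",
            "collapsing to unique")
    x <- unique(x)
  }
  x
}

#' @rdname read_gene_list
#' @param genes Character vector of gene identifiers to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a cell annotation table
#'
#' Two-column TSV (`cell_id`, `class_label`), with or without a header line.
#'
#' @param path File path.
#' @return A data frame of class `"seg_annotation"` with columns `cell_id`
#'   and `class_label` (factor).
#' @export
read_cell_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2)
    stop("annotation file '", path, "' must have two tab-separated columns")
  if (identical(tolower(df[1, 1]), "cell_id")) df <- df[-1, , drop = FALSE]
  cell_annotation(df[[1]], df[[2]])
}

#' Construct a cell annotation
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param class_labels Class label (cell type, developmental stage, ...) per
#'   cell.
#' @return A data frame of class `"seg_annotation"`.
#' @export
cell_annotation <- function(cell_ids, class_labels) {
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids))
    stop("duplicated cell identifiers in annotation")
  if (length(cell_ids) != length(class_labels))
    stop("cell_ids and class_labels lengths differ")
  out <- data.frame(cell_id = cell_ids,
                    class_label = factor(class_labels),
                    stringsAsFactors = FALSE)
  class(out) <- c("seg_annotation", "data.frame")
  out
}

## Align an annotation to a matrix's cells, preserving matrix cell order.
align_annotation <- function(m, ann) {
  stopifnot(inherits(ann, "seg_annotation"))
  idx <- match(cell_ids(m), ann$cell_id)
  if (anyNA(idx))
    stop("annotation is missing ", sum(is.na(idx)), " of the matrix's cells ",
         "(first: '", cell_ids(m)[which(is.na(idx))[1]], "')")
  droplevels(ann$class_label[idx])
}
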
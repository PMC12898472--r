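#' Read an expression matrix
#'
#' Reads either a Matrix Market sparse triplet file (with companion gene and
#' barcode files, one ID per line) or a dense delimited table with gene rows
#' and a header of observation IDs. Values are treated as raw counts.
#'
#' @param path path to the `.mtx` file (format `"mtx"`) or to the delimited
#'   table (format `"dense"`).
#' @param format `"mtx"` or `"dense"`.
#' @param genesFile,barcodesFile companion ID files for `"mtx"` (defaults:
#'   `genes.tsv` / `barcodes.tsv` next to the matrix).
#' @param sep field separator for `"dense"`.
#' @return numeric matrix (genes x observations) with IDs in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(0:3, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))), tf, format = "dense")
#' readExpression(tf, format = "dense")
#' @export
readExpression <- function(path, format = c("mtx", "dense"),
                           genesFile = NULL, barcodesFile = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyDuplicated(genes)) stop("duplicate gene IDs in ", path)
    if (anyDuplicated(colnames(m))) stop("duplicate observation IDs in ", path)
    rownames(m) <- genes
    return(.assertMatrix(m))
  }
  dir <- dirname(path)
  if (is.null(genesFile)) genesFile <- file.path(dir, "genes.tsv")
  if (is.null(barcodesFile)) barcodesFile <- file.path(dir, "barcodes.tsv")
  for (f in c(genesFile, barcodesFile))
    if (!file.exists(f)) stop("companion ID file not found: ", f)
  mm <- Matrix::readMM(path)
  genes <- readLines(genesFile)
  cells <- readLines(barcodesFile)
  ## ID files may carry extra tab-separated annotation columns; first wins
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, "", 1L)
  cells <- vapply(strsplit(cells, "\t", fixed = TRUE), `[[`, "", 1L)
  if (nrow(mm) != length(genes) || ncol(mm) != length(cells))
    stop("matrix dimensions (", nrow(mm), " x ", ncol(mm),
         ") do not match ID files (", length(genes), " genes, ",
         length(cells), " barcodes)")
  if (anyDuplicated(genes)) stop("duplicate gene IDs in ", genesFile)
  if (anyDuplicated(cells)) stop("duplicate barcodes in ", barcodesFile)
  m <- as.matrix(mm)
  dimnames(m) <- list(genes, cells)
  .assertMatrix(m)
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]: writes either a dense delimited table
#' (column `gene_id` first) or a Matrix Market triplet plus `genes.tsv` and
#' `barcodes.tsv` in the same directory.
#'
#' @param mat numeric matrix with gene row names and observation column names.
#' @param path output file path.
#' @param format `"mtx"` or `"dense"`.
#' @param sep field separator for `"dense"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(mat, path, format = c("mtx", "dense"), sep = "\t") {
  format <- match.arg(format)
  mat <- .assertMatrix(mat)
  if (format == "dense") {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(mat, "CsparseMatrix"),
                                "generalMatrix"), path)
    dir <- dirname(path)
    writeLines(rownames(mat), file.path(dir, "genes.tsv"))
    writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read cell metadata
#'
#' Delimited table with at least `cell_id`, `patient_id` and `compartment`
#' columns; `cluster_label` and `tissue` are optional.
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return [S4Vectors::DataFrame] keyed by `cell_id`.
#' @export
readCellMetadata <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "patient_id", "compartment")
  if (!all(need %in% colnames(tab)))
    stop("cell metadata must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$cell_id)) stop("duplicate cell_id in ", path)
  DataFrame(tab, row.names = tab$cell_id)
}

#' Read gene annotation
#'
#' BED-like delimited table with columns `gene_id`, `chromosome`, `start`
#' (0-based start coordinate; only the (chromosome, start) ordering is used).
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return [S4Vectors::DataFrame] keyed by `gene_id`.
#' @export
readGeneAnnotation <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start")
  if (!all(need %in% colnames(tab)))
    stop("gene annotation must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in ", path)
  if (any(tab$start < 0)) stop("negative start coordinates in ", path)
  DataFrame(tab, row.names = tab$gene_id)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT semantics: one set per line, fields `name`, `description`,
#' then gene IDs.
#'
#' @param path path to the `.gmt` file.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields")
    unique(f[-c(1L, 2L)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' Delimited table with columns `sample_id`, `time_months`, `event` and any
#' number of additional covariate columns.
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return [S4Vectors::DataFrame] keyed by `sample_id`.
#' @export
readSurvivalTable <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% colnames(tab)))
    stop("survival table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in ", path)
  if (any(tab$time_months <= 0)) stop("non-positive survival times in ", path)
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1 in ", path)
  DataFrame(tab, row.names = tab$sample_id)
}

#' Read a sample-by-drug AUC table
#'
#' Delimited table: first column `sample_id`, remaining header fields are drug
#' IDs; cells are dose-response AUC values (lower = more sensitive).
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return numeric matrix, samples x drugs.
#' @export
readDrugAuc <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1L] != "sample_id")
    stop("first column of the AUC table must be sample_id")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$sample_id
  m
}

#' Assemble a SingleCellExperiment from matrix, metadata and annotation
#'
#' Convenience constructor bundling a count matrix with per-cell metadata and
#' per-gene annotation; downstream steps ([qcFilter()], [logNormalize()],
#' [runCnvPipeline()], ...) operate on the result.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param meta optional cell metadata ([S4Vectors::DataFrame] or data.frame)
#'   keyed by `cell_id`; every matrix column must be present.
#' @param annotation optional gene annotation keyed by `gene_id`; genes absent
#'   from the annotation keep `NA` coordinates.
#' @return [SingleCellExperiment::SingleCellExperiment] with a `counts` assay.
#' @export
makeSce <- function(counts, meta = NULL, annotation = NULL) {
  counts <- .assertCounts(counts)
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = counts))
  if (!is.null(meta)) {
    meta <- DataFrame(meta)
    key <- if ("cell_id" %in% colnames(meta)) meta$cell_id else rownames(meta)
    if (!all(colnames(counts) %in% key))
      stop("metadata missing cells: ",
           paste(utils::head(setdiff(colnames(counts), key), 5), collapse = ", "))
    meta <- meta[match(colnames(counts), key), , drop = FALSE]
    rownames(meta) <- colnames(counts)
    SummarizedExperiment::colData(sce) <- meta
  }
  if (!is.null(annotation)) {
    annotation <- DataFrame(annotation)
    key <- if ("gene_id" %in% colnames(annotation)) annotation$gene_id
           else rownames(annotation)
    ann <- annotation[match(rownames(counts), key), , drop = FALSE]
    ## "start" is reserved in rowData; store under start_position
    colnames(ann)[colnames(ann) == "start"] <- "start_position"
    SummarizedExperiment::rowData(sce) <- ann
  }
  sce
}
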
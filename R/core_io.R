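# Readers/writers for the standard formats the pipeline touches:
# Matrix Market count bundles, TSV metadata tables, GMT gene sets, JSON
# reports. Matrix Market indices are 1-based on disk (per the format); all
# in-memory objects are plain R matrices indexed from 1 with dimnames.
# On disk the matrix is stored genes x cells (the field's convention);
# in memory everything is cells x genes.

#' Write a count matrix bundle (Matrix Market + gene/barcode tables)
#'
#' @param counts cells x genes matrix (sparse or dense, non-negative).
#' @param meta optional per-cell metadata data.frame (written to cells.tsv).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_mtx_bundle <- function(counts, meta = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(Matrix::t(counts), sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(meta)) {
    utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix bundle
#'
#' Reads `matrix.mtx` (genes x cells on disk), `genes.tsv`, `barcodes.tsv`
#' and, when present, `cells.tsv`. Duplicate gene symbols are resolved by
#' summing their rows, with a warning.
#'
#' @param dir directory containing the bundle.
#' @return list with `counts` (cells x genes sparse matrix) and `meta`
#'   (data.frame or NULL).
#' @export
read_mtx_bundle <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  for (f in c(mtx_path, file.path(dir, "genes.tsv"), file.path(dir, "barcodes.tsv"))) {
    if (!file.exists(f)) stop(sprintf("missing bundle file: %s", f))
  }
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop(sprintf(paste0("format error: matrix header declares %d genes x %d cells ",
                        "but genes.tsv has %d rows and barcodes.tsv has %d rows"),
                 nrow(m), ncol(m), length(genes), length(barcodes)))
  }
  if (any(m@x < 0)) stop("format error: negative entries in count matrix")
  counts <- Matrix::t(m)
  rownames(counts) <- barcodes
  if (anyDuplicated(barcodes)) stop("format error: duplicate cell barcodes")
  if (anyDuplicated(genes)) {
    warning(sprintf("%d duplicate gene symbols collapsed by summing",
                    sum(duplicated(genes))))
    agg <- Matrix::fac2sparse(factor(genes, levels = unique(genes)))
    counts <- Matrix::tcrossprod(counts, agg)
    colnames(counts) <- unique(genes)
  } else {
    colnames(counts) <- genes
  }
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  meta <- NULL
  if (file.exists(file.path(dir, "cells.tsv"))) {
    meta <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  }
  list(counts = counts, meta = meta)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>member...`. Members are
#' de-duplicated within a set. Lines with fewer than three fields are
#' rejected with a warning; an empty file yields an empty collection with a
#' warning.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; names are set names,
#'   `attr(, "description")` keeps the description column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("empty GMT file: %s", path))
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    warning(sprintf("rejected %d GMT line(s) with fewer than 3 fields", sum(short)))
    fields <- fields[!short]
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-cell metadata table
#'
#' Requires at least `cell_id`, `sample_id` and `patient_id` columns;
#' `cell_class` defaults to "unknown" when absent.
#'
#' @param path TSV file.
#' @return data.frame, one row per cell.
#' @export
read_cell_meta <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("cell_id", "sample_id", "patient_id")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop(sprintf("missing required columns: %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id values in metadata")
  if (is.null(meta$cell_class)) meta$cell_class <- "unknown"
  if (!is.null(meta$mito_fraction) &&
      any(meta$mito_fraction < 0 | meta$mito_fraction > 1, na.rm = TRUE)) {
    stop("mito_fraction must lie in [0, 1]")
  }
  meta
}

#' Read a cell-line mutation table
#'
#' Requires `line_id` and `subtype` columns; every other column is a per-gene
#' mutation flag and must be boolean (TRUE/FALSE or 0/1).
#'
#' @param path TSV file.
#' @return data.frame with logical flag columns.
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("line_id", "subtype")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("missing required columns: %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$line_id)) stop("duplicate line_id values")
  for (col in setdiff(names(tab), required)) {
    v <- tab[[col]]
    if (is.logical(v)) next
    if (is.numeric(v) && all(v %in% c(0, 1))) {
      tab[[col]] <- v == 1
    } else if (is.character(v) && all(toupper(v) %in% c("TRUE", "FALSE"))) {
      tab[[col]] <- toupper(v) == "TRUE"
    } else {
      stop(sprintf("mutation flag column '%s' is not boolean", col))
    }
  }
  tab
}

#' Serialize an analysis report
#'
#' Data frames and matrices are written as TSV; everything else as JSON.
#'
#' @param obj object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  if (is.data.frame(obj) || is.matrix(obj)) {
    utils::write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                       row.names = is.matrix(obj) && !is.null(rownames(obj)))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(path)
}
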
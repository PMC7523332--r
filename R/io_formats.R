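#' Read a sample sheet
#'
#' A sample sheet maps each 10x sample directory to its patient and tissue
#' of origin. It is a tab-separated file with header columns `sample_id`,
#' `path`, `patient_id`, `tissue`; `tissue` must be `"primary"` or
#' `"metastasis"`. Paths are interpreted relative to the sheet's directory
#' unless absolute.
#'
#' @param path Path to the TSV sample sheet.
#' @param check_paths Verify that each sample directory exists (default TRUE).
#' @return A data.frame with columns `sample_id`, `path`, `patient_id`,
#'   `tissue`.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "path", "patient_id", "tissue")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample sheet has duplicated sample_id values")
  }
  bad <- setdiff(unique(sheet$tissue), c("primary", "metastasis"))
  if (length(bad) > 0) {
    stop("tissue must be 'primary' or 'metastasis'; found: ",
         paste(bad, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  if (check_paths) {
    gone <- !dir.exists(sheet$path)
    if (any(gone)) {
      stop("sample directory does not exist: ",
           paste(sheet$path[gone], collapse = ", "))
    }
  }
  sheet[required]
}

# Locate a triplet member, accepting plain or gzip variants.
.find_tenx_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else file(path)
}

#' Read a 10x Genomics MTX triplet into a CountMatrix
#'
#' Reads `matrix.mtx(.gz)`, `barcodes.tsv(.gz)` and `features.tsv(.gz)`
#' (or the legacy `genes.tsv`) from one directory. Gene identity is the
#' symbol column of the features file; duplicated symbols are disambiguated
#' by suffixing `.1`, `.2`, ... in file order (never summed). If a
#' `cell_meta.tsv` sidecar (barcode, sample_id, patient_id, tissue) is
#' present it is attached; otherwise metadata fields are `NA`.
#'
#' @param dir Directory containing the triplet.
#' @return A `CountMatrix`: list with `counts` (sparse genes x cells
#'   dgCMatrix with dimnames), `cell_meta` (data.frame, one row per cell)
#'   and `gene_ids` (the feature-ID column, if present).
#' @export
read_10x_mtx <- function(dir) {
  if (!dir.exists(dir)) stop("not a directory: ", dir)
  mtx <- .find_tenx_file(dir, c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("missing matrix.mtx(.gz) in ", dir)
  bc <- .find_tenx_file(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bc)) stop("missing barcodes.tsv(.gz) in ", dir)
  ft <- .find_tenx_file(dir, c("features.tsv", "features.tsv.gz",
                               "genes.tsv", "genes.tsv.gz"))
  if (is.null(ft)) stop("missing features.tsv(.gz)/genes.tsv(.gz) in ", dir)

  counts <- Matrix::readMM(.open_maybe_gz(mtx))
  if (length(counts@x) > 0 &&
      (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    stop("matrix.mtx contains negative or non-integer entries")
  }
  barcodes <- readLines(.open_maybe_gz(bc))
  feat <- utils::read.delim(.open_maybe_gz(ft), header = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(feat) != nrow(counts)) {
    stop("features file has ", nrow(feat), " rows but matrix has ",
         nrow(counts), " genes")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("barcodes file has ", length(barcodes), " rows but matrix has ",
         ncol(counts), " cells")
  }
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  gene_ids <- if (ncol(feat) >= 2) feat[[1]] else NULL
  symbols <- make.unique(symbols, sep = ".")
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  dimnames(counts) <- list(symbols, barcodes)

  meta_path <- file.path(dir, "cell_meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = "character")
    if (!all(c("barcode", "sample_id", "patient_id", "tissue") %in% names(meta))) {
      stop("cell_meta.tsv must have columns barcode, sample_id, patient_id, tissue")
    }
    idx <- match(barcodes, meta$barcode)
    if (anyNA(idx)) stop("cell_meta.tsv does not cover every barcode")
    meta <- meta[idx, c("barcode", "sample_id", "patient_id", "tissue")]
  } else {
    meta <- data.frame(barcode = barcodes,
                       sample_id = NA_character_,
                       patient_id = NA_character_,
                       tissue = NA_character_,
                       stringsAsFactors = FALSE)
  }
  rownames(meta) <- NULL
  new_count_matrix(counts, meta, gene_ids = gene_ids)
}

#' Construct a CountMatrix
#'
#' @param counts Sparse or dense genes x cells matrix of non-negative
#'   integer counts with rownames (gene symbols) and colnames (barcodes).
#' @param cell_meta data.frame with one row per cell: `barcode`,
#'   `sample_id`, `patient_id`, `tissue`.
#' @param gene_ids Optional vector of feature IDs parallel to the genes.
#' @return A `CountMatrix` object.
#' @export
new_count_matrix <- function(counts, cell_meta, gene_ids = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have gene symbols as rownames and barcodes as colnames")
  }
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (nrow(cell_meta) != ncol(counts)) {
    stop("cell_meta must have one row per cell")
  }
  if (length(counts@x) > 0 &&
      (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) stop("gene symbols must be unique")
  obj <- list(counts = counts, cell_meta = cell_meta, gene_ids = gene_ids)
  class(obj) <- "CountMatrix"
  obj
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(x$counts@x), "non-zero entries\n")
  invisible(x)
}

#' Write a CountMatrix as a 10x MTX triplet
#'
#' Emits `matrix.mtx` in the MatrixMarket "coordinate integer general"
#' dialect used by the 10x triplet, plus `barcodes.tsv`, `features.tsv`
#' (ID column repeated from symbols when no IDs are carried) and a
#' `cell_meta.tsv` sidecar. `read_10x_mtx()` round-trips the result.
#'
#' @param m A `CountMatrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_10x_mtx <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  counts <- m$counts
  trip <- Matrix::summary(counts)
  # Matrix::writeMM emits "coordinate real"; the 10x convention is integer.
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             "%",
             paste(nrow(counts), ncol(counts), nrow(trip)),
             if (nrow(trip) > 0)
               paste(trip$i, trip$j, format(trip$x, scientific = FALSE, trim = TRUE)))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(as.character(colnames(counts)), file.path(dir, "barcodes.tsv"))
  ids <- if (is.null(m$gene_ids)) rownames(counts) else m$gene_ids
  utils::write.table(
    data.frame(ids, rownames(counts), "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(m$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a two-column TSV
#'
#' The file must have a header and two tab-separated columns, `set_name`
#' and `gene`. Duplicate genes within a set are dropped with a warning.
#'
#' @param path Path to the TSV.
#' @return Named list of character vectors (one per distinct `set_name`,
#'   in first-appearance order; genes in file order).
#' @export
read_gene_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene") %in% names(tab))) {
    stop("gene-set file must have header columns set_name and gene")
  }
  if (nrow(tab) == 0) stop("gene-set file is empty")
  sets <- lapply(split(tab$gene, factor(tab$set_name, levels = unique(tab$set_name))),
                 function(g) {
                   if (anyDuplicated(g)) {
                     warning("duplicate genes within a set were dropped")
                   }
                   unique(g)
                 })
  sets
}

#' Write gene sets to the two-column TSV dialect
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  tab <- data.frame(
    set_name = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bulk expression cohort with survival outcomes
#'
#' @param expr_path TSV of patients x genes: first column `patient_id`,
#'   remaining columns numeric expression (unit as provided; the pipeline
#'   only uses within-gene medians, so any monotone per-gene unit works).
#' @param clinical_path TSV with columns `patient_id`, `os_time`
#'   (overall-survival time, non-negative) and `os_event` (1 = death
#'   observed, 0 = censored).
#' @return A `BulkCohort`: list with `expr` (numeric matrix patients x
#'   genes, rownames = patient IDs) and `clinical` (data.frame in cohort
#'   order). Patients are intersected between the two files; cohort order
#'   follows the clinical table.
#' @export
read_bulk_cohort <- function(expr_path, clinical_path) {
  expr <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (names(expr)[1] != "patient_id") {
    stop("expression table must have patient_id as its first column")
  }
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "os_time", "os_event") %in% names(clin))) {
    stop("clinical table must have columns patient_id, os_time, os_event")
  }
  if (any(clin$os_time < 0)) stop("negative os_time in clinical table")
  if (!all(clin$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  keep <- clin$patient_id %in% expr$patient_id
  if (!any(keep)) stop("no overlapping patients between expression and clinical tables")
  if (!all(keep)) {
    message(sum(!keep), " clinical patient(s) without expression were dropped")
  }
  clin <- clin[keep, , drop = FALSE]
  em <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(em)) stop("expression values must be numeric")
  rownames(em) <- expr$patient_id
  extra <- nrow(em) - nrow(clin)
  if (extra > 0) message(extra, " expression patient(s) without clinical data were dropped")
  em <- em[clin$patient_id, , drop = FALSE]
  rownames(clin) <- NULL
  new_bulk_cohort(em, clin)
}

#' Construct a BulkCohort
#'
#' @param expr Numeric matrix patients x genes with patient IDs as rownames.
#' @param clinical data.frame with `patient_id`, `os_time`, `os_event`
#'   aligned with `expr` rows.
#' @return A `BulkCohort` object.
#' @export
new_bulk_cohort <- function(expr, clinical) {
  stopifnot(is.matrix(expr), nrow(expr) == nrow(clinical),
            all(rownames(expr) == clinical$patient_id),
            all(clinical$os_time >= 0),
            all(clinical$os_event %in% c(0, 1)))
  if (anyDuplicated(colnames(expr))) stop("cohort genes must be unique")
  obj <- list(expr = expr, clinical = clinical)
  class(obj) <- "BulkCohort"
  obj
}

#' Write a BulkCohort as expression + clinical TSVs
#'
#' @param cohort A `BulkCohort`.
#' @param expr_path,clinical_path Output paths.
#' @return Invisibly, `expr_path`.
#' @export
write_bulk_cohort <- function(cohort, expr_path, clinical_path) {
  stopifnot(inherits(cohort, "BulkCohort"))
  tab <- data.frame(patient_id = rownames(cohort$expr),
                    cohort$expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, clinical_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

#' Read a printed-style composition table
#'
#' Parses a per-patient cell-type percentage table in which trace
#' abundances may be printed as `"< 0.1"`. Such entries are read as 0.05
#' (the midpoint of the printable interval) for computation.
#'
#' @param path TSV with columns `patient_id`, `tissue`, then one numeric
#'   (or `"< 0.1"`) column per cell type.
#' @return data.frame with numeric cell-type columns.
#' @export
read_composition_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("patient_id", "tissue") %in% names(tab)))
  for (col in setdiff(names(tab), c("patient_id", "tissue"))) {
    v <- as.character(tab[[col]])
    v[grepl("^<", trimws(v))] <- "0.05"
    tab[[col]] <- as.numeric(v)
  }
  tab
}
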
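#' Per-patient cell-type composition
#'
#' Percentages of each patient's cells carrying each label, Unknown
#' included as its own column, so every row sums to 100. Full precision
#' is kept here; presentation rounding is done by
#' [format_composition()].
#'
#' @param ann An `AnnotatedCells` data.frame (every cell labeled,
#'   possibly "Unknown").
#' @param cell_types Optional column order; defaults to the labels
#'   present (sorted, Unknown last).
#' @return data.frame: patient_id, tissue, n_cells, one percentage
#'   column per cell type.
#' @export
cell_composition <- function(ann, cell_types = NULL) {
  stopifnot(is.data.frame(ann), all(c("patient_id", "label") %in% names(ann)))
  keep <- !is.na(ann$patient_id)
  if (!all(keep)) {
    warning("cells without patient_id were excluded")
    ann <- ann[keep, , drop = FALSE]
  }
  if (is.null(cell_types)) {
    cell_types <- sort(setdiff(unique(ann$label), "Unknown"))
    if ("Unknown" %in% ann$label) cell_types <- c(cell_types, "Unknown")
  }
  tab <- table(factor(ann$patient_id, levels = unique(ann$patient_id)),
               factor(ann$label, levels = cell_types))
  tab <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  n_cells <- rowSums(tab)
  if (any(n_cells == 0)) {
    warning("patient(s) with zero cells were excluded")
    tab <- tab[n_cells > 0, , drop = FALSE]
    n_cells <- n_cells[n_cells > 0]
  }
  pct <- sweep(as.matrix(tab), 1, n_cells, "/") * 100
  tissue <- ann$tissue[match(rownames(pct), ann$patient_id)]
  out <- data.frame(patient_id = rownames(pct), tissue = tissue,
                    n_cells = as.integer(n_cells),
                    pct, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Min/max/mean composition summary per cell type
#'
#' Unweighted mean across the patients of one tissue, with the
#' per-patient min and max.
#'
#' @param ct A composition table (from [cell_composition()] or
#'   [read_composition_table()]).
#' @param tissue Tissue to summarize over; `NULL` uses all rows.
#' @return data.frame: cell_type, n_patients, min, mean, max.
#' @export
composition_summary <- function(ct, tissue = NULL) {
  stopifnot(is.data.frame(ct))
  if (!is.null(tissue)) {
    ct <- ct[ct$tissue %in% tissue, , drop = FALSE]
  }
  if (nrow(ct) == 0) stop("no patients for the requested tissue")
  type_cols <- setdiff(names(ct), c("patient_id", "tissue", "n_cells"))
  out <- data.frame(cell_type = type_cols,
                    n_patients = nrow(ct),
                    min = vapply(ct[type_cols], min, numeric(1)),
                    mean = vapply(ct[type_cols], mean, numeric(1)),
                    max = vapply(ct[type_cols], max, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Presentation formatting of a composition table
#'
#' Rounds percentages to one decimal and prints nonzero values below
#' 0.05 (which would round to 0.0) as `"< 0.1"`, the dialect used for
#' trace abundances in published per-patient composition tables.
#'
#' @param ct A composition table from [cell_composition()].
#' @return data.frame of character percentage columns.
#' @export
format_composition <- function(ct) {
  type_cols <- setdiff(names(ct), c("patient_id", "tissue", "n_cells"))
  out <- ct
  for (col in type_cols) {
    v <- ct[[col]]
    s <- formatC(round(v, 1), format = "f", digits = 1)
    s[v > 0 & v < 0.05] <- "< 0.1"
    out[[col]] <- s
  }
  out
}
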
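#' Score subtype signatures per cell
#'
#' One module score vector per subtype gene set (bin-matched control
#' genes, see [module_score()]). Published subtype gene lists are user
#' inputs in the two-column gene-set TSV dialect; sets with no gene in
#' the matrix are skipped with a warning.
#'
#' @param nm A `NormMatrix`.
#' @param subtype_sets Named list of gene vectors.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return Numeric matrix cells x subtype sets.
#' @export
score_subtypes <- function(nm, subtype_sets, n_bins = 24, n_ctrl = 100,
                           seed = 1L) {
  stopifnot(inherits(nm, "NormMatrix"), length(subtype_sets) > 0,
            !is.null(names(subtype_sets)))
  cols <- list()
  for (set_name in names(subtype_sets)) {
    s <- tryCatch(
      module_score(nm, subtype_sets[[set_name]], n_bins = n_bins,
                   n_ctrl = n_ctrl, seed = seed),
      error = function(e) {
        warning("subtype set '", set_name, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(s)) cols[[set_name]] <- s
  }
  if (length(cols) == 0) stop("no subtype set could be scored")
  do.call(cbind, cols)
}

#' Summarize subtype scores by cell type or patient
#'
#' Distribution summaries per (signature, group), with the
#' highest-mean group flagged per signature — the violin-plot view of
#' which compartment carries each subtype program.
#'
#' @param scores Matrix cells x signatures from [score_subtypes()].
#' @param groups Character vector of group labels (cell types or patient
#'   ids), one per cell.
#' @return data.frame: signature, group, n_cells, mean, median, q25,
#'   q75, flagged (TRUE for the top-mean group of each signature).
#' @export
summarize_scores <- function(scores, groups) {
  stopifnot(is.matrix(scores), nrow(scores) == length(groups))
  rows <- list()
  for (sig in colnames(scores)) {
    by_group <- split(scores[, sig], groups)
    tab <- data.frame(
      signature = sig,
      group = names(by_group),
      n_cells = lengths(by_group),
      mean = vapply(by_group, mean, numeric(1)),
      median = vapply(by_group, stats::median, numeric(1)),
      q25 = vapply(by_group, function(v) unname(stats::quantile(v, 0.25)),
                   numeric(1)),
      q75 = vapply(by_group, function(v) unname(stats::quantile(v, 0.75)),
                   numeric(1)),
      stringsAsFactors = FALSE)
    tab$flagged <- seq_len(nrow(tab)) == which.max(tab$mean)
    rows[[sig]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restrict, re-embed and re-cluster on a combined signature gene set
#'
#' Convenience for clustering cells on the union of subtype signature
#' genes only (e.g. the combined published subtype panels), to ask
#' whether those genes alone separate the cell compartments.
#'
#' @param nm A `NormMatrix`.
#' @param gene_sets Named list of gene vectors; their union is used.
#' @param resolution Clustering resolution.
#' @param seed Integer seed.
#' @param ... Passed to [embed_cells()].
#' @return List with `embedding` and `clusters`.
#' @export
cluster_on_signature <- function(nm, gene_sets, resolution = 0.8,
                                 seed = 1L, ...) {
  genes <- intersect(unique(unlist(gene_sets)), rownames(nm$values))
  if (length(genes) < 2) stop("fewer than 2 signature genes present")
  sub <- nm
  sub$values <- nm$values[genes, , drop = FALSE]
  emb <- embed_cells(sub, n_hvg = length(genes), seed = seed, ...)
  list(embedding = emb,
       clusters = cluster_cells(emb, resolution = resolution, seed = seed))
}
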
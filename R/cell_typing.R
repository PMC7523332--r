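#' Cluster cells on the kNN graph
#'
#' Modularity-maximizing Louvain community detection on the embedding's
#' kNN graph. Cluster ids are 0-based and ordered by decreasing size.
#'
#' @param embedding An `Embedding` from [embed_cells()].
#' @param resolution Louvain resolution parameter (default 0.8; higher
#'   gives more clusters).
#' @param seed Integer seed (community detection is randomized).
#' @return Named integer vector of cluster ids, one per cell.
#' @export
cluster_cells <- function(embedding, resolution = 0.8, seed = 1L) {
  stopifnot(inherits(embedding, "Embedding"))
  g <- embedding$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(cl)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  stats::setNames(as.integer(relabel[as.character(mem)]),
                  igraph::V(g)$name)
}

#' Module score of a gene set with expression-matched controls
#'
#' Genes are placed into `n_bins` equal-frequency bins by their average
#' expression across cells; for each signature gene, `n_ctrl` control
#' genes are drawn from its bin (without replacement when the bin is
#' large enough, with replacement otherwise). The score of a cell is the
#' mean expression of the signature genes minus the mean expression of
#' the pooled control draws, so a random gene set scores about zero and
#' the score is invariant to adding a constant to every gene in every
#' cell.
#'
#' @param nm A `NormMatrix`.
#' @param genes Character vector of signature genes; genes absent from
#'   the matrix are dropped with a warning.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Integer seed for the control draws.
#' @param control_genes Optional explicit control set overriding the
#'   bin-matched draw (used e.g. for self-control checks).
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(nm, genes, n_bins = 24, n_ctrl = 100, seed = 1L,
                         control_genes = NULL) {
  stopifnot(inherits(nm, "NormMatrix"))
  present <- intersect(genes, rownames(nm$values))
  if (length(present) == 0) stop("no signature gene is present in the matrix")
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " signature gene(s) absent from the matrix were dropped")
  }
  sig_mean <- Matrix::colMeans(nm$values[present, , drop = FALSE])
  if (is.null(control_genes)) {
    set.seed(seed)
    avg <- stats::setNames(Matrix::rowMeans(nm$values), rownames(nm$values))
    n_bins_eff <- min(n_bins, length(avg))
    bin <- ceiling(rank(avg, ties.method = "first") * n_bins_eff / length(avg))
    bins <- split(names(avg), bin)
    bin_of <- stats::setNames(bin, names(avg))
    ctrl_idx <- unlist(lapply(present, function(g) {
      pool <- bins[[as.character(bin_of[g])]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  } else {
    ctrl_idx <- intersect(control_genes, rownames(nm$values))
    if (length(ctrl_idx) == 0) stop("no control gene present in the matrix")
  }
  ctrl_mean <- Matrix::colMeans(nm$values[ctrl_idx, , drop = FALSE])
  stats::setNames(as.numeric(sig_mean - ctrl_mean), colnames(nm$values))
}

#' Default cell-type marker panel
#'
#' Literature-established marker symbols per tumor-microenvironment cell
#' type: EPCAM/KRT19 for ductal epithelial tumor cells; CDH2/SNAI2/ZEB1
#' for EMT-like tumor cells; COL1A1/ACTA2/SPARC for fibroblasts;
#' CD3D/IL7R/CD3G for lymphocytes; CD68 for macrophages; KDR/VWF for
#' endothelial cells; FCER1A for dendritic cells. Ambiguous legacy
#' symbols in the macrophage and DC panels (the CD1 family; G-CSF/CSF3)
#' are deliberately omitted.
#'
#' @return Named list of marker gene vectors.
#' @export
default_marker_panel <- function() {
  list(ETC = c("EPCAM", "KRT19"),
       EMT = c("CDH2", "SNAI2", "ZEB1"),
       CAF = c("COL1A1", "ACTA2", "SPARC"),
       TIL = c("CD3D", "IL7R", "CD3G"),
       TAM = "CD68",
       Endo = c("KDR", "VWF"),
       DC = "FCER1A")
}

#' Assign cluster-level cell-type labels from marker-panel module scores
#'
#' Each panel is scored per cell with [module_score()]; per cluster, the
#' panel with the highest mean score wins if it exceeds the runner-up by
#' at least `min_margin`, otherwise the cluster is `"Unknown"`. A cluster
#' whose two best panels are the epithelial-tumor (ETC) and EMT panels,
#' both clearing the third-best by the margin, is labeled EMT: EMT-
#' positive tumor cells co-express epithelial markers and are treated as
#' their own type. All cells in a cluster share its label.
#'
#' @param clusters Named integer vector of cluster ids (from
#'   [cluster_cells()]).
#' @param nm The `NormMatrix` the clustering was computed on.
#' @param panel Named list of marker gene vectors (default
#'   [default_marker_panel()]).
#' @param min_margin Minimum mean-score margin over the runner-up
#'   (default 0.05 score units).
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return An `AnnotatedCells` data.frame: barcode, sample_id,
#'   patient_id, tissue, cluster, label, plus one `score_<type>` column
#'   per panel.
#' @export
assign_labels <- function(clusters, nm, panel = default_marker_panel(),
                          min_margin = 0.05, n_bins = 24, n_ctrl = 100,
                          seed = 1L) {
  stopifnot(inherits(nm, "NormMatrix"),
            all(names(clusters) == colnames(nm$values)))
  scores <- sapply(panel, function(genes) {
    tryCatch(module_score(nm, genes, n_bins = n_bins, n_ctrl = n_ctrl,
                          seed = seed),
             error = function(e) rep(NA_real_, ncol(nm$values)))
  })
  cluster_ids <- sort(unique(clusters))
  labels <- stats::setNames(character(length(cluster_ids)),
                            as.character(cluster_ids))
  for (cl in cluster_ids) {
    in_cl <- clusters == cl
    means <- colMeans(scores[in_cl, , drop = FALSE])
    means[is.na(means)] <- -Inf
    ord <- order(means, decreasing = TRUE)
    top <- names(means)[ord[1]]
    second <- if (length(means) > 1) means[ord[2]] else -Inf
    third <- if (length(means) > 2) means[ord[3]] else -Inf
    lab <- "Unknown"
    if (is.finite(means[ord[1]]) && means[ord[1]] - second >= min_margin) {
      lab <- top
    } else if (all(c("ETC", "EMT") %in% names(means)) &&
               setequal(names(means)[ord[1:2]], c("ETC", "EMT")) &&
               is.finite(min(means[c("ETC", "EMT")])) &&
               min(means[c("ETC", "EMT")]) - third >= min_margin) {
      lab <- "EMT"
    }
    labels[as.character(cl)] <- lab
  }
  ann <- data.frame(barcode = colnames(nm$values),
                    sample_id = nm$cell_meta$sample_id,
                    patient_id = nm$cell_meta$patient_id,
                    tissue = nm$cell_meta$tissue,
                    cluster = as.integer(clusters),
                    label = unname(labels[as.character(clusters)]),
                    stringsAsFactors = FALSE)
  sc <- as.data.frame(scores)
  names(sc) <- paste0("score_", names(panel))
  ann <- cbind(ann, sc)
  rownames(ann) <- NULL
  class(ann) <- c("AnnotatedCells", "data.frame")
  ann
}

#' Cell-cycle phase calls from G1/S and G2/M module scores
#'
#' A cell is called `G1S` if its G1/S score exceeds both the G2/M score
#' and `thresh`; `G2M` symmetrically; otherwise `non-cycling`. The phase
#' gene lists are user-supplied external inputs.
#'
#' @param nm A `NormMatrix`.
#' @param g1s_genes,g2m_genes Character vectors of phase marker genes.
#' @param thresh Minimum score to call a cell cycling (default 0).
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return Named character vector of phases.
#' @export
cycle_phase <- function(nm, g1s_genes, g2m_genes, thresh = 0,
                        n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (missing(g1s_genes) || missing(g2m_genes) ||
      length(g1s_genes) == 0 || length(g2m_genes) == 0) {
    stop("both phase gene sets must be supplied")
  }
  s1 <- module_score(nm, g1s_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed)
  s2 <- module_score(nm, g2m_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed + 1L)
  phase <- rep("non-cycling", length(s1))
  phase[s1 > pmax(s2, thresh)] <- "G1S"
  phase[s2 > pmax(s1, thresh)] <- "G2M"
  stats::setNames(phase, names(s1))
}
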
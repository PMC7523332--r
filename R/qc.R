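#' Shannon diversity index of one cell's counts
#'
#' H = -sum(p_i * ln p_i) over genes with positive counts, where p_i is
#' the count proportion. Natural logarithm throughout: a filter threshold
#' of 3 corresponds to roughly exp(3) ~ 20 effectively expressed genes.
#' H is invariant to permuting the genes and to multiplying all counts by
#' a constant.
#'
#' @param x Non-negative count vector for one cell.
#' @return The Shannon index (>= 0).
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  total <- sum(x)
  if (total == 0) stop("all-zero count vector has no diversity")
  p <- x[x > 0] / total
  -sum(p * log(p))
}

# Vectorized per-cell Shannon over the columns of a sparse matrix:
# H_j = log(T_j) - sum_i x_ij log(x_ij) / T_j
.shannon_per_cell <- function(counts) {
  totals <- Matrix::colSums(counts)
  xlx <- counts
  xlx@x <- xlx@x * log(xlx@x)
  s <- Matrix::colSums(xlx)
  h <- ifelse(totals > 0, log(totals) - s / totals, NA_real_)
  stats::setNames(h, colnames(counts))
}

#' Quality-control thresholds
#'
#' @param min_umi Minimum per-cell total UMI count; cells strictly below
#'   are removed (default 1000).
#' @param min_shannon Minimum per-cell Shannon diversity (natural log);
#'   cells strictly below are removed (default 3).
#' @param max_mito_frac Optional maximum mitochondrial-count fraction
#'   (genes prefixed "MT-"). `NULL` (the default) reports the fraction
#'   without filtering on it.
#' @return A `QcThresholds` list.
#' @export
qc_thresholds <- function(min_umi = 1000, min_shannon = 3,
                          max_mito_frac = NULL) {
  stopifnot(min_umi >= 0, min_shannon >= 0)
  if (!is.null(max_mito_frac)) {
    stopifnot(max_mito_frac >= 0, max_mito_frac <= 1)
  }
  structure(list(min_umi = min_umi, min_shannon = min_shannon,
                 max_mito_frac = max_mito_frac), class = "QcThresholds")
}

#' Filter cells by library size and Shannon diversity
#'
#' Cells with total UMI below `min_umi` or Shannon diversity below
#' `min_shannon` are removed; cells exactly at a threshold are kept
#' (the removal rules are strict inequalities). The mitochondrial
#' fraction ("MT-"-prefixed genes) is always reported per cell and only
#' filtered on when `max_mito_frac` is set. Filtering is idempotent.
#'
#' @param m A `CountMatrix`.
#' @param thresholds A `QcThresholds` (defaults from [qc_thresholds()]).
#' @return List with `matrix` (filtered `CountMatrix`), `cells`
#'   (per-cell data.frame: barcode, sample_id, total_umi, shannon,
#'   mito_frac, kept) and `samples` (per-sample in/kept tallies).
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "CountMatrix"), inherits(thresholds, "QcThresholds"))
  counts <- m$counts
  if (ncol(counts) == 0) stop("empty CountMatrix")
  totals <- Matrix::colSums(counts)
  shannon <- .shannon_per_cell(counts)
  mito <- grepl("^MT-", rownames(counts))
  mito_frac <- if (any(mito)) {
    ifelse(totals > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / totals, 0)
  } else rep(0, ncol(counts))

  kept <- totals >= thresholds$min_umi &
    !is.na(shannon) & shannon >= thresholds$min_shannon
  kept[is.na(kept)] <- FALSE
  if (!is.null(thresholds$max_mito_frac)) {
    kept <- kept & mito_frac <= thresholds$max_mito_frac
  }

  cells <- data.frame(barcode = colnames(counts),
                      sample_id = m$cell_meta$sample_id,
                      total_umi = as.numeric(totals),
                      shannon = as.numeric(shannon),
                      mito_frac = as.numeric(mito_frac),
                      kept = kept,
                      stringsAsFactors = FALSE)
  samples <- stats::aggregate(cbind(n_in = rep(1, nrow(cells)),
                                    n_kept = as.integer(cells$kept)),
                              by = list(sample_id = cells$sample_id), FUN = sum)
  if (!any(kept)) warning("QC removed every cell")
  out <- new_count_matrix(counts[, kept, drop = FALSE],
                          m$cell_meta[kept, , drop = FALSE],
                          gene_ids = m$gene_ids)
  list(matrix = out, cells = cells, samples = samples)
}

#' Log-normalize a filtered count matrix
#'
#' Each entry becomes `log1p(scale * count / cell_total)`. The sparsity
#' pattern is preserved and a cell's normalized vector is invariant to
#' multiplying its counts by a constant.
#'
#' @param m A `CountMatrix` with all cell totals positive (guaranteed
#'   after QC).
#' @param scale Scale factor (default 1e4).
#' @return A `NormMatrix`: list with `values` (sparse genes x cells),
#'   `cell_meta` and `scale`.
#' @export
log_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CountMatrix"), scale > 0)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) stop("zero-total cell: run qc_filter first")
  values <- m$counts %*% Matrix::Diagonal(x = scale / totals)
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(m$counts)
  values <- methods::as(values, "CsparseMatrix")
  obj <- list(values = values, cell_meta = m$cell_meta, scale = scale)
  class(obj) <- "NormMatrix"
  obj
}

#' @export
print.NormMatrix <- function(x, ...) {
  cat("NormMatrix:", nrow(x$values), "genes x", ncol(x$values), "cells",
      "(log1p, scale", x$scale, ")\n")
  invisible(x)
}

# Highly variable genes by variance standardized against a mean-variance
# loess trend (log10 scale). Degenerate inputs (too few positive-variance
# genes for a trend) fall back to raw variance ranking.
.select_hvg <- function(values, n_hvg) {
  mu <- Matrix::rowMeans(values)
  ex2 <- Matrix::rowMeans(values^2)
  n <- ncol(values)
  v <- pmax(0, (ex2 - mu^2) * n / max(1, n - 1))
  names(v) <- rownames(values)
  score <- v
  pos <- v > 0 & mu > 0
  if (sum(pos) >= 10 && length(unique(signif(mu[pos], 8))) >= 5) {
    fit <- try(stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.5,
                            degree = 2), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      score[pos] <- v[pos] / 10^stats::fitted(fit)
      score[!pos] <- 0
    }
  }
  names(sort(score, decreasing = TRUE))[seq_len(min(n_hvg, length(score)))]
}

#' PCA embedding and kNN graph over highly variable genes
#'
#' Selects `n_hvg` genes by trend-standardized variance, centers and
#' unit-scales each gene with values clipped at 10, runs PCA, and builds
#' a k-nearest-neighbor graph (Euclidean distance in PC space, no
#' self-loops). Deterministic given the seed; PC signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param nm A `NormMatrix`.
#' @param n_hvg Number of highly variable genes (default 2000, capped at
#'   the gene count).
#' @param n_pcs Number of principal components (default 30).
#' @param k_neighbors Neighbors per cell in the kNN graph (default 20).
#' @param seed Integer seed.
#' @param clip Upper clip applied to standardized expression (default 10).
#' @return An `Embedding`: list with `pcs` (cells x n_pcs), `graph`
#'   (igraph kNN graph), `hvg` and the parameters.
#' @export
embed_cells <- function(nm, n_hvg = 2000, n_pcs = 30, k_neighbors = 20,
                        seed = 1L, clip = 10) {
  stopifnot(inherits(nm, "NormMatrix"))
  n_cells <- ncol(nm$values)
  if (n_pcs > n_cells - 1) stop("fewer cells than requested components")
  n_hvg <- min(n_hvg, nrow(nm$values))
  n_pcs <- min(n_pcs, n_hvg)
  set.seed(seed)
  hvg <- .select_hvg(nm$values, n_hvg)
  x <- as.matrix(Matrix::t(nm$values[hvg, , drop = FALSE]))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  x[x > clip] <- clip
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  # deterministic sign convention
  flip <- apply(pc$rotation, 2, function(r) r[which.max(abs(r))] < 0)
  pcs <- pc$x
  pcs[, flip] <- -pcs[, flip]
  rownames(pcs) <- colnames(nm$values)

  k <- min(k_neighbors, n_cells - 1)
  d <- as.matrix(stats::dist(pcs))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  edges <- cbind(rep(seq_len(n_cells), each = k), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  igraph::V(g)$name <- colnames(nm$values)
  obj <- list(pcs = pcs, graph = g, hvg = hvg,
              params = list(n_hvg = n_hvg, n_pcs = n_pcs,
                            k_neighbors = k, seed = seed, clip = clip))
  class(obj) <- "Embedding"
  obj
}
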
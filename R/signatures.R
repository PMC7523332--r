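# Count the number of ways to choose n1 of the ranks 1..N with a given
# rank sum, by polynomial convolution (dp[j, s] = #subsets of size j with
# sum s after processing ranks 1..r). Exact null distribution of the
# rank-sum statistic for untied samples.
.ranksum_counts <- function(n1, N) {
  max_sum <- sum((N - n1 + 1):N)
  dp <- matrix(0, nrow = n1 + 1, ncol = max_sum + 1)
  dp[1, 1] <- 1
  for (r in seq_len(N)) {
    for (j in min(n1, r):1) {
      reach <- which(dp[j, ] > 0)
      if (length(reach) > 0) {
        tgt <- reach + r
        tgt <- tgt[tgt <= max_sum + 1]
        dp[j + 1, tgt] <- dp[j + 1, tgt] + dp[j, tgt - r]
      }
    }
  }
  dp[n1 + 1, ]  # index s+1 = count of subsets with sum s
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Ranks use midranks for ties. For untied samples with
#' `length(x) + length(y) <= 12` the two-sided p-value is exact
#' (doubled smaller tail of the enumerated rank-sum distribution, capped
#' at 1); otherwise it comes from the normal approximation with
#' tie-corrected variance and a continuity correction. When every value
#' is identical across both groups, p = 1 by convention.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List with `statistic` (the Mann-Whitney U for `x`),
#'   `p_value` and `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  N <- n1 + n2
  v <- c(x, y)
  r <- rank(v)
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  ties <- table(v)
  has_ties <- any(ties > 1)
  if (all(ties == N)) {
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  }
  if (!has_ties && N <= 12) {
    counts <- .ranksum_counts(n1, N)
    total <- choose(N, n1)
    sums <- seq_along(counts) - 1
    lo <- sum(counts[sums <= w]) / total
    hi <- sum(counts[sums >= w]) / total
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  e_w <- n1 * (N + 1) / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v_w <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v_w <= 0) {
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  }
  z <- (w - e_w - sign(w - e_w) * 0.5) / sqrt(v_w)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

# Vectorized one-vs-rest rank-sum p-values over the rows of a dense
# matrix: same normal-approximation contract as wilcoxon_rank_sum.
.ranksum_rows <- function(mat, in_group) {
  n1 <- sum(in_group); N <- ncol(mat); n2 <- N - n1
  p <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    r <- rank(mat[i, ])
    w <- sum(r[in_group])
    ties <- table(mat[i, ])
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v_w <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v_w <= 0) {
      p[i] <- 1
    } else {
      z <- (w - n1 * (N + 1) / 2 - sign(w - n1 * (N + 1) / 2) * 0.5) / sqrt(v_w)
      p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  p
}

#' One-vs-rest marker detection for a cell type
#'
#' Genes are prefiltered to those detected in at least `min_pct` of
#' either group and with absolute log fold change at least `min_lfc`
#' (natural log of the ratio of de-logged group means with pseudocount
#' 1); survivors are tested by Wilcoxon rank-sum against all other
#' labeled cells (Unknown included in the rest). P-values are BH-adjusted
#' within the tested set and rows ranked by ascending p, ties broken by
#' descending |lfc| then gene name.
#'
#' @param nm A `NormMatrix`.
#' @param ann An `AnnotatedCells` data.frame aligned with `nm`.
#' @param cell_type Label to contrast against the rest (>= 3 cells), or
#'   `NULL` to run every non-Unknown label.
#' @param min_pct Minimum detection fraction in either group (default 0.1).
#' @param min_lfc Minimum |log fold change| (default 0.25).
#' @return data.frame: cell_type, gene, p_value, adjusted_p,
#'   log_fold_change, pct_in, pct_out, rank.
#' @export
find_markers <- function(nm, ann, cell_type = NULL, min_pct = 0.1,
                         min_lfc = 0.25) {
  stopifnot(inherits(nm, "NormMatrix"),
            nrow(ann) == ncol(nm$values))
  empty <- data.frame(cell_type = character(), gene = character(),
                      p_value = numeric(), adjusted_p = numeric(),
                      log_fold_change = numeric(), pct_in = numeric(),
                      pct_out = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(cell_type)) {
    types <- sort(setdiff(unique(ann$label), "Unknown"))
    out <- lapply(types, function(ct)
      find_markers(nm, ann, ct, min_pct = min_pct, min_lfc = min_lfc))
    return(do.call(rbind, c(list(empty), out)))
  }
  in_group <- ann$label == cell_type
  if (sum(in_group) == 0) stop("cell type not present: ", cell_type)
  if (sum(in_group) < 3) stop("cell type has fewer than 3 cells: ", cell_type)
  vals <- nm$values
  mi <- Matrix::rowMeans(expm1(vals[, in_group, drop = FALSE]))
  mo <- Matrix::rowMeans(expm1(vals[, !in_group, drop = FALSE]))
  lfc <- log((mi + 1) / (mo + 1))
  pct_in <- Matrix::rowMeans(vals[, in_group, drop = FALSE] > 0)
  pct_out <- Matrix::rowMeans(vals[, !in_group, drop = FALSE] > 0)
  keep <- (pct_in >= min_pct | pct_out >= min_pct) & abs(lfc) >= min_lfc
  genes <- rownames(vals)[keep]
  if (length(genes) == 0) return(empty)
  mat <- as.matrix(vals[genes, , drop = FALSE])
  p <- .ranksum_rows(mat, in_group)
  out <- data.frame(cell_type = cell_type, gene = genes,
                    p_value = p, adjusted_p = stats::p.adjust(p, "BH"),
                    log_fold_change = lfc[keep],
                    pct_in = pct_in[keep], pct_out = pct_out[keep],
                    stringsAsFactors = FALSE)
  ord <- order(out$p_value, -abs(out$log_fold_change), out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Truncate a marker table to the top-k signature per cell type
#'
#' @param mt A marker table from [find_markers()].
#' @param k Signature size (default 20); cell types with fewer ranked
#'   genes keep them all with a warning.
#' @return Named list of gene vectors, one per cell type.
#' @export
top_k_signature <- function(mt, k = 20) {
  stopifnot(is.data.frame(mt), all(c("cell_type", "gene", "rank") %in% names(mt)))
  out <- lapply(split(mt, mt$cell_type), function(tab) {
    tab <- tab[order(tab$rank), , drop = FALSE]
    if (nrow(tab) < k) {
      warning("only ", nrow(tab), " ranked genes for ", tab$cell_type[1],
              " (requested ", k, ")")
    }
    utils::head(tab$gene, k)
  })
  out[order(names(out))]
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, p = P(X >= k) with X ~ Hypergeometric(N, K, n): k
#' query genes hit a term of size K inside a universe of size N with a
#' query of size n. Query and terms are intersected with the universe
#' first; BH adjustment across terms.
#'
#' @param query Character vector of genes of interest.
#' @param terms Named list of term gene vectors.
#' @param universe Character vector: the gene universe.
#' @return data.frame: term, k, n, K, N, p_value, adjusted_p.
#' @export
hypergeom_enrich <- function(query, terms, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  query <- intersect(unique(query), universe)
  n <- length(query)
  rows <- lapply(names(terms), function(nm) {
    term <- intersect(unique(terms[[nm]]), universe)
    K <- length(term)
    k <- length(intersect(query, term))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
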
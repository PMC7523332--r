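# Shared fixture builders. Everything is generated in code; no binary data.

# Tiny deterministic CountMatrix with hand-set counts.
make_tiny_counts <- function(counts = NULL, genes = NULL, barcodes = NULL,
                             patient = "P01", tissue = "primary") {
  if (is.null(counts)) {
    counts <- matrix(c(5L, 0L, 3L,
                       0L, 2L, 0L,
                       1L, 1L, 4L), nrow = 3, byrow = TRUE)
  }
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- paste0("BC", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, barcodes)
  meta <- data.frame(barcode = barcodes, sample_id = "S1",
                     patient_id = patient, tissue = tissue,
                     stringsAsFactors = FALSE)
  new_count_matrix(counts, meta)
}

# Random sparse CountMatrix for round-trip checks.
make_random_counts <- function(n_genes = 50, n_cells = 100, seed = 1,
                               density = 0.1, max_count = 20) {
  set.seed(seed)
  counts <- matrix(0L, n_genes, n_cells)
  nnz <- ceiling(density * n_genes * n_cells)
  idx <- sample(n_genes * n_cells, nnz)
  counts[idx] <- sample.int(max_count, nnz, replace = TRUE)
  dimnames(counts) <- list(sprintf("G%03d", seq_len(n_genes)),
                           sprintf("BC%04d", seq_len(n_cells)))
  meta <- data.frame(barcode = colnames(counts),
                     sample_id = sample(c("S1", "S2"), n_cells, TRUE),
                     patient_id = sample(c("P1", "P2"), n_cells, TRUE),
                     tissue = sample(c("primary", "metastasis"), n_cells, TRUE),
                     stringsAsFactors = FALSE)
  new_count_matrix(counts, meta)
}

# A small NormMatrix with two planted populations: cells 1..n1 elevate
# the marker genes. Per-gene baseline means vary (log-normal) so that
# average-expression bins contain comparable non-marker genes. Used for
# scoring/labeling tests without running the full simulator.
make_two_pop_norm <- function(n_genes = 300, n1 = 50, n2 = 50,
                              markers = paste0("G", 1:10), fold = 6,
                              base_mean = 2, seed = 1) {
  set.seed(seed)
  n_cells <- n1 + n2
  gene_means <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 0.6)
  mu <- matrix(gene_means, n_genes, n_cells)
  rownames(mu) <- paste0("G", seq_len(n_genes))
  mu[markers, seq_len(n1)] <- mu[markers, seq_len(n1)] * fold
  counts <- matrix(rpois(n_genes * n_cells, lambda = mu), n_genes, n_cells)
  dimnames(counts) <- list(rownames(mu), sprintf("C%03d", seq_len(n_cells)))
  meta <- data.frame(barcode = colnames(counts), sample_id = "S1",
                     patient_id = rep(c("P1", "P2"), c(n1, n2)),
                     tissue = "primary", stringsAsFactors = FALSE)
  log_normalize(new_count_matrix(counts, meta))
}

# Cached medium simulation shared by several expensive tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sc_sim_config(n_patients = 2, cells_per_patient = 300,
                           cell_types = c("ETC", "CAF", "TIL"),
                           n_genes = 300, seed = 42)
      cache <<- simulate_sc(cfg)
    }
    cache
  }
})
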
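test_that("wilcoxon p-values match brute-force enumeration for small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  set.seed(30)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      if (n2 < 1) next
      x <- rnorm(n1); y <- rnorm(n2)
      r <- wilcoxon_rank_sum(x, y)
      expect_equal(r$method, "exact")
      expect_equal(r$p_value, enum_ranksum_p(x, y), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("wilcoxon is symmetric in its arguments and degenerate-safe", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 7))$p_value, 1)
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(15)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcoxon_rank_sum(y, x)$p_value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(), 1), "non-empty")
})

test_that("wilcoxon agrees with the reference implementation at n = 50", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50, 0.3)
    r <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(unname(r$statistic), unname(ref$statistic))
  }
  # tied data against the tie-corrected reference
  for (i in 1:10) {
    x <- rpois(40, 2); y <- rpois(40, 3)
    r <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("find_markers recovers planted markers and orders by the tie rule", {
  sim <- shared_sim()
  nm <- log_normalize(sim$matrix)
  ann <- data.frame(barcode = names(sim$truth), label = unname(sim$truth),
                    stringsAsFactors = FALSE)
  mk <- find_markers(nm, ann)
  sigs <- top_k_signature(mk, k = 20)
  for (ct in names(sim$marker_panel)) {
    recall <- mean(sim$marker_panel[[ct]] %in% sigs[[ct]])
    expect_gte(recall, 0.9)
  }
  # ranking invariant: ascending p, then descending |lfc|, then gene
  one <- mk[mk$cell_type == "ETC", ]
  expect_true(all(diff(one$p_value) >= 0))
  expect_identical(one$rank, seq_len(nrow(one)))

  # per-gene agreement with the scalar test on a subset
  vals <- as.matrix(nm$values)
  in_grp <- ann$label == "ETC"
  for (g in sample(mk$gene[mk$cell_type == "ETC"], 5)) {
    expect_equal(mk$p_value[mk$cell_type == "ETC" & mk$gene == g],
                 wilcoxon_rank_sum(vals[g, in_grp], vals[g, !in_grp])$p_value,
                 tolerance = 1e-12)
  }
})

test_that("find_markers is invariant to cell order", {
  sim <- shared_sim()
  nm <- log_normalize(sim$matrix)
  ann <- data.frame(barcode = names(sim$truth), label = unname(sim$truth),
                    stringsAsFactors = FALSE)
  set.seed(33)
  perm <- sample(ncol(nm$values))
  nm_p <- nm
  nm_p$values <- nm$values[, perm]
  nm_p$cell_meta <- nm$cell_meta[perm, ]
  mk1 <- find_markers(nm, ann, "CAF")
  mk2 <- find_markers(nm_p, ann[perm, ], "CAF")
  expect_equal(mk1, mk2)
})

test_that("uninformative genes are filtered and relabeled nulls stay null", {
  nm <- make_two_pop_norm(n_genes = 100, n1 = 30, n2 = 30, fold = 1, seed = 34)
  ann <- data.frame(barcode = colnames(nm$values),
                    label = rep(c("A", "B"), c(30, 30)),
                    stringsAsFactors = FALSE)
  # constant gene: lfc = 0 < min_lfc
  mk <- find_markers(nm, ann, "A")
  flat <- Matrix::rowMeans(nm$values)
  expect_false(any(mk$gene %in% names(which(flat == max(flat)))[0]))
  # permutation null: random relabelings rarely yield adjusted hits
  set.seed(35)
  hits <- replicate(20, {
    ann$label <- sample(ann$label)
    mk <- find_markers(nm, ann, "A", min_pct = 0, min_lfc = 0)
    sum(mk$adjusted_p < 0.05)
  })
  expect_gte(mean(hits == 0), 0.95)
})

test_that("marker recall is monotone in the planted fold change", {
  recalls <- sapply(c(1.5, 3, 8), function(fold) {
    cfg <- sc_sim_config(n_patients = 1, cells_per_patient = 300,
                         cell_types = c("A", "B"),
                         cell_type_props = c(0.5, 0.5),
                         tumor_types = character(), n_genes = 200,
                         marker_fold = fold, patient_shift_sd = 0, seed = 36)
    sim <- simulate_sc(cfg)
    nm <- log_normalize(sim$matrix)
    ann <- data.frame(barcode = names(sim$truth), label = unname(sim$truth),
                      stringsAsFactors = FALSE)
    mk <- find_markers(nm, ann, "A", min_pct = 0, min_lfc = 0)
    sigs <- top_k_signature(mk, k = 20)
    mean(sim$marker_panel$A %in% sigs$A)
  })
  expect_true(all(diff(recalls) >= 0))
  expect_gte(recalls[3], 0.9)
})

test_that("top_k truncation honors rank, warns when short, resolves ties stably", {
  mt <- data.frame(cell_type = "X", gene = sprintf("g%02d", 1:25),
                   p_value = seq(0.001, 0.025, length.out = 25),
                   adjusted_p = NA, log_fold_change = 1,
                   pct_in = 1, pct_out = 0, rank = 1:25,
                   stringsAsFactors = FALSE)
  expect_identical(top_k_signature(mt, 20)$X, sprintf("g%02d", 1:20))
  expect_warning(out <- top_k_signature(mt[1:12, ], 20), "12")
  expect_length(out$X, 12)

  # tied p at the boundary: order by |lfc| desc then gene name
  nm <- make_two_pop_norm(n_genes = 60, n1 = 20, n2 = 20, fold = 1, seed = 37)
  dense <- as.matrix(nm$values)
  dense["G10", ] <- dense["G11", ]  # two identical genes -> identical p, lfc
  nm$values <- methods::as(Matrix::Matrix(dense, sparse = TRUE),
                           "CsparseMatrix")
  ann <- data.frame(barcode = colnames(nm$values),
                    label = rep(c("A", "B"), c(20, 20)),
                    stringsAsFactors = FALSE)
  mk1 <- find_markers(nm, ann, "A", min_pct = 0, min_lfc = 0)
  mk2 <- find_markers(nm, ann, "A", min_pct = 0, min_lfc = 0)
  expect_identical(mk1$gene, mk2$gene)
  pair <- mk1[mk1$gene %in% c("G10", "G11"), ]
  expect_identical(pair$gene, sort(pair$gene))
})

test_that("hypergeometric enrichment matches closed-form tails", {
  universe <- sprintf("u%02d", 1:20)
  res <- hypergeom_enrich(universe[1:5], list(hit = universe[1:5]), universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  res2 <- hypergeom_enrich(universe, list(all = universe), universe)
  expect_equal(res2$p_value, 1)

  # k = 0: P(X >= 0) = 1
  res3 <- hypergeom_enrich(universe[1:5], list(miss = universe[16:20]),
                           universe)
  expect_equal(res3$k, 0)
  expect_lte(res3$p_value, 1)
  expect_equal(hypergeom_enrich(universe[1:3], list(none = character()),
                                universe)$p_value, 1)
  expect_error(hypergeom_enrich("a", list(t = "a"), character()), "universe")
})

test_that("enrichment p-values are super-uniform under random queries", {
  set.seed(38)
  universe <- sprintf("u%03d", 1:200)
  term <- list(t = universe[1:30])
  ps <- replicate(500, {
    q <- sample(universe, 20)
    hypergeom_enrich(q, term, universe)$p_value
  })
  # discrete test: empirical CDF should not exceed uniform by much
  expect_gte(suppressWarnings(ks.test(ps, "punif",
                                      alternative = "greater")$p.value), 0.01)
})
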
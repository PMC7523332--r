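#' Default pipeline configuration
#'
#' Returns the full parameter set of the end-to-end pipeline with its
#' defaults; supplied values override. A config may also be read from a
#' YAML file via [read_pipeline_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_sheet = NULL,     # path to the sample-sheet TSV (required)
    marker_panel = NULL,     # gene-set TSV; NULL uses default_marker_panel()
    subtype_sets = NULL,     # gene-set TSV; NULL skips the subtype stage
    cohort_expr = NULL,      # bulk expression TSV; with cohort_clinical
    cohort_clinical = NULL,  #   enables the survival stage
    min_umi = 1000, min_shannon = 3, max_mito_frac = NULL,
    scale = 1e4,
    n_hvg = 2000, n_pcs = 30, k_neighbors = 20,
    resolution = 0.8,
    min_margin = 0.05, n_bins = 24, n_ctrl = 100,
    min_pct = 0.1, min_lfc = 0.25, top_k = 20,
    hr_method = "mantel-haenszel",
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   fields.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_stage <- function(tab, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Composes the stages in order: QC -> normalize -> embed/cluster ->
#' annotate -> composition -> signatures -> subtype scores -> (survival,
#' when a bulk cohort is configured). Every stage writes a TSV into
#' `out_dir` and a `manifest.json` records parameters, stage outputs and
#' their checksums. Deterministic given `cfg$seed`; with `resume = TRUE`
#' stages whose outputs already exist are recomputed only if an upstream
#' stage ran (outputs are recomputed in memory regardless — resume only
#' skips rewriting identical files).
#'
#' @param cfg Config list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Unused placeholder for stage caching; recomputation is
#'   cheap at supported scales.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(cfg, out_dir, resume = FALSE) {
  if (is.null(cfg$sample_sheet)) stop("config must set sample_sheet")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t0 <- Sys.time()

  sheet <- tryCatch(read_sample_sheet(cfg$sample_sheet),
                    error = function(e) stop("stage io failed: ",
                                             conditionMessage(e)))
  mats <- lapply(seq_len(nrow(sheet)), function(i) {
    m <- read_10x_mtx(sheet$path[i])
    m$cell_meta$sample_id <- sheet$sample_id[i]
    m$cell_meta$patient_id <- sheet$patient_id[i]
    m$cell_meta$tissue <- sheet$tissue[i]
    m
  })
  genes <- rownames(mats[[1]]$counts)
  for (m in mats) {
    if (!identical(rownames(m$counts), genes)) {
      stop("stage io failed: samples have differing gene universes")
    }
  }
  combined <- new_count_matrix(
    do.call(cbind, lapply(mats, function(m) m$counts)),
    do.call(rbind, lapply(mats, function(m) m$cell_meta)))

  qc <- qc_filter(combined, qc_thresholds(cfg$min_umi, cfg$min_shannon,
                                          cfg$max_mito_frac))
  stages$qc <- .write_stage(qc$cells, out_dir, "qc_cells.tsv")

  nm <- log_normalize(qc$matrix, scale = cfg$scale)
  norm_summary <- data.frame(n_genes = nrow(nm$values),
                             n_cells = ncol(nm$values),
                             scale = cfg$scale)
  stages$normalize <- .write_stage(norm_summary, out_dir, "normalize_summary.tsv")

  emb <- embed_cells(nm, n_hvg = cfg$n_hvg, n_pcs = cfg$n_pcs,
                     k_neighbors = cfg$k_neighbors, seed = cfg$seed)
  clusters <- cluster_cells(emb, resolution = cfg$resolution,
                            seed = cfg$seed)
  stages$cluster <- .write_stage(
    data.frame(barcode = names(clusters), cluster = as.integer(clusters)),
    out_dir, "clusters.tsv")

  panel <- if (is.null(cfg$marker_panel)) default_marker_panel()
           else read_gene_sets(cfg$marker_panel)
  ann <- assign_labels(clusters, nm, panel = panel,
                       min_margin = cfg$min_margin, n_bins = cfg$n_bins,
                       n_ctrl = cfg$n_ctrl, seed = cfg$seed)
  stages$annotate <- .write_stage(ann, out_dir, "annotation.tsv")

  comp <- cell_composition(ann)
  stages$composition <- .write_stage(format_composition(comp), out_dir,
                                     "composition.tsv")
  .write_stage(comp, out_dir, "composition_full_precision.tsv")

  markers <- find_markers(nm, ann, min_pct = cfg$min_pct,
                          min_lfc = cfg$min_lfc)
  stages$signatures <- .write_stage(markers, out_dir, "markers.tsv")
  sigs <- top_k_signature(markers, k = cfg$top_k)
  write_gene_sets(sigs, file.path(out_dir, "top_signatures.tsv"))

  if (!is.null(cfg$subtype_sets)) {
    subtype_sets <- read_gene_sets(cfg$subtype_sets)
    sc <- score_subtypes(nm, subtype_sets, n_bins = cfg$n_bins,
                         n_ctrl = cfg$n_ctrl, seed = cfg$seed)
    summ <- rbind(
      cbind(grouping = "cell_type", summarize_scores(sc, ann$label)),
      cbind(grouping = "patient", summarize_scores(sc, ann$patient_id)))
    stages$subtype_scores <- .write_stage(summ, out_dir, "subtype_scores.tsv")
  }

  if (!is.null(cfg$cohort_expr) && !is.null(cfg$cohort_clinical)) {
    cohort <- read_bulk_cohort(cfg$cohort_expr, cfg$cohort_clinical)
    rows <- list()
    for (ct in names(sigs)) {
      res <- tryCatch(
        signature_survival(cohort, sigs[[ct]], hr_method = cfg$hr_method),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[ct]] <- data.frame(cell_type = ct, chi_square = res$chi_square,
                               p_value = res$p_value, hr = res$hr,
                               ci_lo = res$ci95[1], ci_hi = res$ci95[2],
                               n_high = sum(res$groups == "high"),
                               n_low = sum(res$groups == "low"))
    }
    surv_tab <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(cell_type = character(), chi_square = numeric(),
                 p_value = numeric(), hr = numeric(), ci_lo = numeric(),
                 ci_hi = numeric(), n_high = integer(), n_low = integer())
    stages$survival <- .write_stage(surv_tab, out_dir, "survival.tsv")
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("sample_sheet", "marker_panel", "subtype_sets",
                         "cohort_expr", "cohort_clinical")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("pdactme")),
    params = cfg[setdiff(names(cfg), names(inputs))],
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
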
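#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Single-cell side: five patients, five planted cell types (ETC and EMT
# tumor cells carry patient-specific expression shifts; CAF/TIL/TAM mix
# across patients), written as per-patient 10x MTX triplets with a
# sample sheet and the planted marker panel. Bulk side: a 200-patient
# cohort whose hazard depends on a planted 20-gene signature
# (top-vs-bottom quartile log HR = log 2.76), plus a clinical table.

suppressMessages(library(pdactme))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

message("Simulating the single-cell cohort ...")
cfg <- sc_sim_config(seed = seed)
sim <- simulate_sc(cfg)

sheet <- NULL
for (p in unique(sim$matrix$cell_meta$patient_id)) {
  cells <- sim$matrix$cell_meta$patient_id == p
  sub <- new_count_matrix(sim$matrix$counts[, cells, drop = FALSE],
                          sim$matrix$cell_meta[cells, , drop = FALSE])
  write_10x_mtx(sub, file.path(out, p))
  sheet <- rbind(sheet, data.frame(sample_id = p, path = p,
                                   patient_id = p, tissue = "primary"))
}
write.table(sheet, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gene_sets(sim$marker_panel, file.path(out, "marker_panel.tsv"))
write.table(data.frame(barcode = names(sim$truth), true_type = sim$truth),
            file.path(out, "sc_truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("  %d cells from %d patients, %d genes, %d planted markers/type",
                ncol(sim$matrix$counts), cfg$n_patients, cfg$n_genes,
                cfg$n_markers_per_type))

message("Simulating the bulk survival cohort ...")
bcfg <- bulk_sim_config(seed = seed)
bulk <- simulate_bulk(bcfg)
write_bulk_cohort(bulk$cohort, file.path(out, "bulk_expr.tsv"),
                  file.path(out, "bulk_clinical.tsv"))
write.table(data.frame(patient_id = names(bulk$truth), latent = bulk$truth),
            file.path(out, "bulk_truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_gene_sets(list(planted_signature = bcfg$signature_genes),
                file.path(out, "bulk_signature.tsv"))
message(sprintf("  %d patients, %d genes, planted quartile HR %.2f, %d%% censoring",
                bcfg$n_patients, bcfg$n_genes, exp(bcfg$beta),
                round(100 * bcfg$censor_rate)))
message("Inputs written under ", out)
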
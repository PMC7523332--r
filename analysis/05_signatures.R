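#!/usr/bin/env Rscript
# Stage 5: one-vs-rest marker signatures and gene-set enrichment.
#
# Wilcoxon rank-sum of each labeled cell type against all other cells,
# BH-adjusted, ranked by p then |lfc|, truncated to the top 20 genes per
# type. The top-20 sets are then tested for over-representation of the
# planted marker panels by the hypergeometric test: each derived
# signature should hit its own panel and no other.

suppressMessages(library(pdactme))

out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

filtered <- read_10x_mtx("results/qc/filtered")
nm <- log_normalize(filtered)
ann <- read.delim("results/annotation/annotation.tsv")

markers <- find_markers(nm, ann, min_pct = 0.1, min_lfc = 0.25)
write.table(markers, file.path(out, "markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sigs <- top_k_signature(markers, k = 20)
write_gene_sets(sigs, file.path(out, "top20_signatures.tsv"))
message(sprintf("Derived top-20 signatures for %d cell types from %d tested genes",
                length(sigs), length(unique(markers$gene))))

panel <- read_gene_sets("results/data/marker_panel.tsv")
recall <- sapply(names(panel), function(ct)
  if (ct %in% names(sigs)) mean(panel[[ct]] %in% sigs[[ct]]) else NA)
message("Planted-marker recall in the top-20 signatures:")
print(round(recall, 3))

universe <- rownames(nm$values)
enr <- do.call(rbind, lapply(names(sigs), function(ct) {
  cbind(signature = ct, hypergeom_enrich(sigs[[ct]], panel, universe))
}))
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top_hit <- sapply(split(enr, enr$signature),
                  function(tab) tab$term[which.min(tab$p_value)])
message("Strongest enrichment per derived signature:")
print(top_hit)
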
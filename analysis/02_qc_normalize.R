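#!/usr/bin/env Rscript
# Stage 2: per-cell quality control and normalization.
#
# Cells with library size < 1000 UMI or Shannon diversity < 3 (natural
# log) are removed; cells at a threshold are kept. The mitochondrial
# fraction is reported, not filtered. The filtered matrix is written
# back as a 10x triplet for the downstream stages.

suppressMessages(library(pdactme))

data_dir <- "results/data"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sheet <- read_sample_sheet(file.path(data_dir, "samples.tsv"))
mats <- lapply(seq_len(nrow(sheet)), function(i) read_10x_mtx(sheet$path[i]))
combined <- new_count_matrix(
  do.call(cbind, lapply(mats, function(m) m$counts)),
  do.call(rbind, lapply(mats, function(m) m$cell_meta)))
message(sprintf("Loaded %d cells x %d genes from %d samples",
                ncol(combined$counts), nrow(combined$counts), nrow(sheet)))

res <- qc_filter(combined, qc_thresholds(min_umi = 1000, min_shannon = 3))
write.table(res$cells, file.path(out, "qc_cells.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$samples, file.path(out, "qc_samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_10x_mtx(res$matrix, file.path(out, "filtered"))

kept <- sum(res$cells$kept)
message(sprintf("QC kept %d / %d cells (%.1f%%); removed %d for library size, %d for diversity",
                kept, nrow(res$cells), 100 * kept / nrow(res$cells),
                sum(res$cells$total_umi < 1000),
                sum(res$cells$total_umi >= 1000 & res$cells$shannon < 3)))
message(sprintf("Median library size %d UMI; median Shannon %.2f",
                round(median(res$cells$total_umi)), median(res$cells$shannon)))
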
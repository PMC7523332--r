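#!/usr/bin/env Rscript
# Stage 7: signature-score survival analysis of the bulk cohort.
#
# For each signature: binarize genes against their cohort medians, sum
# to a per-patient score, stratify into the extreme score quartiles
# (boundary ties included), and compare the high and low groups by
# Kaplan-Meier / Mantel-Cox log-rank with a Mantel-Haenszel hazard
# ratio. The planted hazardous signature should separate the groups;
# a background signature should not.

suppressMessages(library(pdactme))

out <- "results/survival"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- read_bulk_cohort("results/data/bulk_expr.tsv",
                           "results/data/bulk_clinical.tsv")
planted <- read_gene_sets("results/data/bulk_signature.tsv")$planted_signature
background <- grep("^BG", colnames(cohort$expr), value = TRUE)[1:20]

rows <- NULL
for (sig_name in c("planted_signature", "background_signature")) {
  sig <- if (sig_name == "planted_signature") planted else background
  res <- signature_survival(cohort, sig)
  message(sprintf("%s: chi-square %.2f, p %.3g, HR %.2f [%.2f, %.2f], high n=%d low n=%d",
                  sig_name, res$chi_square, res$p_value, res$hr,
                  res$ci95[1], res$ci95[2],
                  sum(res$groups == "high"), sum(res$groups == "low")))
  rows <- rbind(rows, data.frame(
    signature = sig_name, chi_square = res$chi_square,
    p_value = res$p_value, hr = res$hr,
    ci_lo = res$ci95[1], ci_hi = res$ci95[2],
    n_high = sum(res$groups == "high"), n_low = sum(res$groups == "low")))
  write.table(data.frame(patient_id = names(res$scores),
                         score = res$scores, group = res$groups),
              file.path(out, paste0(sig_name, "_groups.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  km <- rbind(cbind(group = "high", res$km_high),
              cbind(group = "low", res$km_low))
  write.table(km, file.path(out, paste0(sig_name, "_km.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(rows, file.path(out, "survival_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
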
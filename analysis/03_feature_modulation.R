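#!/usr/bin/env Rscript
# Test every feature for modulation by the administered isoflurane
# concentration: per-animal means per concentration, two-sided
# Mann-Whitney U tests for each concentration pair, Benjamini-Hochberg
# FDR control within each feature's family of three pairwise tests.
# Writes results/modulation_report.tsv.

source("analysis/00_config.R")

ft <- data.table::fread(file.path(RESULTS_DIR, "features.tsv"),
                        data.table = FALSE)
report <- modulation_report(ft, q = 0.05)
write_tsv(report, file.path(RESULTS_DIR, "modulation_report.tsv"))
message("Wrote ", file.path(RESULTS_DIR, "modulation_report.tsv"),
        " (BH family: ", attr(report, "bh_family"), ")")

sig <- aggregate(reject ~ feature, report, sum)
sig <- sig[order(-sig$reject), ]
message("Features significant in all 3 concentration pairs: ",
        paste(sig$feature[sig$reject == 3], collapse = ", "))
message("Top modulated features (significant pairs / 3):")
print(utils::head(sig, 10), row.names = FALSE)
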
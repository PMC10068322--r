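#!/usr/bin/env Rscript

# Step 3 - differential PAS cleavage between conditions.
#
# On the genome-scale simulated count matrix: median-of-ratios size factors
# from the upstream windows, the expression filter, per-gene NB interaction
# Wald tests, and the quadrant classification at P < 0.05. Calls are
# compared against the generator's ground truth.

suppressPackageStartupMessages(library(pascleave))

x <- read_counts_tsv("results/sim_counts.tsv")
truth <- read.delim("results/sim_truth.tsv")

flt <- filter_low_counts(x, min_reads = 10L)
cat(sprintf("expression filter: %d/%d genes kept\n",
            nrow(flt$kept$up), nrow(x$up)))
x <- flt$kept

sf <- estimate_size_factors(x)
cat("size factors:", paste(sprintf("%s=%.3f", names(sf), sf),
                           collapse = ", "), "\n")
disp <- estimate_dispersion(x, sf)
cat(sprintf("dispersion: median %.3f (trend-shrunk method of moments)\n",
            median(disp)))

res <- classify_regulation(test_differential_cleavage(x, sf, disp),
                           alpha = 0.05)
write.table(res, "results/cleavage_test_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(res$label))

tr <- truth[match(res$gene_id, truth$gene_id), ]
called <- res$label == "repressed_cleavage"
cat(sprintf("vs truth: sensitivity %.3f, precision %.3f (raw p < 0.05)\n",
            mean(called[tr$regulated]),
            sum(called & tr$regulated) / sum(called)))
called_bh <- !is.na(res$q_value) & res$q_value < 0.05 & res$delta_log2 > 0
cat(sprintf("          sensitivity %.3f, precision %.3f (BH q < 0.05)\n",
            mean(called_bh[tr$regulated]),
            sum(called_bh & tr$regulated) / sum(called_bh)))

ratios <- uncleaved_total_ratio_from_counts(x, sf)
write.table(ratios, "results/uncleaved_total_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean uncleaved/total ratio: control %.3f, treated %.3f\n",
            mean(ratios$ratio_control, na.rm = TRUE),
            mean(ratios$ratio_treated, na.rm = TRUE)))
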
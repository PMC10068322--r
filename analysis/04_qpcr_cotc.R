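#!/usr/bin/env Rscript

# Step 4 - the companion single-gene assays.
#
# (i) delta-Ct ratio statistics on simulated qPCR measurements of a gene
# whose cleavage efficiency drops upon treatment; (ii) primer-walk
# localization of a CoTC cleavage interval, with the oligo-dT test for
# alternative-PAS use; (iii) AT-rich element scanning of a simulated
# 3'-flanking sequence carrying an embedded AT island.

suppressPackageStartupMessages(library(pascleave))

# qPCR: uncleaved fraction 0.05 untreated vs 0.40 treated, 3 replicates
cts <- lapply(1:3, function(rep) {
  simulate_ct(c(total_untreated = 100, uncleaved_untreated = 5,
                total_treated = 80, uncleaved_treated = 32),
              noise_sd = 0.15, seed = 20 + rep)
})
ratio_of <- function(cond) {
  r <- vapply(cts, function(ct) {
    uncleaved_total_ratio(ct$ct[ct$target == paste0("total_", cond)],
                          ct$ct[ct$target == paste0("uncleaved_", cond)])
  }, numeric(1))
  aggregate_ratios(r)
}
cat(sprintf("uncleaved/total ratio: untreated %.3f, treated %.3f (truth 0.05 / 0.40)\n",
            ratio_of("untreated"), ratio_of("treated")))

# primer walk over the probe ladder, true cleavage 1,200 nt past the PAS
probes <- c(229, 558, 852, 1000, 1400, 1800)
walk <- simulate_primer_walk(1200, probes)
ci <- infer_cleavage_interval(walk)
print(ci)
oligo_dt <- transform(walk, amplified = FALSE)
cat("poly(A) status:", classify_polyA_status(walk, oligo_dt), "\n")

# AT-rich scan of a 5-kb flank with a 300-nt 80%-AT island at +1,200 nt
set.seed(30)
base_p <- function(at) c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
piece <- function(n, at) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                      base_p(at)), collapse = "")
flank <- paste0(piece(1200, 0.45), piece(300, 0.8), piece(3500, 0.45))
els <- scan_at_rich_elements(flank, window = 100, threshold = 0.65)
write.table(els, "results/at_rich_elements.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("AT-rich elements found: %d\n", nrow(els)))
print(els)
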
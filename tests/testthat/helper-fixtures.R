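# Shared fixture builders. Everything is generated in code under a fixed
# seed; no data files.

# Random transcript-level annotation: several transcripts per gene symbol,
# one chromosome/strand per symbol, 0-based half-open coordinates.
random_annotation <- function(n_genes, seed, chroms = c("chr1", "chr2")) {
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n_genes), function(g) {
      n_tx <- sample(1:4, 1)
      chrom <- sample(chroms, 1)
      strand <- sample(c("+", "-"), 1)
      anchor <- sample(10000:2000000, 1)
      start <- anchor + sample(0:500, n_tx, replace = TRUE)
      end <- start + sample(1000:20000, n_tx, replace = TRUE)
      data.frame(chrom = chrom, start = start, end = end, strand = strand,
                 gene_id = sprintf("rg%04d", g))
    })
    do.call(rbind, recs)
  })
}

# Random gene layouts for overlap-filter oracles: genes scattered on one
# chromosome densely enough that some downstream windows collide.
random_gene_layout <- function(n_genes, seed, span = 2e6) {
  withr::with_seed(seed, {
    start <- sort(sample.int(span, n_genes))
    len <- sample(1000:15000, n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    data.frame(gene_id = sprintf("lg%04d", seq_len(n_genes)),
               chrom = "chr1", start = start, end = start + len,
               strand = strand,
               pas = ifelse(strand == "+", start + len, start))
  })
}

# Quadratic all-pairs oracle for the overlap-discard rule.
overlap_discard_oracle <- function(windows, genes, stranded = FALSE) {
  vapply(seq_len(nrow(windows)), function(i) {
    ds <- windows$downstream_start[i]; de <- windows$downstream_end[i]
    any(vapply(seq_len(nrow(genes)), function(j) {
      if (genes$gene_id[j] == windows$gene_id[i]) return(FALSE)
      if (genes$chrom[j] != windows$chrom[i]) return(FALSE)
      if (stranded && genes$strand[j] != windows$strand[i]) return(FALSE)
      ds < genes$end[j] && genes$start[j] < de
    }, logical(1)))
  }, logical(1))
}

# The published p53 primer walk: products amplified up to 1,000 nt
# downstream of the PAS, lost at 1,400 nt and beyond.
p53_walk_random_primed <- function() {
  data.frame(offset = c(229, 558, 852, 1000, 1400, 1800),
             amplified = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
}

p53_walk_oligodt <- function() {
  data.frame(offset = c(229, 558, 852, 1000, 1400, 1800),
             amplified = FALSE)
}

# Exhaustive O(n*w) sliding-window AT-scan oracle, independent of the
# cumulative-sum implementation.
scan_at_oracle <- function(sequence, window, threshold) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  empty <- data.frame(start = integer(), end = integer(),
                      at_fraction = numeric())
  if (n < window) return(empty)
  covered <- logical(n)
  for (i in seq_len(n - window + 1)) {
    if (sum(chars[i:(i + window - 1)] %in% c("A", "T")) / window >=
        threshold) {
      covered[i:(i + window - 1)] <- TRUE
    }
  }
  if (!any(covered)) return(empty)
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- lapply(which(r$values), function(k) {
    s <- starts[k] - 1L
    e <- ends[k]
    data.frame(start = s, end = e,
               at_fraction = sum(chars[(s + 1L):e] %in% c("A", "T")) /
                 (e - s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_dna <- function(n, seed, at_prob = 0.5) {
  withr::with_seed(seed, {
    p <- c(at_prob / 2, (1 - at_prob) / 2, (1 - at_prob) / 2, at_prob / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
  })
}
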
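#' Simulation configuration for PAS window count matrices
#'
#' The generative model mirrors the structure the window-counting analysis
#' assumes. Per gene `g`, condition `c` and sample `j` (size factor `s_j`):
#' upstream counts are `NB(mean = s_j * mu_g, dispersion = alpha)` and
#' downstream counts `NB(mean = s_j * mu_g * r_gc, alpha)`, so the expected
#' downstream/upstream ratio is exactly the readthrough fraction `r_gc`.
#' `mu_g` is log-normal. A fraction `frac_regulated` of genes has its
#' treated-condition readthrough multiplied by `effect_fold` (capped at 1;
#' `r = 1` means no PAS cleavage at all).
#'
#' Defaults reflect the study conditions the pipeline targets: two
#' conditions with two biological replicates each, 5,000 genes, and NB
#' dispersion 0.05.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_reps Replicates per condition (default 2).
#' @param mean_log,sd_log Log-normal parameters of the per-gene upstream
#'   mean `mu_g` (defaults `log(200)` and 1).
#' @param readthrough Baseline downstream/upstream ratio `r` in `(0, 1]`
#'   (default 0.3).
#' @param dispersion NB dispersion `alpha >= 0` (0 = Poisson; default 0.05).
#' @param frac_regulated Fraction of genes whose treated readthrough changes
#'   (default 0).
#' @param effect_fold Multiplier on `r` in the treated condition for
#'   regulated genes (default 1).
#' @param library_scalars Per-sample library size multipliers (length
#'   `2 * n_reps`; default all 1).
#' @param seed Integer seed fixing the output bit-for-bit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L, n_reps = 2L,
                       mean_log = log(200), sd_log = 1,
                       readthrough = 0.3, dispersion = 0.05,
                       frac_regulated = 0, effect_fold = 1,
                       library_scalars = NULL, seed = 1L) {
  bad <- character()
  if (n_genes < 1) bad <- c(bad, "n_genes")
  if (n_reps < 1) bad <- c(bad, "n_reps")
  if (!(readthrough > 0 && readthrough <= 1)) bad <- c(bad, "readthrough")
  if (dispersion < 0) bad <- c(bad, "dispersion")
  if (frac_regulated < 0 || frac_regulated > 1)
    bad <- c(bad, "frac_regulated")
  if (effect_fold <= 0) bad <- c(bad, "effect_fold")
  if (is.null(library_scalars)) library_scalars <- rep(1, 2L * n_reps)
  if (length(library_scalars) != 2L * n_reps || any(library_scalars <= 0))
    bad <- c(bad, "library_scalars")
  if (length(bad)) stop("invalid sim_config field(s): ",
                        paste(bad, collapse = ", "))
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 mean_log = mean_log, sd_log = sd_log,
                 readthrough = readthrough, dispersion = dispersion,
                 frac_regulated = frac_regulated, effect_fold = effect_fold,
                 library_scalars = library_scalars,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-entity substream: draws for gene g never depend on how
# many other genes exist, so growing a simulation leaves earlier genes'
# counts untouched.
with_substream <- function(seed, i, expr) {
  sub <- (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(sub))
  expr
}

rnb <- function(n, mean, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mean))
  stats::rnbinom(n, size = 1 / alpha, mu = mean)
}

#' Simulate a PAS window count matrix with ground truth
#'
#' @param config A [sim_config()].
#' @return list with `counts` (a [pas_counts()] matrix; samples
#'   `control_1..n`, `treated_1..n`) and `truth` (data.frame `gene_id`,
#'   `mu`, `r_control`, `r_treated`, `true_delta_log2 =
#'   log2(r_treated/r_control)`, `regulated`).
#' @export
simulate_count_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  reps <- config$n_reps
  s <- config$library_scalars
  genes <- sprintf("gene%05d", seq_len(n))
  samples <- data.frame(
    sample_id = c(paste0("control_", seq_len(reps)),
                  paste0("treated_", seq_len(reps))),
    condition = rep(c("control", "treated"), each = reps),
    replicate = rep(seq_len(reps), 2L))
  up <- matrix(0L, n, 2L * reps, dimnames = list(genes, samples$sample_id))
  down <- up
  mu <- numeric(n); r_ctrl <- numeric(n); r_trt <- numeric(n)
  regulated <- logical(n)
  treated <- samples$condition == "treated"
  for (g in seq_len(n)) {
    draws <- with_substream(config$seed, g, {
      mu_g <- stats::rlnorm(1L, config$mean_log, config$sd_log)
      reg <- stats::runif(1L) < config$frac_regulated
      r_c <- config$readthrough
      r_t <- if (reg) min(r_c * config$effect_fold, 1) else r_c
      r_gc <- ifelse(treated, r_t, r_c)
      list(mu = mu_g, reg = reg, r_c = r_c, r_t = r_t,
           up = rnb(length(s), s * mu_g, config$dispersion),
           down = rnb(length(s), s * mu_g * r_gc, config$dispersion))
    })
    mu[g] <- draws$mu; regulated[g] <- draws$reg
    r_ctrl[g] <- draws$r_c; r_trt[g] <- draws$r_t
    up[g, ] <- draws$up; down[g, ] <- draws$down
  }
  truth <- data.frame(gene_id = genes, mu = mu, r_control = r_ctrl,
                      r_treated = r_trt,
                      true_delta_log2 = log2(r_trt / r_ctrl),
                      regulated = regulated)
  list(counts = pas_counts(up, down, samples), truth = truth)
}

#' Build a toy genome of non-overlapping gene models
#'
#' Genes of varying length are laid out along one chromosome with intergenic
#' gaps large enough that no downstream window overlaps a neighbour,
#' alternating strands. Optionally emits a random nucleotide sequence.
#'
#' @param n_genes Number of genes (default 50).
#' @param gene_length_range Gene length bounds in nt (default 2000-8000).
#' @param gap Intergenic gap in nt (default 3000; keep it above the window
#'   width plus any readthrough extension to avoid overlap discards).
#' @param seed Integer seed.
#' @param emit_sequence Also generate a uniform-random ACGT chromosome
#'   sequence?
#' @return list of class `toy_genome`: `genes` (a gene-model data.frame as
#'   from [load_gene_models()]), `chrom_lengths` (named integer) and
#'   optionally `sequence` (named character).
#' @export
simulate_toy_genome <- function(n_genes = 50L,
                                gene_length_range = c(2000L, 8000L),
                                gap = 3000L, seed = 1L,
                                emit_sequence = FALSE) {
  lens <- with_substream(seed, 0L, {
    as.integer(stats::runif(n_genes, gene_length_range[1L],
                            gene_length_range[2L]))
  })
  starts <- cumsum(c(gap, utils::head(lens + gap, -1L)))
  ends <- starts + lens
  strand <- rep(c("+", "-"), length.out = n_genes)
  genes <- data.frame(gene_id = sprintf("tg%03d", seq_len(n_genes)),
                      chrom = "chrT", start = starts, end = ends,
                      strand = strand,
                      pas = ifelse(strand == "+", ends, starts))
  chrom_len <- max(ends) + gap
  out <- list(genes = genes, chrom_lengths = c(chrT = chrom_len))
  if (emit_sequence) {
    seqs <- with_substream(seed, 1L, {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = "")
    })
    out$sequence <- c(chrT = seqs)
  }
  structure(out, class = "toy_genome")
}

#' Simulate stranded single-end alignments over a toy genome
#'
#' Emulates a reverse-stranded (dUTP) nuclear RNA-seq library: per gene, a
#' Poisson number of 100-nt single-end reads whose alignment strand is
#' antisense to the gene. A fraction `readthrough` of a gene's transcripts is
#' PAS-uncleaved and extends `extension` nt past the PAS; reads start
#' uniformly over the transcript. MAPQ is drawn from a two-point
#' distribution. No sequence-level error model: the counting contract
#' depends only on span, strand and MAPQ, so alignment records are emitted
#' directly.
#'
#' A companion truth table of per-window counts under `truth_params` is
#' computed by the generator's own brute-force per-read assignment
#' ([count_reads_bruteforce()]), independent of the production counter.
#'
#' @param toy A [simulate_toy_genome()] object.
#' @param reads_per_gene Expected reads per gene (default 200).
#' @param readthrough Fraction of PAS-uncleaved transcripts (default 0.3).
#' @param extension Readthrough extension past the PAS in nt (default 1000).
#' @param read_length Read length in nt (default 100).
#' @param mapq_values,mapq_probs Two-point MAPQ distribution (defaults 60/10
#'   with probabilities 0.9/0.1).
#' @param seed Integer seed.
#' @param width Window width used for the companion truth table.
#' @param truth_params [counting_params()] for the truth table.
#' @return list: `alignments` (data.frame `qname`, `chrom`, `start`, `end`,
#'   `strand`, `mapq`), `windows` (the PAS window pairs), `truth`
#'   (data.frame `gene_id`, `upstream`, `downstream`).
#' @export
simulate_alignments <- function(toy, reads_per_gene = 200,
                                readthrough = 0.3, extension = 1000L,
                                read_length = 100L,
                                mapq_values = c(60L, 10L),
                                mapq_probs = c(0.9, 0.1), seed = 1L,
                                width = 500L,
                                truth_params = counting_params()) {
  stopifnot(inherits(toy, "toy_genome"))
  genes <- toy$genes
  per_gene <- lapply(seq_len(nrow(genes)), function(g) {
    with_substream(seed, g, {
      n <- stats::rpois(1L, reads_per_gene)
      if (n == 0L) return(NULL)
      uncleaved <- stats::runif(n) < readthrough
      glen <- genes$end[g] - genes$start[g]
      span <- ifelse(uncleaved, glen + extension, glen)
      # read start offset in transcript coordinates (5' end of transcript)
      offs <- floor(stats::runif(n) * pmax(span - read_length, 1))
      if (genes$strand[g] == "+") {
        start <- genes$start[g] + offs
      } else {
        start <- genes$end[g] - offs - read_length
      }
      aln_strand <- if (genes$strand[g] == "+") "-" else "+"
      data.frame(qname = sprintf("%s_r%04d", genes$gene_id[g], seq_len(n)),
                 chrom = genes$chrom[g],
                 start = as.integer(start),
                 end = as.integer(start + read_length),
                 strand = aln_strand,
                 mapq = sample(mapq_values, n, replace = TRUE,
                               prob = mapq_probs))
    })
  })
  aln <- do.call(rbind, per_gene)
  if (is.null(aln)) {
    aln <- data.frame(qname = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), mapq = integer())
  }
  aln <- aln[aln$start >= 0L, , drop = FALSE]
  rownames(aln) <- NULL
  windows <- build_pas_windows(genes, width = width)
  truth <- count_reads_bruteforce(aln, windows, truth_params)
  list(alignments = aln, windows = windows, truth = truth)
}

#' Brute-force per-read window counting oracle
#'
#' Reference implementation of the counting contract as an explicit loop
#' over reads: MAPQ filter, >= 1 bp span overlap, strand compatibility,
#' then the ambiguity rule for reads touching both windows of one pair. Used
#' to generate truth tables and to cross-check the production counter; kept
#' deliberately naive and independent of it.
#'
#' @param alignments data.frame `chrom`, `start`, `end`, `strand`, `mapq`.
#' @param windows Window pairs from [build_pas_windows()].
#' @param params A [counting_params()].
#' @return data.frame `gene_id`, `upstream`, `downstream`.
#' @export
count_reads_bruteforce <- function(alignments, windows,
                                   params = counting_params()) {
  n_genes <- nrow(windows)
  up <- integer(n_genes); down <- integer(n_genes)
  for (i in seq_len(nrow(alignments))) {
    if (alignments$mapq[i] < params$min_mapq) next
    same_chrom <- alignments$chrom[i] == windows$chrom
    ok_strand <- switch(params$strandedness,
                        unstranded = rep(TRUE, n_genes),
                        forward = alignments$strand[i] == windows$strand,
                        reverse = alignments$strand[i] != windows$strand)
    in_up <- same_chrom & ok_strand &
      alignments$start[i] < windows$upstream_end &
      windows$upstream_start < alignments$end[i]
    in_down <- same_chrom & ok_strand &
      alignments$start[i] < windows$downstream_end &
      windows$downstream_start < alignments$end[i]
    if (params$ambiguous_policy == "drop") {
      amb <- in_up & in_down
      in_up <- in_up & !amb
      in_down <- in_down & !amb
    }
    up <- up + in_up
    down <- down + in_down
  }
  data.frame(gene_id = windows$gene_id, upstream = as.integer(up),
             downstream = as.integer(down))
}

#' Write alignment records as a SAM file
#'
#' Emits a minimal valid coordinate-sorted SAM (header `@HD`/`@SQ`, FLAG
#' 0/16 for +/- alignments, 1-based POS, all-match CIGAR, `*` SEQ/QUAL).
#'
#' @param alignments data.frame from [simulate_alignments()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(alignments)) {
    a <- alignments[order(alignments$chrom, alignments$start), ]
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                       a$qname, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                       a$start + 1L, a$mapq, a$end - a$start), con)
  }
  invisible(path)
}

#' Simulate a primer-walk amplification profile
#'
#' A probe amplifies iff its offset lies short of the true cleavage offset;
#' amplified probes are flipped to negative with probability
#' `false_negative_rate` (PCR dropout).
#'
#' @param true_cleavage_offset True cleavage position, nt downstream of the
#'   PAS.
#' @param probe_offsets Strictly increasing probe offsets (nt).
#' @param false_negative_rate Dropout probability (default 0).
#' @param seed Integer seed.
#' @return data.frame `offset`, `amplified` with attribute
#'   `true_cleavage_offset`.
#' @export
simulate_primer_walk <- function(true_cleavage_offset, probe_offsets,
                                 false_negative_rate = 0, seed = 1L) {
  stopifnot(!is.unsorted(probe_offsets, strictly = TRUE))
  amp <- probe_offsets < true_cleavage_offset
  if (false_negative_rate > 0) {
    amp <- with_substream(seed, 0L, {
      amp & stats::runif(length(amp)) >= false_negative_rate
    })
  }
  structure(data.frame(offset = probe_offsets, amplified = amp),
            true_cleavage_offset = true_cleavage_offset)
}

#' Simulate qPCR Ct values from true template quantities
#'
#' `Ct = c0 - log_E(quantity) + N(0, noise_sd)`: halving the template delays
#' detection by one cycle at perfect efficiency. The additive constant `c0`
#' cancels from every ratio statistic.
#'
#' @param quantities Named positive template quantities.
#' @param c0 Ct of a unit quantity (default 30).
#' @param efficiency Per-cycle amplification factor (default 2).
#' @param noise_sd Gaussian Ct noise, cycles (default 0).
#' @param seed Integer seed.
#' @return data.frame `target`, `quantity`, `ct`.
#' @export
simulate_ct <- function(quantities, c0 = 30, efficiency = 2,
                        noise_sd = 0, seed = 1L) {
  if (any(quantities <= 0)) stop("quantities must be positive")
  ct <- with_substream(seed, 0L, {
    c0 - log(quantities, base = efficiency) +
      stats::rnorm(length(quantities), 0, noise_sd)
  })
  data.frame(target = if (is.null(names(quantities))) {
    paste0("q", seq_along(quantities))
  } else names(quantities),
  quantity = as.numeric(quantities), ct = as.numeric(ct))
}
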
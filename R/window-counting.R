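#' Read-counting parameters
#'
#' @param min_mapq Minimum Phred-scaled mapping quality; alignments below it
#'   are ignored (default 20).
#' @param strandedness Library strand rule deciding whether an alignment is
#'   compatible with a window: `"reverse"` (dUTP-type stranded protocols: the
#'   alignment strand is the opposite of the transcript/window strand, the
#'   default), `"forward"` (same strand) or `"unstranded"` (ignored).
#' @param ambiguous_policy What to do with an alignment overlapping both
#'   windows of one gene's pair: `"drop"` it (default) or `"count_both"`.
#' @return A list of class `counting_params`.
#' @export
counting_params <- function(min_mapq = 20L,
                            strandedness = c("reverse", "forward",
                                             "unstranded"),
                            ambiguous_policy = c("drop", "count_both")) {
  min_mapq <- as.integer(min_mapq)
  stopifnot(min_mapq >= 0L)
  structure(list(min_mapq = min_mapq,
                 strandedness = match.arg(strandedness),
                 ambiguous_policy = match.arg(ambiguous_policy)),
            class = "counting_params")
}

#' Load alignments from a SAM/BAM file
#'
#' Unmapped, secondary (0x100) and supplementary (0x800) records are excluded
#' up front so that one sequenced read contributes at most once; MAPQ
#' filtering happens later, at counting time. SAM input is converted to BAM
#' in a temporary directory via Rsamtools.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open
#'   aligned reference span, deletions/splices included), `strand`, `mapq`.
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "strand", "mapq", "cigar"))
  res <- Rsamtools::scanBam(bam, param = par)[[1L]]
  n <- length(res$pos)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mapq = integer()))
  }
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  data.frame(chrom = as.character(res$rname),
             start = res$pos - 1L,
             end = res$pos - 1L + ref_width,
             strand = as.character(res$strand),
             mapq = ifelse(is.na(res$mapq), 0L, res$mapq))
}

#' Count reads in PAS window pairs
#'
#' An alignment is assigned to a window iff (a) its MAPQ passes `min_mapq`,
#' (b) its aligned reference span overlaps the window by at least 1 bp and
#' (c) its strand is compatible under the library `strandedness`. An
#' alignment overlapping both windows of one pair straddles the PAS and is
#' ambiguous between "total" and "uncleaved": it is dropped (default) or
#' counted in both, per `ambiguous_policy`.
#'
#' @param alignments For one sample, a data.frame as returned by
#'   [read_alignments()] (or a SAM/BAM path); for several samples, a named
#'   list of these, keyed by `sample_id`.
#' @param windows Window pairs from [build_pas_windows()].
#' @param params A [counting_params()] object.
#' @param samples Optional sample sheet (`sample_id`, `condition`,
#'   `replicate`). Required when `alignments` is a list; single-sample input
#'   defaults to one "control" sample.
#' @return A [pas_counts()] matrix.
#' @export
count_window_reads <- function(alignments, windows,
                               params = counting_params(),
                               samples = NULL) {
  if (!is.data.frame(alignments) && !is.list(alignments) &&
      is.character(alignments)) {
    alignments <- read_alignments(alignments)
  }
  if (is.data.frame(alignments)) alignments <- list(sample1 = alignments)
  alignments <- lapply(alignments, function(a) {
    if (is.character(a)) read_alignments(a) else a
  })
  if (is.null(samples)) {
    samples <- data.frame(sample_id = names(alignments),
                          condition = "control",
                          replicate = seq_along(alignments))
  }
  stopifnot(identical(names(alignments), samples$sample_id))
  genes <- windows$gene_id
  up <- matrix(0L, length(genes), length(alignments),
               dimnames = list(genes, names(alignments)))
  down <- up
  for (j in seq_along(alignments)) {
    cnt <- count_one_sample(alignments[[j]], windows, params)
    up[, j] <- cnt$upstream
    down[, j] <- cnt$downstream
  }
  pas_counts(up, down, samples)
}

count_one_sample <- function(aln, windows, params) {
  n_genes <- nrow(windows)
  if (nrow(aln) == 0L) {
    return(list(upstream = integer(n_genes), downstream = integer(n_genes)))
  }
  missing_chrom <- setdiff(unique(windows$chrom), unique(aln$chrom))
  if (length(missing_chrom)) {
    warning("window chromosome(s) absent from alignments: ",
            paste(missing_chrom, collapse = ", "), " (zero counts)")
  }
  keep <- aln$mapq >= params$min_mapq
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) {
    return(list(upstream = integer(n_genes), downstream = integer(n_genes)))
  }
  reads <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start + 1L, aln$end))
  win_gr <- function(s, e) GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(s + 1L, e))
  hit_idx <- function(win) {
    # disjoint seqlevels are already reported above as missing chromosomes
    h <- suppressWarnings(
      GenomicRanges::findOverlaps(reads, win, ignore.strand = TRUE))
    q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
    ok <- switch(params$strandedness,
                 unstranded = rep(TRUE, length(q)),
                 forward = aln$strand[q] == windows$strand[s],
                 reverse = aln$strand[q] != windows$strand[s])
    cbind(read = q[ok], gene = s[ok])
  }
  up_hits <- hit_idx(win_gr(windows$upstream_start, windows$upstream_end))
  down_hits <- hit_idx(win_gr(windows$downstream_start,
                              windows$downstream_end))
  if (params$ambiguous_policy == "drop") {
    key_up <- paste(up_hits[, 1L], up_hits[, 2L])
    key_down <- paste(down_hits[, 1L], down_hits[, 2L])
    amb <- intersect(key_up, key_down)
    up_hits <- up_hits[!key_up %in% amb, , drop = FALSE]
    down_hits <- down_hits[!key_down %in% amb, , drop = FALSE]
  }
  list(upstream = tabulate(up_hits[, 2L], nbins = n_genes),
       downstream = tabulate(down_hits[, 2L], nbins = n_genes))
}

#' Keep genes with enough reads in both regions in at least one condition
#'
#' A gene is kept iff some condition has at least `min_reads` reads summed
#' over its replicates in the upstream region AND at least `min_reads` in the
#' downstream region. This mirrors the expression filter applied before
#' differential testing (without downstream reads somewhere, the
#' uncleaved/total ratio is unobservable).
#'
#' @param x A [pas_counts()] matrix.
#' @param min_reads Threshold on per-condition regional sums (default 10).
#' @return list with `kept` (filtered `pas_counts`) and `report` (data.frame
#'   of the per-condition upstream/downstream sums and the keep decision).
#' @export
filter_low_counts <- function(x, min_reads = 10L) {
  conds <- unique(x$samples$condition)
  sums <- lapply(conds, function(cc) {
    j <- x$samples$condition == cc
    cbind(up = rowSums(x$up[, j, drop = FALSE]),
          down = rowSums(x$down[, j, drop = FALSE]))
  })
  qualifies <- Reduce(`|`, lapply(sums, function(s) {
    s[, "up"] >= min_reads & s[, "down"] >= min_reads
  }))
  report <- data.frame(gene_id = rownames(x$up))
  for (i in seq_along(conds)) {
    report[[paste0("up_", conds[i])]] <- sums[[i]][, "up"]
    report[[paste0("down_", conds[i])]] <- sums[[i]][, "down"]
  }
  report$kept <- qualifies
  list(kept = subset_genes(x, qualifies), report = report)
}
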
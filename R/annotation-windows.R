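#' Load merged gene models from a GTF/BED annotation
#'
#' Collapses all annotation records sharing a gene symbol into a single gene
#' model: the span is the union of the symbol's transcript intervals and the
#' polyadenylation site (PAS) is taken as the strand-appropriate 3' extreme of
#' that union (the merged gene's 3' terminus). Symbols whose records fall on
#' more than one chromosome or strand cannot be merged unambiguously and are
#' dropped with a warning.
#'
#' All coordinates are handled 0-based half-open internally; GTF input
#' (1-based closed) is converted on read.
#'
#' @param annotation Path to a GTF (`.gtf`) or BED (`.bed`) file, or a
#'   data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`) and `gene_id`.
#' @return A data.frame of gene models with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open union span), `strand` and `pas`
#'   (0-based coordinate of the cleavage site: `end` on `+`, `start` on `-`).
#' @examples
#' tx <- data.frame(chrom = "chr1", start = c(100L, 150L), end = c(900L, 1000L),
#'                  strand = "+", gene_id = "G")
#' load_gene_models(tx)
#' @export
load_gene_models <- function(annotation) {
  recs <- if (is.data.frame(annotation)) {
    validate_annotation_df(annotation)
  } else {
    read_annotation_file(annotation)
  }
  if (nrow(recs) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), pas = integer()))
  }

  by_gene <- split(recs, recs$gene_id)
  bad <- vapply(by_gene, function(g) {
    length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L
  }, logical(1))
  if (any(bad)) {
    warning("dropping gene symbol(s) spanning multiple chromosomes or strands: ",
            paste(names(by_gene)[bad], collapse = ", "))
    by_gene <- by_gene[!bad]
  }

  models <- lapply(by_gene, function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end), strand = g$strand[1L])
  })
  out <- do.call(rbind, c(models, list(make.row.names = FALSE)))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$pas <- ifelse(out$strand == "+", out$end, out$start)
  out
}

read_annotation_file <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  gr <- tryCatch(
    switch(ext,
           gtf = , gff = , gff2 = rtracklayer::import(path, format = "gtf"),
           bed = rtracklayer::import(path, format = "bed"),
           stop("unsupported annotation format: .", ext,
                " (expected GTF or BED)")),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  sym <- if ("gene_name" %in% names(md) && !all(is.na(md$gene_name))) {
    as.character(md$gene_name)
  } else if ("gene_id" %in% names(md)) {
    as.character(md$gene_id)
  } else if ("name" %in% names(md)) {
    as.character(md$name)
  } else {
    stop("annotation lacks a gene symbol attribute ",
         "(gene_name / gene_id / name)")
  }
  if (anyNA(sym)) stop("annotation has records without a gene symbol")
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands == "*")) stop("annotation has records without strand")
  # GRanges are 1-based closed; convert to 0-based half-open
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strands,
             gene_id = sym)
}

validate_annotation_df <- function(df) {
  need <- c("chrom", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation data.frame lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) && any(df$start >= df$end))
    stop("malformed annotation record(s) (start >= end) at row(s): ",
         paste(which(df$start >= df$end), collapse = ", "))
  if (nrow(df) && !all(df$strand %in% c("+", "-")))
    stop("malformed annotation record(s) (strand not +/-) at row(s): ",
         paste(which(!df$strand %in% c("+", "-")), collapse = ", "))
  df[need]
}

#' Build the PAS-flanking window pair for each gene
#'
#' Defines, for every gene model, two equal-width windows abutting at the PAS:
#' the transcribed-side window upstream of the PAS captures all transcripts
#' ("total RNA") and the 3'-flanking window downstream of the PAS captures
#' only transcripts not yet cleaved at the PAS ("uncleaved RNA"). On the `+`
#' strand upstream is `[pas - width, pas)` and downstream `[pas, pas + width)`;
#' mirrored on the `-` strand.
#'
#' @param genes Gene models from [load_gene_models()].
#' @param width Window width in nucleotides (default 500).
#' @return A data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `upstream_start`, `upstream_end`, `downstream_start`, `downstream_end`
#'   (all 0-based half-open) and `width`.
#' @export
build_pas_windows <- function(genes, width = 500L) {
  width <- as.integer(width)
  stopifnot(is.data.frame(genes), width >= 1L)
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, genes$pas - width, genes$pas)
  up_end <- up_start + width
  down_start <- ifelse(plus, genes$pas, genes$pas - width)
  down_end <- down_start + width
  if (any(pmin(up_start, down_start) < 0L)) {
    bad <- genes$gene_id[pmin(up_start, down_start) < 0L]
    stop("window extends past coordinate 0 for gene(s): ",
         paste(bad, collapse = ", "))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand,
             upstream_start = as.integer(up_start),
             upstream_end = as.integer(up_end),
             downstream_start = as.integer(down_start),
             downstream_end = as.integer(down_end),
             width = width)
}

#' Discard genes whose downstream window overlaps another gene
#'
#' Reads falling in a downstream window are interpreted as PAS-uncleaved RNA
#' of that gene; if the window lies inside another gene's span the signal is
#' confounded, so the pair is discarded. The overlap test is against gene
#' *spans* (not other genes' windows) and is strand-agnostic by default, since
#' reads from an overlapping gene on either strand can contaminate the window
#' under imperfect library strandedness; set `stranded = TRUE` to only
#' consider same-strand genes.
#'
#' @param windows Window pairs from [build_pas_windows()].
#' @param genes Gene models from [load_gene_models()].
#' @param stranded Consider only same-strand genes when testing overlap?
#' @return A list with `retained` (subset of `windows`) and `discarded`
#'   (data.frame `gene_id`, `reason`, `offending_gene`).
#' @export
filter_overlapping <- function(windows, genes, stranded = FALSE) {
  if (nrow(windows) == 0L) {
    return(list(retained = windows,
                discarded = data.frame(gene_id = character(),
                                       reason = character(),
                                       offending_gene = character())))
  }
  down <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(windows$downstream_start + 1L, windows$downstream_end),
    strand = windows$strand)
  spans <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  hits <- GenomicRanges::findOverlaps(down, spans,
                                      ignore.strand = !stranded)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  other <- windows$gene_id[qh] != genes$gene_id[sh]
  qh <- qh[other]; sh <- sh[other]
  bad <- unique(qh)
  discarded <- if (length(qh)) {
    first <- !duplicated(qh)
    data.frame(gene_id = windows$gene_id[qh[first]],
               reason = "downstream_window_overlaps_gene",
               offending_gene = genes$gene_id[sh[first]])
  } else {
    data.frame(gene_id = character(), reason = character(),
               offending_gene = character())
  }
  retained <- windows[setdiff(seq_len(nrow(windows)), bad), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, discarded = discarded)
}

#' Export window pairs as BED6 records
#'
#' @param windows Window pairs from [build_pas_windows()].
#' @param path Output file path.
#' @return `path`, invisibly. Names are `<gene_id>|up` / `<gene_id>|down`.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- rbind(
    data.frame(chrom = windows$chrom, start = windows$upstream_start,
               end = windows$upstream_end,
               name = paste0(windows$gene_id, "|up"),
               score = 0L, strand = windows$strand),
    data.frame(chrom = windows$chrom, start = windows$downstream_start,
               end = windows$downstream_end,
               name = paste0(windows$gene_id, "|down"),
               score = 0L, strand = windows$strand))
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
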
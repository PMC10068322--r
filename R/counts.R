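#' Construct a PAS window count matrix
#'
#' Dense per-gene, per-sample read counts for the two PAS-flanking regions:
#' `upstream` (total RNA) and `downstream` (PAS-uncleaved RNA).
#'
#' @param upstream,downstream Integer matrices (genes x samples) with
#'   identical dimnames; rownames are gene ids, colnames sample ids.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `replicate`; one row per column of the count matrices, in order.
#' @return An object of class `pas_counts`: a list with elements `up`, `down`
#'   (matrices) and `samples`.
#' @export
pas_counts <- function(upstream, downstream, samples) {
  upstream <- as.matrix(upstream)
  downstream <- as.matrix(downstream)
  stopifnot(identical(dim(upstream), dim(downstream)),
            identical(dimnames(upstream), dimnames(downstream)))
  if (is.null(rownames(upstream)) && nrow(upstream) > 0L)
    stop("count matrices must have gene ids as rownames")
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[need]
  if (nrow(samples) != ncol(upstream))
    stop("samples sheet rows (", nrow(samples),
         ") do not match count matrix columns (", ncol(upstream), ")")
  if (anyDuplicated(samples[c("condition", "replicate")]))
    stop("(condition, replicate) pairs must be unique")
  if (any(upstream < 0) || any(downstream < 0) ||
      any(upstream != round(upstream)) || any(downstream != round(downstream)))
    stop("counts must be non-negative integers")
  colnames(upstream) <- colnames(downstream) <- samples$sample_id
  structure(list(up = upstream, down = downstream, samples = samples),
            class = "pas_counts")
}

#' @export
print.pas_counts <- function(x, ...) {
  cat("pas_counts: ", nrow(x$up), " genes x ", ncol(x$up), " samples (",
      paste(table(x$samples$condition), collapse = " + "),
      " per condition), regions {upstream, downstream}\n", sep = "")
  invisible(x)
}

#' @export
dim.pas_counts <- function(x) dim(x$up)

#' Subset a pas_counts object by gene
#'
#' @param x A `pas_counts` object.
#' @param genes Character vector of gene ids (or logical/integer row index).
#' @return A `pas_counts` restricted to those genes.
#' @export
subset_genes <- function(x, genes) {
  pas_counts(x$up[genes, , drop = FALSE], x$down[genes, , drop = FALSE],
             x$samples)
}

#' Write / read a long-format counts table
#'
#' Columns: gene_id, sample_id, condition, replicate, upstream_count,
#' downstream_count.
#'
#' @param x A `pas_counts` object.
#' @param path TSV path.
#' @return `write_counts_tsv`: `path` invisibly; `read_counts_tsv`: a
#'   `pas_counts`.
#' @export
write_counts_tsv <- function(x, path) {
  long <- data.frame(
    gene_id = rep(rownames(x$up), times = ncol(x$up)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$up)),
    condition = rep(x$samples$condition, each = nrow(x$up)),
    replicate = rep(x$samples$replicate, each = nrow(x$up)),
    upstream_count = as.vector(x$up),
    downstream_count = as.vector(x$down))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  samples <- unique(long[c("sample_id", "condition", "replicate")])
  genes <- unique(long$gene_id)
  up <- matrix(0L, length(genes), nrow(samples),
               dimnames = list(genes, samples$sample_id))
  down <- up
  idx <- cbind(match(long$gene_id, genes),
               match(long$sample_id, samples$sample_id))
  up[idx] <- long$upstream_count
  down[idx] <- long$downstream_count
  pas_counts(up, down, samples)
}
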
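#' Infer a co-transcriptional cleavage interval from a primer walk
#'
#' In a primer walk, a fixed forward primer upstream of the PAS is paired
#' with reverse primers at increasing distances downstream; a primer pair
#' amplifies the template only if the transcript is continuous across it.
#' The cleavage site is therefore bracketed between the farthest amplified
#' probe and the nearest non-amplified one. Offsets measure the reverse
#' primer's PAS-distal end in nt downstream of the PAS, so the interval reads
#' directly as "nt downstream of the PAS".
#'
#' @param profile data.frame with columns `offset` (nt downstream of the PAS,
#'   strictly increasing) and `amplified` (logical or 0/1).
#' @return list of class `cleavage_interval`: `lower` (nt, exclusive; the
#'   last amplified offset, 0 if none), `upper` (nt, inclusive; the first
#'   non-amplified offset, `Inf` when open-ended), `open_ended` (no
#'   non-amplified probe: no cleavage detected within the assayed range) and
#'   `inconsistent` (an amplified probe beyond a non-amplified one - an
#'   experimental failure that is reported, never silently repaired).
#' @examples
#' walk <- data.frame(offset = c(229, 558, 852, 1000, 1400, 1800),
#'                    amplified = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
#' infer_cleavage_interval(walk)
#' @export
infer_cleavage_interval <- function(profile) {
  profile <- validate_profile(profile)
  amp <- profile$offset[profile$amplified]
  non <- profile$offset[!profile$amplified]
  lower <- if (length(amp)) max(amp) else 0
  open_ended <- length(non) == 0L
  upper <- if (open_ended) Inf else min(non)
  structure(list(lower = lower, upper = upper, open_ended = open_ended,
                 inconsistent = !open_ended && lower > upper),
            class = "cleavage_interval")
}

#' @export
print.cleavage_interval <- function(x, ...) {
  if (x$open_ended) {
    cat("cleavage interval: open-ended beyond", x$lower,
        "nt downstream of the PAS\n")
  } else {
    cat("cleavage interval: (", x$lower, ", ", x$upper,
        "] nt downstream of the PAS", sep = "")
    if (x$inconsistent) cat("  [INCONSISTENT profile]")
    cat("\n")
  }
  invisible(x)
}

validate_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("offset", "amplified") %in% names(profile)))
  if (nrow(profile) == 0L) stop("empty probe list")
  if (is.unsorted(profile$offset, strictly = TRUE))
    stop("probe offsets must be strictly increasing")
  profile$amplified <- as.logical(profile$amplified)
  profile
}

#' Classify poly(A) status from random-primed vs oligo-dT-primed walks
#'
#' A transcript cleaved at a downstream CoTC site lacks a poly(A) tail, so
#' the downstream region amplifies from randomly primed cDNA but not from
#' oligo-dT-primed cDNA. Conversely, amplification downstream of the PAS
#' from oligo-dT cDNA indicates a polyadenylated 3' end there, i.e. use of an
#' alternative PAS rather than CoTC cleavage.
#'
#' @param random_profile,oligodt_profile Primer-walk data.frames on the same
#'   probe offsets (see [infer_cleavage_interval()]), reverse-transcribed
#'   with random primers and with oligo-dT respectively.
#' @return `"cotc_cleavage"`, `"alternative_pas"` or `"indeterminate"`
#'   (random-primed template itself yields nothing).
#' @export
classify_polyA_status <- function(random_profile, oligodt_profile) {
  random_profile <- validate_profile(random_profile)
  oligodt_profile <- validate_profile(oligodt_profile)
  if (!identical(random_profile$offset, oligodt_profile$offset))
    stop("random-primed and oligo-dT profiles have mismatched probe offsets")
  if (any(oligodt_profile$amplified)) return("alternative_pas")
  if (!any(random_profile$amplified)) return("indeterminate")
  "cotc_cleavage"
}

#' Scan a 3'-flanking sequence for AT-rich candidate CoTC elements
#'
#' CoTC cleavage tends to occur at AT-rich elements a kilobase or more
#' downstream of the PAS. The scanner slides a `window`-nt window one nt at a
#' time, flags windows whose A/T fraction reaches `threshold` (`N` counts as
#' non-AT), and merges the flagged windows' footprints into maximal disjoint
#' elements, reporting each element's overall A/T fraction. Coordinates are
#' 0-based offsets into `sequence`, i.e. nt downstream of the PAS when the
#' sequence starts at the PAS.
#'
#' @param sequence Character string or [Biostrings::DNAString] over ACGTN.
#' @param window Sliding window width in nt (default 100).
#' @param threshold Minimum windowed A/T fraction (default 0.65).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `at_fraction`; elements are disjoint and sorted. Empty (with a warning)
#'   when the sequence is shorter than the window.
#' @export
scan_at_rich_elements <- function(sequence, window = 100L,
                                  threshold = 0.65) {
  window <- as.integer(window)
  stopifnot(window >= 1L, threshold > 0, threshold <= 1)
  seq <- Biostrings::DNAString(as.character(sequence))
  empty <- data.frame(start = integer(), end = integer(),
                      at_fraction = numeric())
  if (length(seq) < window) {
    warning("sequence (", length(seq), " nt) shorter than scan window (",
            window, " nt)")
    return(empty)
  }
  n <- length(seq)
  is_at <- as.integer(strsplit(as.character(seq), "")[[1L]] %in% c("A", "T"))
  win_at <- as.vector(stats::filter(is_at, rep(1, window), sides = 1))
  win_at <- win_at[window:n]  # window i covers [i-1, i-1+window), 0-based
  hit <- win_at / window >= threshold
  if (!any(hit)) return(empty)
  # an element is a connected component of the union of qualifying windows'
  # coverage, so nearby windows merge and elements come out disjoint
  covered <- logical(n)
  for (i in which(hit)) covered[i:(i + window - 1L)] <- TRUE
  r <- rle(covered)
  ends_pos <- cumsum(r$lengths)
  starts_pos <- ends_pos - r$lengths + 1L
  out <- lapply(which(r$values), function(k) {
    s <- starts_pos[k] - 1L      # 0-based element start
    e <- ends_pos[k]             # 0-based half-open element end
    data.frame(start = s, end = e,
               at_fraction = sum(is_at[(s + 1L):e]) / (e - s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract the 3'-flanking sequence of a gene from a genome
#'
#' Strand-aware: returns `length` nt immediately downstream of the PAS in
#' transcription direction, reverse-complemented for `-`-strand genes so the
#' result always reads 5'->3' away from the PAS.
#'
#' @param genome A named list/character of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param gene One row of a gene-model data.frame ([load_gene_models()]).
#' @param length Number of nt to extract (default 5000, clipped to the
#'   chromosome).
#' @return Character string.
#' @export
pas_flanking_sequence <- function(genome, gene, length = 5000L) {
  chrom_seq <- Biostrings::DNAString(as.character(genome[[gene$chrom]]))
  if (gene$strand == "+") {
    s <- gene$pas + 1L
    e <- min(gene$pas + length, length(chrom_seq))
    as.character(chrom_seq[s:e])
  } else {
    e <- gene$pas
    s <- max(gene$pas - length + 1L, 1L)
    as.character(Biostrings::reverseComplement(chrom_seq[s:e]))
  }
}
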
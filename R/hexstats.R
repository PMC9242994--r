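## Hexamer-set statistics across transcript classes: per-transcript set
## frequencies, two-sample KS comparisons, positional profiles around
## anchored codons, and the 18S-rRNA heptamer split lookup.

#' Hexamer-set frequency of a single transcript
#'
#' Breaks the sequence into overlapping hexamer windows (step 1 nt, i.e. 5-nt
#' overlaps) and returns the fraction of windows whose hexamer belongs to the
#' set. Windows containing N are excluded from both numerator and
#' denominator. With `mode = "per_hexamer_mean"` the per-window value is
#' divided by the set size, giving the mean individual-hexamer frequency.
#'
#' @param seq Nucleotide string (length >= 6; alphabet ACGTN).
#' @param hset Character vector of hexamers ("the set"); use
#'   [all_hexamers()] for the full space.
#' @param mode `"per_window"` (default) or `"per_hexamer_mean"`.
#' @return A single frequency in `[0, 1]`.
#' @export
transcript_set_frequency <- function(seq, hset,
                                     mode = c("per_window",
                                              "per_hexamer_mean")) {
  mode <- match.arg(mode)
  if (nchar(seq) < 6L)
    stop("sequence shorter than 6 nt", call. = FALSE)
  assert_dna(seq, "transcript", allow_n = TRUE)
  wins <- kmer_windows(seq, 6L)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (length(wins) == 0L) return(NA_real_)
  v <- sum(wins %in% hset) / length(wins)
  if (mode == "per_hexamer_mean") v <- v / length(unique(hset))
  v
}

#' Per-transcript frequency distribution of a hexamer set
#'
#' @param seqs Named character vector or `DNAStringSet` of transcripts.
#' @inheritParams transcript_set_frequency
#' @return A `freq_distribution`: numeric vector of per-transcript values
#'   (named by transcript id) with attribute `n`.
#' @export
set_frequency_distribution <- function(seqs, hset,
                                       mode = c("per_window",
                                                "per_hexamer_mean")) {
  mode <- match.arg(mode)
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  vals <- vapply(seqs, transcript_set_frequency, numeric(1),
                 hset = hset, mode = mode)
  structure(vals, n = length(vals), class = "freq_distribution")
}

#' Two-sided Kolmogorov-Smirnov comparison of two frequency distributions
#'
#' @param a,b Numeric vectors (e.g. from [set_frequency_distribution()]),
#'   each with at least 2 values.
#' @return list with `D` (statistic), `p` (two-sided p-value), `n_a`, `n_b`.
#' @export
compare_sets_ks <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per sample", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       n_a = length(a), n_b = length(b))
}

#' Positional hexamer-set profile over anchored regions
#'
#' For a set of equal-length regions (e.g. +/-300 nt around annotated start
#' or stop codons), slides a 6-nt window with step 1 from 5' to 3' and
#' reports, at each window offset, the fraction of contributing sequences
#' whose hexamer at that offset belongs to the set. Windows containing N do
#' not contribute at that offset.
#'
#' @param regions Character vector of equal-length sequences.
#' @param hset Hexamer set.
#' @return data.frame with columns `offset` (1-based window start) and
#'   `frequency`; `length(regions[1]) - 5` rows.
#' @export
positional_profile <- function(regions, hset) {
  if (length(regions) == 0L) stop("no regions", call. = FALSE)
  lens <- nchar(regions)
  if (length(unique(lens)) != 1L)
    stop("all regions must have the same length", call. = FALSE)
  L <- lens[1]
  if (L < 6L) stop("regions shorter than 6 nt", call. = FALSE)
  nw <- L - 5L
  freq <- vapply(seq_len(nw), function(w) {
    hx <- substr(regions, w, w + 5L)
    ok <- !grepl("N", hx, fixed = TRUE)
    if (!any(ok)) return(NA_real_)
    sum(hx[ok] %in% hset) / sum(ok)
  }, numeric(1))
  data.frame(offset = seq_len(nw), frequency = freq)
}

#' Extract anchored regions around start or stop codons
#'
#' Cuts a +/-`flank` nt region centred on the first base of the anchor codon
#' from each transcript; transcripts where the region would extend past
#' either end are dropped (not padded).
#'
#' @param seqs Named character vector of transcript sequences.
#' @param anchor_pos Integer vector (1-based position of the anchor codon's
#'   first base in each transcript), parallel to `seqs`.
#' @param flank Number of nucleotides on each side (default 300).
#' @return Character vector of regions of length `2*flank + 1`.
#' @export
anchored_regions <- function(seqs, anchor_pos, flank = 300L) {
  stopifnot(length(seqs) == length(anchor_pos))
  lo <- anchor_pos - flank
  hi <- anchor_pos + flank
  keep <- lo >= 1L & hi <= nchar(seqs)
  substr(seqs[keep], lo[keep], hi[keep])
}

#' Split heptamers into hexamers and look up their enrichment scores
#'
#' Each 7-mer contributes its two overlapping 6-mers; their z scores are
#' returned grouped by the heptamer's class label (e.g. 18S rRNA "active"
#' vs "inactive" regions).
#'
#' @param heptamers data.frame with columns `heptamer` and `class`, or a
#'   character vector (single unnamed class).
#' @param scores Score table from [score_enrichment()].
#' @return data.frame with columns heptamer, class, hexamer, z.
#' @export
heptamer_split_lookup <- function(heptamers, scores) {
  if (is.character(heptamers))
    heptamers <- data.frame(heptamer = heptamers, class = "all",
                            stringsAsFactors = FALSE)
  if (any(nchar(heptamers$heptamer) != 7L))
    stop("all inputs must be heptamers (7 nt)", call. = FALSE)
  z <- setNames(scores$z, scores$hexamer)
  out <- do.call(rbind, lapply(seq_len(nrow(heptamers)), function(i) {
    h <- heptamers$heptamer[i]
    hx <- c(substr(h, 1L, 6L), substr(h, 2L, 7L))
    data.frame(heptamer = h, class = heptamers$class[i], hexamer = hx,
               z = unname(z[hx]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
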
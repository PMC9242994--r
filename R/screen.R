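## Screen enrichment: recover reporter-library inserts from sorted-fraction
## reads and score hexamer enrichment between translating ("green") and
## non-translating ("dark") cells.

# Default reporter context. The decamer library sits between the vector arms
# of the circRNA-GFP reporter; the exact post-cloning construct is not public,
# so these arms are configuration, not constants. The 2-nt extensions default
# to the bases abutting the insert in the library primer (AGTAA-N10-ATCATG).
.DEFAULT_UPSTREAM  <- "GCTAGCGAGTCGACTCATACAGTAA"   # ...AGTAA | insert
.DEFAULT_DOWNSTREAM <- "ATCATGGTGAGCAAGGGCGAGGAGCTGTTC" # insert | ATCATG...

#' Reporter vector context for the decamer screen
#'
#' Describes the fixed vector sequence around the random 10-nt library insert:
#' the flanks used for exact-match insert recovery (last 24 nt upstream,
#' first 30 nt downstream) and the 2-nt extensions appended to each insert
#' before hexamer counting, so that elements straddling the vector boundary
#' are still seen.
#'
#' @param upstream_flank Vector sequence immediately 5' of the insert
#'   (>= 24 nt).
#' @param downstream_flank Vector sequence immediately 3' of the insert
#'   (>= 30 nt).
#' @return An object of class `vector_context`.
#' @examples
#' ctx <- vector_context()
#' ctx$extension_left   # last 2 nt of the upstream flank
#' @export
vector_context <- function(upstream_flank = .DEFAULT_UPSTREAM,
                           downstream_flank = .DEFAULT_DOWNSTREAM) {
  assert_dna(upstream_flank, "upstream_flank")
  assert_dna(downstream_flank, "downstream_flank")
  if (nchar(upstream_flank) < 24L)
    stop("upstream_flank must be at least 24 nt", call. = FALSE)
  if (nchar(downstream_flank) < 30L)
    stop("downstream_flank must be at least 30 nt", call. = FALSE)
  nu <- nchar(upstream_flank)
  structure(list(
    upstream_flank = upstream_flank,
    downstream_flank = downstream_flank,
    extension_left = substr(upstream_flank, nu - 1L, nu),
    extension_right = substr(downstream_flank, 1L, 2L)
  ), class = "vector_context")
}

#' Recover library inserts from raw reads
#'
#' A 10-nt insert is recovered from a read only when the last 24 nt of the
#' upstream vector flank and the first 30 nt of the downstream flank both
#' match exactly around it, on the read's forward orientation. Inserts
#' containing N (or any non-ACGT character) are dropped. No quality trimming
#' is performed.
#'
#' @param reads Character vector of read sequences (qualities ignored).
#' @param ctx A [vector_context()].
#' @param fraction_label Label of the sorted fraction these reads came from.
#' @return An `insert_set`: list with `fraction_label`, `inserts` (multiset,
#'   one entry per matched read), `n_reads_total`, `n_reads_matched`.
#' @export
extract_inserts <- function(reads, ctx = vector_context(),
                            fraction_label = "unknown") {
  stopifnot(inherits(ctx, "vector_context"))
  up24 <- substr(ctx$upstream_flank,
                 nchar(ctx$upstream_flank) - 23L, nchar(ctx$upstream_flank))
  dn30 <- substr(ctx$downstream_flank, 1L, 30L)
  n_total <- length(reads)
  inserts <- character(0)
  if (n_total > 0L) {
    pos <- regexpr(up24, reads, fixed = TRUE)
    hit <- pos > 0L
    if (any(hit)) {
      s <- pos[hit] + 24L
      cand <- substr(reads[hit], s, s + 9L)
      down <- substr(reads[hit], s + 10L, s + 39L)
      ok <- nchar(cand) == 10L & down == dn30 & grepl("^[ACGT]{10}$", cand)
      inserts <- cand[ok]
    }
  }
  structure(list(fraction_label = fraction_label,
                 inserts = inserts,
                 n_reads_total = n_total,
                 n_reads_matched = length(inserts)),
            class = "insert_set")
}

#' Read one or more FASTQ files into a single insert set
#'
#' @param paths FASTQ file paths (gzip allowed); reads are pooled.
#' @inheritParams extract_inserts
#' @return An `insert_set`.
#' @export
extract_inserts_fastq <- function(paths, ctx = vector_context(),
                                  fraction_label = "unknown") {
  reads <- unlist(lapply(paths, function(p) {
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  }), use.names = FALSE)
  if (is.null(reads)) reads <- character(0)
  extract_inserts(reads, ctx, fraction_label)
}

#' Count hexamers over vector-extended inserts
#'
#' Each 10-nt insert is extended to a 14-mer with the 2-nt vector sequence on
#' each side, and the 14-mer is decomposed into its 9 overlapping hexamers.
#' Counts are accumulated over all inserts (per read, so PCR duplicates count
#' multiply). Inserts that are not exactly 10 nt are rejected and tallied in
#' the `rejected` attribute.
#'
#' @param insert_set An `insert_set` from [extract_inserts()], or a plain
#'   character vector of 10-nt inserts.
#' @param ctx A [vector_context()] supplying the 2-nt extensions.
#' @return A `hexamer_counts` object: named integer vector over the full
#'   4096-hexamer space with attributes `total` and `rejected`.
#' @export
count_hexamers <- function(insert_set, ctx = vector_context()) {
  inserts <- if (inherits(insert_set, "insert_set")) insert_set$inserts
             else as.character(insert_set)
  ok <- nchar(inserts) == 10L
  rejected <- sum(!ok)
  inserts <- inserts[ok]
  space <- all_hexamers()
  if (length(inserts) == 0L) {
    counts <- setNames(integer(length(space)), space)
  } else {
    m14 <- paste0(ctx$extension_left, inserts, ctx$extension_right)
    wins <- unlist(lapply(1:9, function(w) substr(m14, w, w + 5L)),
                   use.names = FALSE)
    counts <- table(factor(wins, levels = space))
    counts <- setNames(as.integer(counts), space)
  }
  structure(counts, total = sum(counts), rejected = rejected,
            class = "hexamer_counts")
}

#' Hexamer enrichment between two sorted fractions
#'
#' For every hexamer, compares its frequency among all counted windows in the
#' "green" (translating) fraction against the "dark" (non-translating)
#' fraction with a pooled two-proportion z statistic:
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' where \eqn{\hat p} pools the counts of both fractions. Hexamers with
#' `z > z_hi` are classified `enriched` (IRES-like elements), `z < z_lo`
#' `depleted`, and the rest `neutral`. A hexamer absent from both fractions
#' scores 0 by convention (no pseudocounts are added).
#'
#' @param green,dark `hexamer_counts` tables with positive totals.
#' @param z_hi,z_lo Classification thresholds (defaults +7 / -7).
#' @return data.frame with columns hexamer, count_green, count_dark,
#'   freq_green, freq_dark, z, class — one row per hexamer (4096 rows).
#' @export
score_enrichment <- function(green, dark, z_hi = 7, z_lo = -7) {
  n1 <- attr(green, "total"); n2 <- attr(dark, "total")
  if (is.null(n1)) n1 <- sum(green)
  if (is.null(n2)) n2 <- sum(dark)
  if (n1 <= 0 || n2 <= 0)
    stop("both count tables must have positive totals", call. = FALSE)
  space <- all_hexamers()
  x1 <- as.numeric(green[space]); x2 <- as.numeric(dark[space])
  if (anyNA(x1) || anyNA(x2))
    stop("count tables must cover the full hexamer space", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(x1 + x2 == 0, 0, (p1 - p2) / se)
  cls <- ifelse(z > z_hi, "enriched", ifelse(z < z_lo, "depleted", "neutral"))
  data.frame(hexamer = space, count_green = x1, count_dark = x2,
             freq_green = p1, freq_dark = p2, z = z, class = cls,
             stringsAsFactors = FALSE)
}

#' Base and dinucleotide composition of an insert set
#'
#' Base frequencies over all insert positions, dinucleotide probabilities
#' over the 9 overlapping dinucleotide windows of each 10-nt insert, and
#' dinucleotide odds ratios odds(XY) = P(XY) / (P(X) P(Y)). A dinucleotide
#' whose denominator contains a zero-frequency base is reported NA.
#'
#' @param insert_set An `insert_set` or character vector of inserts.
#' @return list with `base_freq` (length 4), `dinuc_freq` (4 x 4 matrix,
#'   rows = first base), `odds` (4 x 4 matrix).
#' @export
composition_stats <- function(insert_set) {
  inserts <- if (inherits(insert_set, "insert_set")) insert_set$inserts
             else as.character(insert_set)
  if (length(inserts) == 0L) stop("empty insert set", call. = FALSE)
  chars <- strsplit(paste(inserts, collapse = ""), "")[[1]]
  base_freq <- table(factor(chars, levels = DNA_BASES))
  base_freq <- as.numeric(base_freq) / length(chars)
  names(base_freq) <- DNA_BASES
  din <- unlist(lapply(1:9, function(w) substr(inserts, w, w + 1L)),
                use.names = FALSE)
  lev <- paste0(rep(DNA_BASES, each = 4L), DNA_BASES)  # row-major AA,AC,...
  dfreq <- table(factor(din, levels = lev))
  dfreq <- as.numeric(dfreq) / length(din)
  dmat <- matrix(dfreq, 4, 4, byrow = TRUE,
                 dimnames = list(DNA_BASES, DNA_BASES))
  expected <- outer(base_freq, base_freq)
  odds <- ifelse(expected == 0, NA_real_, dmat / expected)
  list(base_freq = base_freq, dinuc_freq = dmat, odds = odds)
}

# minimal mismatch distance between two hexamers over ungapped offsets -2..+2;
# positions outside the overlap count as mismatches
hexamer_distance <- function(a, b, offsets = -2:2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- 6L
  for (o in offsets) {
    ia <- seq(max(1L, 1L + o), min(6L, 6L + o))
    ib <- ia - o
    mm <- sum(ca[ia] != cb[ib]) + (6L - length(ia))
    if (mm < best) best <- mm
  }
  best
}

# best alignment offset of member hexamer against a seed (ties: |o| then o)
best_offset <- function(member, seed, offsets = -2:2) {
  cm <- strsplit(member, "")[[1]]; cs <- strsplit(seed, "")[[1]]
  score <- vapply(offsets, function(o) {
    is <- seq(max(1L, 1L + o), min(6L, 6L + o))
    sum(cs[is] != cm[is - o]) + (6L - length(is))
  }, numeric(1))
  ord <- order(score, abs(offsets), offsets)
  offsets[ord[1]]
}

#' Cluster hexamers into consensus motifs
#'
#' Deterministic average-linkage hierarchical clustering on a best-offset
#' ungapped mismatch distance (offsets -2..+2, unaligned positions count as
#' mismatches). For each cluster, members are aligned to the
#' lexicographically smallest member at their best offset and summarised as a
#' position frequency matrix; columns each sum to 1 over the members covering
#' that position.
#'
#' @param hexamers Character vector of hexamers (>= 1).
#' @param n_clusters Number of clusters, between 1 and `length(hexamers)`.
#' @return List of `motif_cluster` objects: `members`, `offsets`,
#'   `consensus_matrix` (4 x width, rows A,C,G,T), `label` (consensus string).
#' @export
cluster_hexamers <- function(hexamers, n_clusters) {
  hexamers <- sort(unique(as.character(hexamers)))
  n <- length(hexamers)
  if (n < 1L) stop("need at least one hexamer", call. = FALSE)
  if (n_clusters < 1L || n_clusters > n)
    stop("n_clusters must be between 1 and the number of hexamers",
         call. = FALSE)
  if (n == 1L) {
    memb <- setNames(1L, hexamers)
  } else {
    d <- matrix(0, n, n, dimnames = list(hexamers, hexamers))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- hexamer_distance(hexamers[i], hexamers[j])
    }
    hc <- hclust(as.dist(d), method = "average")
    memb <- cutree(hc, k = n_clusters)
  }
  lapply(split(names(memb), memb), function(members) {
    members <- sort(members)
    seed <- members[1]
    offs <- vapply(members, best_offset, integer(1), seed = seed)
    span <- range(c(offs + 1L, offs + 6L, 1L, 6L))
    width <- span[2] - span[1] + 1L
    mat <- matrix(0, 4, width, dimnames = list(DNA_BASES, NULL))
    for (k in seq_along(members)) {
      pos <- (offs[k] + 1L):(offs[k] + 6L) - span[1] + 1L
      ch <- strsplit(members[k], "")[[1]]
      for (p in seq_len(6L)) mat[ch[p], pos[p]] <- mat[ch[p], pos[p]] + 1
    }
    mat <- sweep(mat, 2, colSums(mat), "/")
    label <- paste(DNA_BASES[apply(mat, 2, which.max)], collapse = "")
    structure(list(members = members, offsets = unname(offs),
                   consensus_matrix = mat, label = label),
              class = "motif_cluster")
  })
}

#' Write a hexamer score table as TSV
#' @param scores data.frame from [score_enrichment()].
#' @param path Output file.
#' @export
write_score_table <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif clusters as JASPAR-style position frequency matrices
#' @param clusters List from [cluster_hexamers()].
#' @param path Output file.
#' @export
write_cluster_pfms <- function(clusters, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    writeLines(sprintf(">cluster%d %s members=%s", i, cl$label,
                       paste(cl$members, collapse = ",")), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(formatC(cl$consensus_matrix[b, ],
                                       format = "f", digits = 4),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
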
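## ORF prediction on circular sequences, including rolling-circle ORFs, and
## the host-overlap / homology survey with reversed and shuffled controls.

#' Find ORFs on a circular sequence
#'
#' The circle is repeated four times into a concatemer and scanned for NTG
#' start codons (ATG/CTG/GTG/TTG; non-ATG initiation is common in
#' cap-independent translation) at offsets within the first copy. From each
#' start, translation proceeds codon by codon. If a stop codon (TAA/TAG/TGA)
#' is reached, a cORF is reported when the peptide is at least `min_aa`
#' residues. If no stop occurs within 3 full circle lengths past the start,
#' the reading frame can never terminate (the frame path is periodic with
#' period at most 3L) and a rolling-circle ORF (rcORF) is reported with
#' infinite length.
#'
#' Position 0 immediately follows the back-splice junction; the junction lies
#' between positions L-1 and 0.
#'
#' @param seq Circular sequence (character, A/C/G/T only).
#' @param id Identifier copied into the output.
#' @param min_aa Minimum peptide length for a cORF (default 20).
#' @param starts Allowed start codons.
#' @return data.frame with one row per qualifying ORF: `circ_id`,
#'   `start_offset` (0-based), `start_codon`, `type` ("cORF"/"rcORF"),
#'   `length_aa` (Inf for rcORF), `stop_offset` (0-based position of the
#'   first stop base on the circle; NA for rcORF), `crosses_junction`,
#'   `peptide` (for rcORF, one full period of the repeating product).
#' @export
find_circorfs <- function(seq, id = "circ", min_aa = 20L,
                          starts = NTG_STARTS) {
  assert_dna(seq, "circRNA sequence")
  L <- nchar(seq)
  empty <- data.frame(circ_id = character(0), start_offset = integer(0),
                      start_codon = character(0), type = character(0),
                      length_aa = numeric(0), stop_offset = integer(0),
                      crosses_junction = logical(0), peptide = character(0),
                      stringsAsFactors = FALSE)
  if (L < 3L) return(empty)
  concat <- strrep(seq, 4L)
  # all codon strings starting at each concatemer offset we may visit
  codon_at <- function(p0) substr(concat, p0 + 1L, p0 + 3L)  # 0-based p0
  rows <- list()
  for (s in 0:(L - 1L)) {
    sc <- codon_at(s)
    if (!(sc %in% starts)) next
    n_codons <- L  # 3L nt past the start = L codons
    stop_at <- NA_integer_
    for (k in seq_len(n_codons) - 1L) {
      cd <- codon_at(s + 3L * k)
      if (cd %in% STOP_CODONS) { stop_at <- k; break }
    }
    if (is.na(stop_at)) {
      # rolling circle: one period of the repeating peptide
      period <- if (L %% 3L == 0L) L %/% 3L else L
      pep <- paste(translate_codons(
        vapply(seq_len(period) - 1L, function(k) codon_at(s + 3L * k),
               character(1))), collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = id, start_offset = s, start_codon = sc, type = "rcORF",
        length_aa = Inf, stop_offset = NA_integer_, crosses_junction = TRUE,
        peptide = pep, stringsAsFactors = FALSE)
    } else if (stop_at >= min_aa) {
      pep <- paste(translate_codons(
        vapply(seq_len(stop_at) - 1L, function(k) codon_at(s + 3L * k),
               character(1))), collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = id, start_offset = s, start_codon = sc, type = "cORF",
        length_aa = stop_at, stop_offset = (s + 3L * stop_at) %% L,
        crosses_junction = (s + 3L * stop_at + 3L) > L, peptide = pep,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Call ORFs over a set of circular sequences
#'
#' @param circs data.frame with columns `id` and `seq` (and optionally
#'   `host_id`), or a named character vector of sequences.
#' @inheritParams find_circorfs
#' @return Combined ORF data.frame (see [find_circorfs()]).
#' @export
find_circorfs_set <- function(circs, min_aa = 20L, starts = NTG_STARTS) {
  circs <- as_circ_df(circs)
  do.call(rbind, c(lapply(seq_len(nrow(circs)), function(i) {
    find_circorfs(circs$seq[i], circs$id[i], min_aa, starts)
  }), list(make.row.names = FALSE)))
}

as_circ_df <- function(circs) {
  if (is.character(circs)) {
    ids <- names(circs)
    if (is.null(ids)) ids <- sprintf("circ%d", seq_along(circs))
    circs <- data.frame(id = ids, seq = unname(circs),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(circs), all(c("id", "seq") %in% names(circs)))
  circs
}

# does `pep` share a run of >= k identical consecutive residues with `prot`?
shares_run <- function(pep, prot, k) {
  n <- nchar(pep)
  if (n < k || nchar(prot) < k) return(FALSE)
  subs <- unique(substring(pep, seq_len(n - k + 1L),
                           seq_len(n - k + 1L) + k - 1L))
  any(vapply(subs, function(s) grepl(s, prot, fixed = TRUE), logical(1)))
}

# best ungapped alignment: is there an offset placing the shorter of a,b
# inside the longer with <= max_mm mismatching residues?
hamming_homolog <- function(a, b, max_mm = 2L) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nchar(a); nb <- nchar(b)
  ca <- strsplit(a, "")[[1]]
  for (off in 0:(nb - na)) {
    cb <- strsplit(substr(b, off + 1L, off + na), "")[[1]]
    if (sum(ca != cb) <= max_mm) return(TRUE)
  }
  FALSE
}

#' Survey circRNA coding potential against host genes and known proteins
#'
#' Classifies every circRNA into one of six mutually exclusive categories:
#' `overlapped_cORF` / `overlapped_rcORF` (the representative ORF shares at
#' least `min_overlap_aa` consecutive residues with the host-gene protein),
#' `homologous_cORF` / `homologous_rcORF` (not host-overlapping, but matching
#' some known protein in an ungapped alignment with at most `max_mismatch`
#' substitutions over the shorter sequence), `non_homologous` (has an ORF but
#' neither), or `no_orf` (no ORF of at least `min_aa` residues).
#'
#' The representative ORF per circRNA ranks rcORFs above cORFs and longer
#' above shorter (ties broken by smallest start offset).
#'
#' @param circs circRNA set (see [find_circorfs_set()]); the `host_id` column
#'   links each circle to `host_proteins`.
#' @param host_proteins Named character vector of host protein sequences.
#' @param known_proteins Character vector of known protein sequences.
#' @param min_aa Minimum cORF peptide length (default 20).
#' @param min_overlap_aa Minimum shared run for host overlap (default 7).
#' @param max_mismatch Substitutions tolerated by the homology test
#'   (default 2).
#' @param homology_fun Optional pluggable homology oracle
#'   `function(peptide, known_proteins) -> logical`; replaces the internal
#'   ungapped matcher (e.g. to adapt external alignment output).
#' @return list with `per_circ` (data.frame: circ_id, category, orf_type,
#'   start_offset) and `fractions` (named vector over the six categories,
#'   summing to 1).
#' @export
survey_orfs <- function(circs, host_proteins = character(0),
                        known_proteins = character(0), min_aa = 20L,
                        min_overlap_aa = 7L, max_mismatch = 2L,
                        homology_fun = NULL) {
  circs <- as_circ_df(circs)
  if (is.null(homology_fun)) {
    homology_fun <- function(pep, known) {
      any(vapply(known, hamming_homolog, logical(1), a = pep,
                 max_mm = max_mismatch))
    }
  }
  cats <- c("overlapped_cORF", "overlapped_rcORF", "homologous_cORF",
            "homologous_rcORF", "non_homologous", "no_orf")
  res <- lapply(seq_len(nrow(circs)), function(i) {
    orfs <- find_circorfs(circs$seq[i], circs$id[i], min_aa = min_aa)
    if (nrow(orfs) == 0L)
      return(data.frame(circ_id = circs$id[i], category = "no_orf",
                        orf_type = NA_character_, start_offset = NA_integer_,
                        stringsAsFactors = FALSE))
    ord <- order(orfs$type != "rcORF", -orfs$length_aa, orfs$start_offset)
    rep_orf <- orfs[ord[1L], ]
    pep <- rep_orf$peptide
    sub <- if (rep_orf$type == "rcORF") "rcORF" else "cORF"
    host <- NULL
    if ("host_id" %in% names(circs) && !is.na(circs$host_id[i]) &&
        circs$host_id[i] %in% names(host_proteins))
      host <- host_proteins[[circs$host_id[i]]]
    category <-
      if (!is.null(host) && shares_run(pep, host, min_overlap_aa))
        paste0("overlapped_", sub)
      else if (length(known_proteins) > 0L && homology_fun(pep, known_proteins))
        paste0("homologous_", sub)
      else "non_homologous"
    data.frame(circ_id = circs$id[i], category = category, orf_type = sub,
               start_offset = rep_orf$start_offset, stringsAsFactors = FALSE)
  })
  per_circ <- do.call(rbind, res)
  fr <- table(factor(per_circ$category, levels = cats))
  fractions <- as.numeric(fr) / nrow(per_circ)
  names(fractions) <- cats
  list(per_circ = per_circ, fractions = fractions)
}

#' Reversed and shuffled control circRNA sets
#'
#' Reversal is plain character reversal (no complementation); shuffling is a
#' per-sequence random permutation under the given seed. Both preserve length
#' and base composition.
#'
#' @param circs circRNA set.
#' @param seed Integer seed for the shuffle.
#' @return list with `reversed` and `shuffled` circ data.frames (ids gain
#'   `_rev` / `_shuf` suffixes; other columns carried over).
#' @export
make_controls <- function(circs, seed = 1L) {
  circs <- as_circ_df(circs)
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  reversed <- circs
  reversed$id <- paste0(circs$id, "_rev")
  reversed$seq <- vapply(circs$seq, rev1, character(1), USE.NAMES = FALSE)
  shuffled <- circs
  shuffled$id <- paste0(circs$id, "_shuf")
  shuffled$seq <- with_seed(seed, vapply(circs$seq, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
  list(reversed = reversed, shuffled = shuffled)
}

#' First-exon position and mRNA-region statistics for circRNAs
#'
#' For each circRNA with a host mapping, reports the ordinal of its first
#' exon within the host transcript and the mRNA region its span overlaps:
#' `"CDS"` (entirely within the coding region), `"5UTR-CDS"`, `"CDS-3UTR"`,
#' or `"other"`.
#'
#' @param circ_map data.frame with columns `circ_id`, `host_id`, `start`,
#'   `end` (transcript coordinates of the circularised span, 1-based closed).
#' @param annotation list with `exons` (data.frame: transcript_id, exon,
#'   start, end in transcript coordinates) and `cds` (data.frame:
#'   transcript_id, cds_start, cds_end).
#' @return list with `per_circ` (circ_id, host_id, first_exon, region),
#'   `exon_histogram` (table of first-exon ordinals), `region_fractions`,
#'   and `n_unmapped`.
#' @export
first_exon_stats <- function(circ_map, annotation) {
  stopifnot(all(c("circ_id", "host_id", "start", "end") %in% names(circ_map)))
  exons <- annotation$exons; cds <- annotation$cds
  rows <- lapply(seq_len(nrow(circ_map)), function(i) {
    tid <- circ_map$host_id[i]
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    cd <- cds[cds$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cd) == 0L)
      return(data.frame(circ_id = circ_map$circ_id[i], host_id = tid,
                        first_exon = NA_integer_, region = NA_character_,
                        stringsAsFactors = FALSE))
    s <- circ_map$start[i]; e <- circ_map$end[i]
    hit <- ex$exon[ex$end >= s & ex$start <= e]
    first_exon <- if (length(hit)) min(hit) else NA_integer_
    region <- {
      cs <- cd$cds_start[1]; ce <- cd$cds_end[1]
      in_cds <- s <= ce && e >= cs
      in_5utr <- s < cs
      in_3utr <- e > ce
      if (in_cds && !in_5utr && !in_3utr) "CDS"
      else if (in_cds && in_5utr && !in_3utr) "5UTR-CDS"
      else if (in_cds && in_3utr && !in_5utr) "CDS-3UTR"
      else "other"
    }
    data.frame(circ_id = circ_map$circ_id[i], host_id = tid,
               first_exon = first_exon, region = region,
               stringsAsFactors = FALSE)
  })
  per_circ <- do.call(rbind, rows)
  mapped <- per_circ[!is.na(per_circ$first_exon), , drop = FALSE]
  regs <- c("5UTR-CDS", "CDS", "CDS-3UTR", "other")
  rf <- table(factor(mapped$region, levels = regs))
  list(per_circ = per_circ,
       exon_histogram = table(mapped$first_exon),
       region_fractions = setNames(as.numeric(rf) / max(1L, nrow(mapped)),
                                   regs),
       n_unmapped = sum(is.na(per_circ$first_exon)))
}

#' Read a circRNA FASTA into a circ data.frame
#'
#' FASTA headers of the form `id` or `id host=HOSTID` are parsed; the host
#' tag populates the `host_id` column.
#'
#' @param path FASTA file.
#' @return data.frame with columns id, seq, host_id.
#' @export
read_circ_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  host <- ifelse(grepl("host=", hdr),
                 sub("^.*host=(\\S+).*$", "\\1", hdr), NA_character_)
  data.frame(id = id, seq = as.character(x), host_id = host,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an ORF table as TSV
#' @param orfs data.frame from [find_circorfs_set()].
#' @param path Output file.
#' @export
write_orf_table <- function(orfs, path) {
  out <- orfs[, c("circ_id", "start_offset", "start_codon", "type",
                  "length_aa", "crosses_junction")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
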
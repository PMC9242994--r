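## Back-splice-junction proteogenomics: three-frame translation through the
## junction, in-silico tryptic digestion, the junction-peptide search
## database, and the sequential PSM filter cascade.

MOD_WHITELIST <- c("Carbamidomethyl", "Oxidation", "Acetyl",
                   "Pyro-Glu", "Phospho")

#' Translate a circRNA through its back-splice junction in all three frames
#'
#' The junction lies between the last and first base of the mature circle.
#' For each frame f (0, 1, 2: the number of junction-spanning codon bases on
#' the upstream side), translation extends left and right from the junction
#' codon until a stop codon or one full circle per side, whichever comes
#' first (the one-circle cap keeps rolling-circle frames finite).
#'
#' @param seq Circular sequence (A/C/G/T).
#' @param id circRNA identifier.
#' @return data.frame with exactly 3 rows: `circ_id`, `frame`, `protein`,
#'   `junction_pos` (1-based index of the first residue whose codon spans or
#'   follows the junction), `n_left` (residues encoded entirely upstream of
#'   the junction), `spanning` (TRUE when a codon straddles the junction,
#'   i.e. frame != 0).
#' @export
junction_translations <- function(seq, id = "circ") {
  assert_dna(seq, "circRNA sequence")
  L <- nchar(seq)
  if (L < 6L) stop("circle shorter than 6 nt", call. = FALSE)
  triple <- strrep(seq, 3L)          # junction of interest at 0-based pos L
  codon_at <- function(p0) substr(triple, p0 + 1L, p0 + 3L)
  rows <- lapply(0:2, function(f) {
    a <- L - f                        # anchor codon start (0-based)
    # right extension: anchor plus following codons, capped one circle past
    # the junction (codon start < 2L), stop codon terminates
    right <- character(0)
    p <- a
    while (p < 2L * L) {
      cd <- codon_at(p)
      if (cd %in% STOP_CODONS) break
      right <- c(right, cd)
      p <- p + 3L
    }
    # left extension: codons before the anchor, capped one circle upstream
    # of the junction (codon start >= 0 in the triple, i.e. >= L-f-L)
    left <- character(0)
    p <- a - 3L
    while (p >= max(0L, a - L)) {
      cd <- codon_at(p)
      if (cd %in% STOP_CODONS) break
      left <- c(cd, left)
      p <- p - 3L
    }
    prot <- paste(translate_codons(c(left, right)), collapse = "")
    data.frame(circ_id = id, frame = f, protein = prot,
               junction_pos = length(left) + 1L, n_left = length(left),
               spanning = f != 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R), suppressed when the
#' next residue is proline (the standard KP/RP rule; set
#' `suppress_proline = FALSE` to cleave regardless). All peptides with at
#' most `max_missed` internal cleavage sites and at least `min_len` residues
#' are emitted, with their coordinates in the parent protein.
#'
#' @param protein Amino-acid string.
#' @param max_missed Maximum internal missed cleavage sites (default 3).
#' @param min_len Minimum peptide length (default 8; use 1 for a full
#'   digest listing).
#' @param suppress_proline Suppress cleavage before proline (default TRUE).
#' @return data.frame: `peptide`, `start`, `end` (1-based, inclusive),
#'   `missed` (internal missed cleavage count).
#' @export
digest_trypsin <- function(protein, max_missed = 3L, min_len = 8L,
                           suppress_proline = TRUE) {
  if (nchar(protein) == 0L)
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  # cut after position i
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (suppress_proline)
    cut_after <- cut_after[aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)                # fragment boundaries
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      if (e - s + 1L < min_len) next
      rows[[length(rows) + 1L]] <-
        data.frame(peptide = substr(protein, s, e), start = s, end = e,
                   missed = j - i, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  do.call(rbind, rows)
}

# flank bookkeeping for a peptide [ps, pe] within a junction protein with
# n_left wholly-upstream residues and a spanning residue iff `spanning`
peptide_junction_geometry <- function(ps, pe, n_left, spanning) {
  left_flank <- max(0L, min(pe, n_left) - ps + 1L)
  first_right <- n_left + 1L + as.integer(spanning)
  right_flank <- max(0L, pe - first_right + 1L)
  has_span <- spanning && ps <= n_left + 1L && pe >= n_left + 1L
  list(left_flank = left_flank, right_flank = right_flank,
       spanning = has_span,
       # peptide-local index of the first residue whose codon spans or
       # follows the junction (protein index n_left + 1)
       junction_offset = n_left + 2L - ps,
       covers = ps <= n_left + 1L && pe >= first_right)
}

#' Build the back-splice-junction peptide database
#'
#' Translates every circRNA through its junction in three frames, digests
#' with trypsin, and keeps tryptic peptides that span the junction with at
#' least `min_flank` newly-encoded residues on each side, length at least
#' `min_len`, and at most `max_missed` missed cleavages. Records are
#' deduplicated by peptide sequence; provenance lists every contributing
#' circRNA/frame.
#'
#' @param circs circRNA set (data.frame id/seq or named character vector).
#' @param min_len Minimum peptide length (default 8).
#' @param min_flank Minimum residues on each side of the junction
#'   (default 2).
#' @param max_missed Maximum missed cleavages (default 3).
#' @return data.frame: `peptide`, `circ_id`, `frame`, `junction_offset`
#'   (1-based residue index, within the peptide, of the first residue whose
#'   codon spans or follows the junction), `left_flank_aa`, `right_flank_aa`,
#'   `missed_cleavages`, `spanning`, `provenance`.
#' @export
build_junction_db <- function(circs, min_len = 8L, min_flank = 2L,
                              max_missed = 3L) {
  circs <- as_circ_df(circs)
  rows <- list()
  for (i in seq_len(nrow(circs))) {
    jt <- junction_translations(circs$seq[i], circs$id[i])
    for (r in seq_len(nrow(jt))) {
      prot <- jt$protein[r]
      if (grepl("*", prot, fixed = TRUE)) next  # defensive; stops are bounded
      peps <- digest_trypsin(prot, max_missed = max_missed, min_len = min_len)
      if (nrow(peps) == 0L) next
      for (k in seq_len(nrow(peps))) {
        g <- peptide_junction_geometry(peps$start[k], peps$end[k],
                                       jt$n_left[r], jt$spanning[r])
        if (!g$covers) next
        if (g$left_flank < min_flank || g$right_flank < min_flank) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = peps$peptide[k], circ_id = circs$id[i],
          frame = jt$frame[r],
          junction_offset = g$junction_offset,
          left_flank_aa = g$left_flank, right_flank_aa = g$right_flank,
          missed_cleavages = peps$missed[k], spanning = g$spanning,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(peptide = character(0), circ_id = character(0),
                      frame = integer(0), junction_offset = integer(0),
                      left_flank_aa = integer(0), right_flank_aa = integer(0),
                      missed_cleavages = integer(0), spanning = logical(0),
                      provenance = character(0)))
  db <- do.call(rbind, rows)
  prov <- vapply(split(sprintf("%s/f%d", db$circ_id, db$frame), db$peptide),
                 function(x) paste(sort(unique(x)), collapse = ";"),
                 character(1))
  db <- db[!duplicated(db$peptide), , drop = FALSE]
  db$provenance <- unname(prov[db$peptide])
  rownames(db) <- NULL
  db[order(db$circ_id, db$frame, db$peptide), , drop = FALSE]
}

#' Write / read the junction peptide database as FASTA
#'
#' Headers follow `circ|<id>|f<frame>|j<offset>`.
#'
#' @param db data.frame from [build_junction_db()].
#' @param path FASTA file path.
#' @return `write_junction_db`: the path, invisibly. `read_junction_db`:
#'   a data.frame with peptide, circ_id, frame, junction_offset.
#' @export
write_junction_db <- function(db, path) {
  aas <- Biostrings::AAStringSet(db$peptide)
  names(aas) <- sprintf("circ|%s|f%d|j%d", db$circ_id, db$frame,
                        db$junction_offset)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' @rdname write_junction_db
#' @export
read_junction_db <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(peptide = as.character(x),
             circ_id = vapply(hdr, `[`, character(1), 2L),
             frame = as.integer(sub("^f", "",
                                    vapply(hdr, `[`, character(1), 3L))),
             junction_offset = as.integer(sub("^j", "",
                                              vapply(hdr, `[`,
                                                     character(1), 4L))),
             row.names = NULL, stringsAsFactors = FALSE)
}

# --- PSM handling -----------------------------------------------------------

#' Read / write PSM tables in the package's TSV dialect
#'
#' Required columns: `spectrum_id`, `peptide`, `q_value`, `modifications`
#' (semicolon-separated `pos:Name`, empty for none), `sample_id`,
#' `matched_ions` (semicolon-separated b/y ions such as `b3;y5`). Annotated
#' tables additionally carry `circ_id`, `frame`, `left_flank_aa`,
#' `right_flank_aa`, `missed_cleavages`, `spanning`.
#'
#' @param path TSV file.
#' @param psms data.frame of PSMs.
#' @return `read_psm_table`: data.frame. `write_psm_table`: the path.
#' @export
read_psm_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(modifications = "character",
                                 matched_ions = "character"))
  x$modifications[is.na(x$modifications)] <- ""
  x$matched_ions[is.na(x$matched_ions)] <- ""
  x
}

#' @rdname read_psm_table
#' @export
write_psm_table <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate raw PSMs with junction geometry from the peptide database
#'
#' Joins engine output (peptide sequences only) onto the junction database
#' to recover flank widths and missed-cleavage counts. PSMs whose peptide is
#' absent from the database are dropped with a message (they cannot span a
#' junction).
#'
#' @param psms Raw PSM data.frame (dialect of [read_psm_table()]).
#' @param db Junction database from [build_junction_db()].
#' @return Annotated PSM data.frame.
#' @export
annotate_psms <- function(psms, db) {
  idx <- match(psms$peptide, db$peptide)
  drop <- is.na(idx)
  if (any(drop))
    message(sum(drop), " PSM(s) not in the junction database; dropped")
  psms <- psms[!drop, , drop = FALSE]
  idx <- idx[!drop]
  for (col in c("circ_id", "frame", "left_flank_aa", "right_flank_aa",
                "missed_cleavages", "spanning"))
    psms[[col]] <- db[[col]][idx]
  psms
}

parse_mods <- function(s) {
  if (is.na(s) || s == "") return(data.frame(pos = integer(0),
                                             name = character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):(.+)$", parts))
  if (any(lengths(m) != 3L)) return(NULL)  # malformed
  data.frame(pos = as.integer(vapply(m, `[`, character(1), 2L)),
             name = vapply(m, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

parse_ions <- function(s) {
  if (is.na(s) || s == "") return(data.frame(series = character(0),
                                             ordinal = integer(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([by])([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) return(NULL)  # malformed
  data.frame(series = vapply(m, `[`, character(1), 2L),
             ordinal = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

# fragmentation sites (after residue i, 1..len-1) strictly left / right of
# the junction, given wholly-left count and whether a residue spans it
junction_sites <- function(len, left_flank, spanning) {
  sites <- seq_len(max(0L, len - 1L))
  if (spanning) {
    list(left = sites[sites <= left_flank],
         right = sites[sites >= left_flank + 1L])
  } else {
    list(left = sites[sites <= left_flank - 1L],
         right = sites[sites >= left_flank + 1L])
  }
}

il_collapse <- function(x) gsub("L", "I", x, fixed = TRUE)

# is `pep` an exact substring of any reference protein? (I/L-collapsed)
matches_reference_exact <- function(pep, ref) {
  any(vapply(ref, function(r) grepl(pep, r, fixed = TRUE), logical(1)))
}

# does `pep` align ungapped to any reference protein with <= max_mm
# substitutions? (I/L-collapsed input expected)
matches_reference_homolog <- function(pep, ref, max_mm = 2L) {
  any(vapply(ref, function(r) hamming_homolog(pep, r, max_mm), logical(1)))
}

#' Sequential PSM filter cascade for junction peptides
#'
#' Applies, in order, the filters used to call circRNA-coded peptides from
#' open-search PSMs, logging in/out counts for each step:
#'
#' 1. `threshold` — spectrum-level q-value < `max_q`; peptide length >=
#'    `min_len`; at least `min_flank` residues on each side of the junction;
#'    missed cleavages <= `max_missed`; all modifications in the whitelist
#'    (carbamidomethyl, oxidation, acetyl, pyro-Glu, phospho). Records with
#'    malformed modification or ion strings are rejected here with a reason.
#' 2. `reference_exact` — peptides that are exact substrings of any
#'    reference protein are removed (I and L treated as equivalent).
#' 3. `reference_homology` — peptides matching the reference in an ungapped
#'    alignment with at most `max_mismatch` substitutions are removed.
#' 4. `fragment_ions` — requires at least one matched b or y ion whose
#'    fragmentation site lies strictly upstream of the junction and one
#'    strictly downstream.
#'
#' @param psms Annotated PSM data.frame (see [annotate_psms()]).
#' @param reference Character vector of reference proteome sequences.
#' @param max_q q-value cutoff (default 0.01, exclusive).
#' @param min_len Minimum peptide length (default 8).
#' @param min_flank Minimum residues each side of the junction (default 2).
#' @param max_missed Maximum missed cleavages (default 3).
#' @param max_mismatch Homology filter mismatch allowance (default 2).
#' @param mod_whitelist Allowed modification names.
#' @param il_equivalent Treat I and L as indistinguishable in reference
#'   matching (default TRUE).
#' @return list with `psms` (surviving records), `report` (data.frame:
#'   filter, n_in, n_out), and `rejected` (data.frame: spectrum_id, step,
#'   reason).
#' @export
filter_psms <- function(psms, reference, max_q = 0.01, min_len = 8L,
                        min_flank = 2L, max_missed = 3L, max_mismatch = 2L,
                        mod_whitelist = MOD_WHITELIST, il_equivalent = TRUE) {
  need <- c("spectrum_id", "peptide", "q_value", "modifications",
            "sample_id", "matched_ions", "left_flank_aa", "right_flank_aa",
            "missed_cleavages", "spanning")
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("PSM table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  reference <- as.character(reference)
  refX <- if (il_equivalent) il_collapse(reference) else reference
  rejected <- list()
  note <- function(ids, step, reason) {
    if (length(ids))
      rejected[[length(rejected) + 1L]] <<-
        data.frame(spectrum_id = ids, step = step, reason = reason,
                   stringsAsFactors = FALSE)
  }
  report <- list()

  # step 1: thresholds -------------------------------------------------------
  n_in <- nrow(psms)
  len <- nchar(psms$peptide)
  keep <- rep(TRUE, n_in)
  bad <- psms$q_value >= max_q
  note(psms$spectrum_id[keep & bad], "threshold", "q_value"); keep <- keep & !bad
  bad <- len < min_len
  note(psms$spectrum_id[keep & bad], "threshold", "length"); keep <- keep & !bad
  bad <- psms$left_flank_aa < min_flank | psms$right_flank_aa < min_flank
  note(psms$spectrum_id[keep & bad], "threshold", "flank"); keep <- keep & !bad
  bad <- psms$missed_cleavages > max_missed
  note(psms$spectrum_id[keep & bad], "threshold", "missed_cleavages")
  keep <- keep & !bad
  modsv <- lapply(psms$modifications, parse_mods)
  ionsv <- lapply(psms$matched_ions, parse_ions)
  bad <- vapply(seq_len(n_in), function(i) {
    io <- ionsv[[i]]
    is.null(modsv[[i]]) || is.null(io) ||
      (nrow(io) > 0 && any(io$ordinal < 1L | io$ordinal >= len[i]))
  }, logical(1))
  note(psms$spectrum_id[keep & bad], "threshold", "malformed")
  keep <- keep & !bad
  bad <- vapply(seq_len(n_in), function(i) {
    m <- modsv[[i]]
    !is.null(m) && nrow(m) > 0 && !all(m$name %in% mod_whitelist)
  }, logical(1))
  note(psms$spectrum_id[keep & bad], "threshold", "modification")
  keep <- keep & !bad
  psms <- psms[keep, , drop = FALSE]
  ionsv <- ionsv[keep]
  report[["threshold"]] <- c(n_in, nrow(psms))

  # step 2: exact reference substring ---------------------------------------
  n_in <- nrow(psms)
  pepX <- if (il_equivalent) il_collapse(psms$peptide) else psms$peptide
  bad <- vapply(pepX, matches_reference_exact, logical(1), ref = refX)
  note(psms$spectrum_id[bad], "reference_exact", "known_protein")
  psms <- psms[!bad, , drop = FALSE]; ionsv <- ionsv[!bad]; pepX <- pepX[!bad]
  report[["reference_exact"]] <- c(n_in, nrow(psms))

  # step 3: <= max_mismatch homology ----------------------------------------
  n_in <- nrow(psms)
  bad <- vapply(pepX, matches_reference_homolog, logical(1), ref = refX,
                max_mm = max_mismatch)
  note(psms$spectrum_id[bad], "reference_homology", "homolog")
  psms <- psms[!bad, , drop = FALSE]; ionsv <- ionsv[!bad]
  report[["reference_homology"]] <- c(n_in, nrow(psms))

  # step 4: fragment ions on both sides of the junction ---------------------
  n_in <- nrow(psms)
  ok <- vapply(seq_len(nrow(psms)), function(i) {
    io <- ionsv[[i]]
    if (nrow(io) == 0L) return(FALSE)
    l <- nchar(psms$peptide[i])
    sites <- ifelse(io$series == "b", io$ordinal, l - io$ordinal)
    js <- junction_sites(l, psms$left_flank_aa[i], psms$spanning[i])
    any(sites %in% js$left) && any(sites %in% js$right)
  }, logical(1))
  if (nrow(psms) == 0L) ok <- logical(0)
  note(psms$spectrum_id[!ok], "fragment_ions", "one_sided")
  psms <- psms[ok, , drop = FALSE]
  report[["fragment_ions"]] <- c(n_in, nrow(psms))

  rep_df <- data.frame(filter = names(report),
                       n_in = vapply(report, `[`, numeric(1), 1L),
                       n_out = vapply(report, `[`, numeric(1), 2L),
                       row.names = NULL, stringsAsFactors = FALSE)
  rej <- if (length(rejected)) do.call(rbind, rejected)
         else data.frame(spectrum_id = character(0), step = character(0),
                         reason = character(0))
  list(psms = psms, report = rep_df, rejected = rej)
}

#' Control peptides across the linear splice junctions adjacent to a circRNA
#'
#' For the host transcript of a circRNA spanning exons i..j, the linear
#' splice junctions immediately upstream (exon i-1 / exon i) and downstream
#' (exon j / exon j+1) are translated through in all three frames
#' (stop-bounded, as for the back-splice junction) and digested with the
#' identical tryptic / flank / length rules.
#'
#' @param host_seq Spliced host transcript sequence.
#' @param exon_ends Cumulative exon end positions within the transcript
#'   (1-based; `exon_ends[k]` is the last base of exon k).
#' @param circ_exons Integer range `c(first, last)` of the circularised
#'   exons.
#' @param min_len,min_flank,max_missed Digestion parameters, as for
#'   [build_junction_db()].
#' @return data.frame like [build_junction_db()] output plus a `junction`
#'   column ("upstream"/"downstream"); zero rows when no adjacent exon
#'   exists (e.g. single-exon host).
#' @export
linear_control_peptides <- function(host_seq, exon_ends, circ_exons,
                                    min_len = 8L, min_flank = 2L,
                                    max_missed = 3L) {
  assert_dna(host_seq, "host transcript")
  n_exons <- length(exon_ends)
  out <- list()
  jpos <- c(upstream = if (circ_exons[1] > 1L)
                         exon_ends[circ_exons[1] - 1L] else NA_integer_,
            downstream = if (circ_exons[2] < n_exons)
                         exon_ends[circ_exons[2]] else NA_integer_)
  for (side in names(jpos)) {
    J <- jpos[[side]]                 # junction after base J
    if (is.na(J)) next
    for (f in 0:2) {
      # codon grid with f bases of the junction codon on the upstream side
      a <- J - f                      # 0-based anchor codon start
      right <- character(0); p <- a
      while (p + 3L <= nchar(host_seq)) {
        cd <- substr(host_seq, p + 1L, p + 3L)
        if (cd %in% STOP_CODONS) break
        right <- c(right, cd); p <- p + 3L
      }
      left <- character(0); p <- a - 3L
      while (p >= 0L) {
        cd <- substr(host_seq, p + 1L, p + 3L)
        if (cd %in% STOP_CODONS) break
        left <- c(cd, left); p <- p - 3L
      }
      prot <- paste(translate_codons(c(left, right)), collapse = "")
      n_left <- length(left); spanning <- f != 0L
      peps <- digest_trypsin(prot, max_missed = max_missed,
                             min_len = min_len)
      for (k in seq_len(nrow(peps))) {
        g <- peptide_junction_geometry(peps$start[k], peps$end[k],
                                       n_left, spanning)
        if (!g$covers) next
        if (g$left_flank < min_flank || g$right_flank < min_flank) next
        out[[length(out) + 1L]] <- data.frame(
          peptide = peps$peptide[k], junction = side, frame = f,
          junction_offset = g$junction_offset,
          left_flank_aa = g$left_flank, right_flank_aa = g$right_flank,
          missed_cleavages = peps$missed[k], spanning = g$spanning,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(0), junction = character(0),
                      frame = integer(0), junction_offset = integer(0),
                      left_flank_aa = integer(0), right_flank_aa = integer(0),
                      missed_cleavages = integer(0), spanning = logical(0)))
  res <- do.call(rbind, out)
  res[!duplicated(res[c("peptide", "junction")]), , drop = FALSE]
}

#' Residue statistics around back-splice junctions
#'
#' The -1 position is the residue immediately upstream of the junction
#' (the last wholly-upstream residue). Records whose junction sits at a
#' protein boundary (no upstream residue) are skipped.
#'
#' @param jprots data.frame from [junction_translations()] (possibly
#'   row-bound over many circRNAs).
#' @return list: `frac_kr_minus1` (fraction with K or R at -1),
#'   `frac_any_kr` (fraction of junction proteins containing any K/R),
#'   `n_used`, `n_skipped`.
#' @export
junction_residue_stats <- function(jprots) {
  usable <- jprots$n_left >= 1L & nchar(jprots$protein) >= jprots$n_left
  used <- jprots[usable, , drop = FALSE]
  minus1 <- substr(used$protein, used$n_left, used$n_left)
  list(frac_kr_minus1 = if (nrow(used)) mean(minus1 %in% c("K", "R"))
                        else NA_real_,
       frac_any_kr = if (nrow(jprots))
                       mean(grepl("[KR]", jprots$protein)) else NA_real_,
       n_used = nrow(used), n_skipped = sum(!usable))
}

#' Per-junction spectra and sample summaries
#'
#' @param psms Surviving PSM data.frame (must carry `circ_id` and
#'   `sample_id`).
#' @return data.frame: `circ_id`, `spectra` (supporting spectrum count),
#'   `samples` (distinct sample count); zero rows for empty input.
#' @export
spectra_summaries <- function(psms) {
  if (nrow(psms) == 0L)
    return(data.frame(circ_id = character(0), spectra = integer(0),
                      samples = integer(0)))
  sp <- split(psms$sample_id, psms$circ_id)
  data.frame(circ_id = names(sp),
             spectra = vapply(sp, length, integer(1)),
             samples = vapply(sp, function(x) length(unique(x)), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
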
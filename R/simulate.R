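## Ground-truthed synthetic data for every pipeline stage: sorted-fraction
## screen reads with planted active hexamers, circRNAs with planted
## cORFs/rcORFs and toy host annotation, and PSM tables with planted
## violators of each filter. All generators are pure functions of
## (config, seed).

# AU-rich planted defaults, in the spirit of the screen's hit class
.DEFAULT_PLANTED <- c("AATAAA", "AAGAAG", "AATTCA", "TATTAT", "ACATTT")

#' Configuration for the reporter-screen simulator
#'
#' The activity model is deliberately minimal: an insert is "active" iff its
#' vector-extended 14-mer contains a planted hexamer; active inserts sort
#' into the green (translating) population with probability `p_active`,
#' inactive ones with `p_background`. Green cells split medium:high 10:1 and
#' dark cells negative:low 7:3, loosely mirroring sorted-cell proportions in
#' such screens.
#'
#' @param n_inserts Number of distinct library inserts (default 200000).
#' @param planted_hexamers Hexamers that confer activity (default 5 AU-rich
#'   hexamers).
#' @param p_active,p_background Sorting probabilities (defaults 0.8 / 0.02).
#' @param reads_per_fraction Reads sequenced per sorted fraction (default
#'   3000: desk-scale depth, about 6-7 expected background counts per
#'   hexamer per fraction after the 9x window expansion).
#' @param vector A [vector_context()].
#' @param error_rate Per-base uniform substitution probability applied to
#'   finished reads (default 0; exercises the exact-flank filter when > 0).
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_inserts = 200000L,
                              planted_hexamers = .DEFAULT_PLANTED,
                              p_active = 0.8, p_background = 0.02,
                              reads_per_fraction = 3000L,
                              vector = vector_context(),
                              error_rate = 0, seed = 1L) {
  stopifnot(p_background >= 0, p_background < p_active, p_active <= 1)
  assert_dna(planted_hexamers, "planted hexamers")
  stopifnot(all(nchar(planted_hexamers) == 6L))
  structure(list(n_inserts = as.integer(n_inserts),
                 planted_hexamers = planted_hexamers,
                 p_active = p_active, p_background = p_background,
                 reads_per_fraction = as.integer(reads_per_fraction),
                 vector = vector, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate the sorted-fraction reporter screen
#'
#' @param cfg A [screen_sim_config()].
#' @param out_dir Optional directory; when given, one FASTQ per fraction
#'   (`negative.fastq`, `low.fastq`, `medium.fastq`, `high.fastq`) and a
#'   `truth.json` are written.
#' @return list with `reads` (named list of read vectors per fraction),
#'   `truth` (list: planted hexamers, per-insert data.frame with insert,
#'   active flag and fraction, config echo), and `files` (paths, when
#'   written).
#' @export
simulate_screen <- function(cfg = screen_sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  res <- with_seed(cfg$seed, {
    inserts <- random_dna(cfg$n_inserts, 10L)
    m14 <- paste0(cfg$vector$extension_left, inserts,
                  cfg$vector$extension_right)
    active <- rep(FALSE, cfg$n_inserts)
    for (h in cfg$planted_hexamers)
      active <- active | grepl(h, m14, fixed = TRUE)
    p <- ifelse(active, cfg$p_active, cfg$p_background)
    green <- runif(cfg$n_inserts) < p
    fraction <- character(cfg$n_inserts)
    fraction[green] <- ifelse(runif(sum(green)) < 10 / 11, "medium", "high")
    fraction[!green] <- ifelse(runif(sum(!green)) < 0.7, "negative", "low")
    reads <- lapply(c(negative = "negative", low = "low",
                      medium = "medium", high = "high"), function(fr) {
      pool <- inserts[fraction == fr]
      if (length(pool) == 0L) return(character(0))
      ins <- sample(pool, cfg$reads_per_fraction, replace = TRUE)
      rd <- paste0(cfg$vector$upstream_flank, ins,
                   cfg$vector$downstream_flank)
      if (cfg$error_rate > 0) rd <- mutate_reads(rd, cfg$error_rate)
      rd
    })
    list(reads = reads,
         truth = list(planted_hexamers = cfg$planted_hexamers,
                      inserts = data.frame(insert = inserts, active = active,
                                           fraction = fraction,
                                           stringsAsFactors = FALSE)))
  })
  res$truth$config <- cfg[setdiff(names(cfg), "vector")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(res$reads), function(fr) {
      p <- file.path(out_dir, paste0(fr, ".fastq"))
      write_fastq(res$reads[[fr]], p, prefix = fr)
      p
    }, character(1))
    tj <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(planted_hexamers = cfg$planted_hexamers,
                              n_active = sum(res$truth$inserts$active)),
                         tj, auto_unbox = TRUE)
    res$files <- c(files, truth = tj)
  }
  res
}

mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit))
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(reads, path, prefix = "read") {
  n <- length(reads)
  if (n == 0L) { file.create(path); return(invisible(path)) }
  lines <- character(4L * n)
  lines[seq(1, by = 4, length.out = n)] <- sprintf("@%s_%d", prefix,
                                                   seq_len(n))
  lines[seq(2, by = 4, length.out = n)] <- reads
  lines[seq(3, by = 4, length.out = n)] <- "+"
  lines[seq(4, by = 4, length.out = n)] <- strrep("I", nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

# codons that never terminate translation
non_stop_codons <- function() {
  cods <- names(codon_aa())
  setdiff(cods, STOP_CODONS)
}

# codons safe for planted-ORF bodies: no stops, and no NTG so the planted
# start is the only start in its frame
safe_body_alphabet <- function() setdiff(non_stop_codons(), NTG_STARTS)

# "frame-killer" block: Leu-Ile-Ser in frame 0, but reads TAA in the +1
# frame and TAG in the +2 frame, so shifted frames of a planted ORF body
# always terminate and can never host spurious ORFs
.FRAME_KILLER <- c("TTA", "ATT", "AGT")

# naa random safe codons with a frame-killer block after every 5th codon;
# the spacing caps any shifted-frame stop-free run well below the 20-codon
# ORF threshold, so planted ORFs are the only ORFs the caller can find
safe_body_codons <- function(naa) {
  base <- sample(safe_body_alphabet(), naa, replace = TRUE)
  out <- character(0)
  for (i in seq_len(naa)) {
    out <- c(out, base[i])
    if (i %% 5L == 0L) out <- c(out, .FRAME_KILLER)
  }
  out
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulate circRNAs with planted ORFs and toy host annotation
#'
#' Three kinds of circles are produced in the given proportions: circles
#' with a planted stop-terminated cORF (start codon, 20-60 sense codons,
#' stop, random tail), circles with a planted stop-free frame (rcORF;
#' length a multiple of 3), and circles with no NTG start at all (drawn from
#' the alphabet A/C/T, hence no ORF). For circles with an ORF, a host
#' protein embedding the planted peptide is emitted with probability
#' `p_overlap`; otherwise, with probability `p_homolog`, a known protein at
#' Hamming distance <= 2 from the planted peptide is added to the known set,
#' and with the remaining probability the ORF matches nothing.
#'
#' @param n Number of circRNAs (default 30).
#' @param props Proportions of cORF / rcORF / no-ORF circles.
#' @param p_overlap,p_homolog Host-overlap and known-homolog probabilities
#'   for ORF-bearing circles (defaults 0.6 / 0.5 of the remainder).
#' @param seed Integer seed.
#' @param out_dir Optional output directory (`circs.fa`, `hosts.bed`,
#'   `truth.json`).
#' @return list: `circs` (data.frame id/seq/host_id), `host_proteins`
#'   (named vector), `known_proteins` (vector), `circ_map` + `annotation`
#'   (toy exon structure for first-exon statistics), `truth` (data.frame:
#'   circ_id, kind, start_offset, length_aa, category).
#' @export
simulate_circrnas <- function(n = 30L,
                              props = c(cORF = 0.5, rcORF = 0.3, none = 0.2),
                              p_overlap = 0.6, p_homolog = 0.5,
                              seed = 1L, out_dir = NULL) {
  stopifnot(abs(sum(props) - 1) < 1e-9)
  empty_circs <- data.frame(id = character(0), seq = character(0),
                            host_id = character(0), stringsAsFactors = FALSE)
  empty_truth <- data.frame(circ_id = character(0), kind = character(0),
                            start_offset = integer(0),
                            length_aa = numeric(0), category = character(0),
                            stringsAsFactors = FALSE)
  res <- with_seed(seed, {
    kinds <- sample(names(props), n, replace = TRUE, prob = props)
    circs <- vector("list", n)
    truth <- vector("list", n)
    host_proteins <- character(0)
    known_proteins <- character(0)
    for (i in seq_len(n)) {
      id <- sprintf("circ%03d", i)
      kind <- kinds[i]
      if (kind == "none") {
        seq <- random_dna(1L, sample(60:200, 1L), alphabet = c("A", "C", "T"))
        circs[[i]] <- data.frame(id = id, seq = seq,
                                 host_id = NA_character_,
                                 stringsAsFactors = FALSE)
        truth[[i]] <- data.frame(circ_id = id, kind = kind,
                                 start_offset = NA_integer_,
                                 length_aa = NA_real_, category = "no_orf",
                                 stringsAsFactors = FALSE)
        next
      }
      naa <- sample(20:50, 1L)
      start <- sample(NTG_STARTS, 1L, prob = c(0.7, 0.1, 0.1, 0.1))
      body <- safe_body_codons(naa)
      if (kind == "cORF") {
        tail_n <- sample(0:5, 1L)        # codons after the stop; safe
        # alphabet plus a closing frame-killer, so the planted start stays
        # the only frame-0 start and shifted frames stay stop-dense
        tl <- c(if (tail_n > 0) sample(safe_body_alphabet(), tail_n,
                                       replace = TRUE), .FRAME_KILLER)
        codons <- c(start, body, sample1(STOP_CODONS), tl)
        length_aa <- length(body) + 1L
      } else {
        codons <- c(start, body)         # L %% 3 == 0, stop-free frame 0
        length_aa <- Inf
      }
      lin <- paste(codons, collapse = "")
      rot <- sample(0:(nchar(lin) - 1L), 1L)
      seq <- rotate_string(lin, rot)
      start_offset <- (0L - rot) %% nchar(lin)
      pep <- paste(translate_codons(c(start, body)), collapse = "")
      u <- runif(1L)
      if (u < p_overlap) {
        host_id <- sprintf("host%03d", i)
        host_proteins[host_id] <-
          paste0(random_aa(sample(5:20, 1L)), pep, random_aa(sample(5:20, 1L)))
        category <- paste0("overlapped_", kind)
      } else if (u < p_overlap + (1 - p_overlap) * p_homolog) {
        host_id <- NA_character_
        mut <- mutate_protein(pep, sample(1:2, 1L))
        known_proteins <- c(known_proteins, mut)
        category <- paste0("homologous_", kind)
      } else {
        host_id <- NA_character_
        category <- "non_homologous"
      }
      circs[[i]] <- data.frame(id = id, seq = seq, host_id = host_id,
                               stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(circ_id = id, kind = kind,
                               start_offset = start_offset,
                               length_aa = length_aa, category = category,
                               stringsAsFactors = FALSE)
    }
    circs <- do.call(rbind, c(circs, list(empty_circs)))
    truth <- do.call(rbind, c(truth, list(empty_truth)))
    # toy host exon structure: 5 exons; the circle occupies exons 2-3
    exon_len <- 120L
    hosts <- unique(circs$host_id[!is.na(circs$host_id)])
    exons <- do.call(rbind, c(lapply(hosts, function(h) {
      data.frame(transcript_id = h, exon = 1:5,
                 start = exon_len * (0:4) + 1L, end = exon_len * (1:5),
                 stringsAsFactors = FALSE)
    }), list(data.frame(transcript_id = character(0), exon = integer(0),
                        start = integer(0), end = integer(0)))))
    cds <- data.frame(transcript_id = as.character(hosts),
                      cds_start = rep(60L, length(hosts)),
                      cds_end = rep(540L, length(hosts)),
                      stringsAsFactors = FALSE)
    has_host <- !is.na(circs$host_id)
    circ_map <- data.frame(circ_id = circs$id[has_host],
                           host_id = circs$host_id[has_host],
                           start = rep(exon_len + 1L, sum(has_host)),
                           end = rep(3L * exon_len, sum(has_host)),
                           stringsAsFactors = FALSE)
    list(circs = circs, truth = truth, host_proteins = host_proteins,
         known_proteins = known_proteins, circ_map = circ_map,
         annotation = list(exons = exons, cds = cds))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "circs.fa")
    x <- Biostrings::DNAStringSet(res$circs$seq)
    names(x) <- ifelse(is.na(res$circs$host_id), res$circs$id,
                       paste0(res$circs$id, " host=", res$circs$host_id))
    Biostrings::writeXStringSet(x, fa)
    bed <- file.path(out_dir, "hosts.bed")
    ex <- res$annotation$exons
    write.table(data.frame(ex$transcript_id, ex$start - 1L, ex$end,
                           paste0("exon", ex$exon)),
                bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    tj <- file.path(out_dir, "truth.json")
    jsonlite::write_json(res$truth, tj, auto_unbox = TRUE, digits = NA)
    res$files <- c(circs = fa, hosts = bed, truth = tj)
  }
  res
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(p, k) {
  ch <- strsplit(p, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (q in pos) ch[q] <- sample(setdiff(.AA20, c(ch[q], "I", "L")), 1L)
  paste(ch, collapse = "")
}

#' Simulate a PSM table against a junction peptide database
#'
#' Emits true junction PSMs (q < 0.01, allowed modifications, fragment ions
#' on both sides of the junction) plus one planted violator per filter rule:
#' excessive q-value, short peptide, thin junction flank, excess missed
#' cleavages, disallowed modification, exact reference-proteome match,
#' two-mismatch reference match, and one-sided fragment ions. Each record is
#' tagged with its intended fate in the returned truth table.
#'
#' @param db Junction peptide database from [build_junction_db()]
#'   (non-empty).
#' @param reference Reference proteome (character vector); needed to plant
#'   the reference-matching violators.
#' @param n_true Number of true junction PSMs (default 10).
#' @param violators Character vector naming the violator kinds to plant
#'   (default: one of each).
#' @param samples Sample labels to draw from.
#' @param seed Integer seed.
#' @param out_dir Optional directory (`psms.tsv`, `truth.json`).
#' @return list: `psms` (annotated PSM data.frame), `truth` (data.frame:
#'   spectrum_id, kind, fate — "retained" or the filter that removes it).
#' @export
simulate_psms <- function(db, reference, n_true = 10L,
                          violators = c("high_q", "short_peptide",
                                        "thin_flank", "excess_missed",
                                        "bad_mod", "ref_exact", "ref_2mm",
                                        "one_sided_ions"),
                          samples = c("HeLa", "HEK293", "Liver", "Brain",
                                      "Colon", "Testis"),
                          seed = 1L, out_dir = NULL) {
  if (nrow(db) == 0L) stop("empty junction database", call. = FALSE)
  reference <- as.character(reference)
  res <- with_seed(seed, {
    refX <- il_collapse(reference)
    # db peptides that are safely novel vs the reference (so that planted
    # fates cannot collide with a chance reference match)
    novel <- vapply(il_collapse(db$peptide), function(p) {
      !matches_reference_homolog(p, refX, 2L)
    }, logical(1))
    pool <- db[novel & db$left_flank_aa >= 2L & db$right_flank_aa >= 2L &
                 db$missed_cleavages <= 3L, , drop = FALSE]
    if (nrow(pool) == 0L)
      stop("no usable junction peptides in the database", call. = FALSE)
    rows <- list(); truth <- list(); sid <- 0L
    new_id <- function() { sid <<- sid + 1L; sprintf("spec%04d", sid) }
    both_side_ions <- function(len, lf, span) {
      js <- junction_sites(len, lf, span)
      b <- sample1(js$left)
      y <- len - sample1(js$right)
      sprintf("b%d;y%d", b, y)
    }
    good_mod <- function(pep) {
      mpos <- which(strsplit(pep, "")[[1]] == "M")
      if (length(mpos) && runif(1) < 0.5)
        sprintf("%d:Oxidation", mpos[1]) else ""
    }
    emit <- function(row, kind, fate) {
      rows[[length(rows) + 1L]] <<- row
      truth[[length(truth) + 1L]] <<-
        data.frame(spectrum_id = row$spectrum_id, kind = kind, fate = fate,
                   stringsAsFactors = FALSE)
    }
    db_row <- function(i, q, ions, mods) {
      d <- pool[i, ]
      data.frame(spectrum_id = new_id(), peptide = d$peptide, q_value = q,
                 modifications = mods, sample_id = sample(samples, 1L),
                 matched_ions = ions, circ_id = d$circ_id, frame = d$frame,
                 left_flank_aa = d$left_flank_aa,
                 right_flank_aa = d$right_flank_aa,
                 missed_cleavages = d$missed_cleavages,
                 spanning = d$spanning, stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_true)) {
      i <- sample(nrow(pool), 1L)
      d <- pool[i, ]
      emit(db_row(i, runif(1, 0, 0.009),
                  both_side_ions(nchar(d$peptide), d$left_flank_aa,
                                 d$spanning),
                  good_mod(d$peptide)),
           "true", "retained")
    }
    synth_row <- function(pep, lf, rf, span, mc, q, ions, mods) {
      data.frame(spectrum_id = new_id(), peptide = pep, q_value = q,
                 modifications = mods, sample_id = sample(samples, 1L),
                 matched_ions = ions, circ_id = "synthetic",
                 frame = 1L, left_flank_aa = lf, right_flank_aa = rf,
                 missed_cleavages = mc, spanning = span,
                 stringsAsFactors = FALSE)
    }
    novel_aa <- function(len) {
      repeat {
        p <- random_aa(len)
        if (!matches_reference_homolog(il_collapse(p), refX, 2L) &&
            !grepl("[KR]", substr(p, 1, len - 1))) return(p)
      }
    }
    for (v in violators) {
      if (v == "high_q") {
        i <- sample(nrow(pool), 1L); d <- pool[i, ]
        emit(db_row(i, runif(1, 0.02, 0.2),
                    both_side_ions(nchar(d$peptide), d$left_flank_aa,
                                   d$spanning), ""),
             v, "threshold")
      } else if (v == "short_peptide") {
        pep <- novel_aa(7L)
        emit(synth_row(pep, 3L, 3L, TRUE, 0L, runif(1, 0, 0.009),
                       both_side_ions(7L, 3L, TRUE), ""),
             v, "threshold")
      } else if (v == "thin_flank") {
        pep <- novel_aa(10L)
        emit(synth_row(pep, 1L, 8L, TRUE, 0L, runif(1, 0, 0.009),
                       both_side_ions(10L, 1L, TRUE), ""),
             v, "threshold")
      } else if (v == "excess_missed") {
        # 15-mer with 4 internal K sites; novelty checked on the whole
        pep <- NULL
        repeat {
          frag <- function() paste(sample(setdiff(.AA20, c("K", "R")), 2L,
                                          replace = TRUE), collapse = "")
          p <- paste0(frag(), "K", frag(), "K", frag(), "K", frag(), "K",
                      substr(random_aa(3L), 1, 3))
          if (!matches_reference_homolog(il_collapse(p), refX, 2L)) {
            pep <- p; break
          }
        }
        emit(synth_row(pep, 6L, 8L, TRUE, 4L, runif(1, 0, 0.009),
                       both_side_ions(nchar(pep), 6L, TRUE), ""),
             v, "threshold")
      } else if (v == "bad_mod") {
        i <- sample(nrow(pool), 1L); d <- pool[i, ]
        emit(db_row(i, runif(1, 0, 0.009),
                    both_side_ions(nchar(d$peptide), d$left_flank_aa,
                                   d$spanning), "3:Deamidated"),
             v, "threshold")
      } else if (v == "ref_exact") {
        r <- sample(length(reference), 1L)
        len <- 10L
        s <- sample(nchar(reference[r]) - len + 1L, 1L)
        pep <- substr(reference[r], s, s + len - 1L)
        emit(synth_row(pep, 4L, 5L, TRUE, 0L, runif(1, 0, 0.009),
                       both_side_ions(len, 4L, TRUE), ""),
             v, "reference_exact")
      } else if (v == "ref_2mm") {
        repeat {
          r <- sample(length(reference), 1L)
          len <- 10L
          s <- sample(nchar(reference[r]) - len + 1L, 1L)
          pep <- mutate_protein(substr(reference[r], s, s + len - 1L), 2L)
          px <- il_collapse(pep)
          if (!matches_reference_exact(px, refX) &&
              matches_reference_homolog(px, refX, 2L)) break
        }
        emit(synth_row(pep, 4L, 5L, TRUE, 0L, runif(1, 0, 0.009),
                       both_side_ions(len, 4L, TRUE), ""),
             v, "reference_homology")
      } else if (v == "one_sided_ions") {
        i <- sample(nrow(pool), 1L); d <- pool[i, ]
        js <- junction_sites(nchar(d$peptide), d$left_flank_aa, d$spanning)
        ions <- sprintf("b%d", sample1(js$left))
        emit(db_row(i, runif(1, 0, 0.009), ions, ""), v, "fragment_ions")
      } else stop("unknown violator kind: ", v, call. = FALSE)
    }
    if (length(rows) == 0L) {
      psms <- db_row(1L, 0, "b1;y1", "")[0, , drop = FALSE]
      truth <- data.frame(spectrum_id = character(0), kind = character(0),
                          fate = character(0))
      list(psms = psms, truth = truth)
    } else {
      psms <- do.call(rbind, rows)
      truth <- do.call(rbind, truth)
      ord <- sample(nrow(psms))        # shuffle so order carries no signal
      list(psms = psms[ord, , drop = FALSE], truth = truth)
    }
  })
  rownames(res$psms) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(out_dir, "psms.tsv")
    write_psm_table(res$psms, tsv)
    tj <- file.path(out_dir, "truth.json")
    jsonlite::write_json(res$truth, tj, auto_unbox = TRUE)
    res$files <- c(psms = tsv, truth = tj)
  }
  res
}

#' Simulate a reference proteome
#'
#' @param n_proteins Number of proteins (default 20).
#' @param len_range Protein length range.
#' @param seed Integer seed.
#' @return Character vector of protein sequences named `ref001`...
#' @export
simulate_reference_proteome <- function(n_proteins = 20L,
                                        len_range = c(50L, 200L),
                                        seed = 1L) {
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n_proteins, replace = TRUE)
    setNames(vapply(lens, random_aa, character(1)),
             sprintf("ref%03d", seq_len(n_proteins)))
  })
}
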
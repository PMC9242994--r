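test_that("junction_translations returns 3 stop-bounded frames", {
  set.seed(31)
  for (i in 1:20) {
    L <- 3 * sample(10:40, 1) + sample(0:2, 1)
    sq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    jt <- junction_translations(sq)
    expect_identical(nrow(jt), 3L)
    expect_identical(jt$frame, 0:2)
    expect_false(any(grepl("\\*", jt$protein)))
    # each side is capped at one full circle
    expect_true(all(jt$n_left <= ceiling(L / 3) + 1))
    expect_true(all(nchar(jt$protein) - jt$n_left <= ceiling(L / 3) + 1))
    expect_true(all(jt$junction_pos == jt$n_left + 1L))
  }

  # stop-free circle: both sides hit the one-circle cap exactly
  rc <- strrep("GCT", 20)   # 60 nt of Ala, no stop in any frame
  jt2 <- junction_translations(rc)
  f0 <- jt2[jt2$frame == 0, ]
  expect_identical(f0$n_left, 20L)
  expect_identical(nchar(f0$protein), 40L)

  # stops right next to the junction bound the frame-0 protein tightly
  tight <- paste0("GCTGCT", "TAA", strrep("GCT", 3), "TAA", "GCT")
  jt3 <- junction_translations(tight)
  f0t <- jt3[jt3$frame == 0, ]
  expect_identical(nchar(f0t$protein), 3L)
  expect_identical(f0t$n_left, 1L)
})

test_that("digest_trypsin implements K/R cleavage with KP suppression", {
  d <- digest_trypsin("AAAAKCCCCR", max_missed = 1, min_len = 1)
  expect_setequal(d$peptide, c("AAAAK", "CCCCR", "AAAAKCCCCR"))
  expect_identical(d$missed[d$peptide == "AAAAKCCCCR"], 1L)

  # no K/R: the whole protein as one 0-missed peptide
  d2 <- digest_trypsin("ACDEFGHM", max_missed = 3, min_len = 1)
  expect_identical(d2$peptide, "ACDEFGHM")
  expect_identical(d2$missed, 0L)

  # KP suppression
  d3 <- digest_trypsin("AAKPAAR", max_missed = 0, min_len = 1)
  expect_identical(d3$peptide, "AAKPAAR")
  expect_identical(d3$missed, 0L)
  d3b <- digest_trypsin("AAKPAAR", max_missed = 0, min_len = 1,
                        suppress_proline = FALSE)
  expect_setequal(d3b$peptide, c("AAK", "PAAR"))
})

test_that("digestion satisfies the reconstruction identities", {
  set.seed(33)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:25) {
    prot <- paste(sample(aas, sample(20:120, 1), replace = TRUE),
                  collapse = "")
    d <- digest_trypsin(prot, max_missed = 3, min_len = 1)
    zero <- d[d$missed == 0, ]
    zero <- zero[order(zero$start), ]
    # 0-missed peptides tile the protein exactly
    expect_identical(paste(zero$peptide, collapse = ""), prot)
    expect_identical(paste(oracle_tryptic_fragments(prot), collapse = ""),
                     prot)
    expect_identical(sort(zero$peptide),
                     sort(oracle_tryptic_fragments(prot)))
    # every k-missed peptide is the concatenation of k+1 consecutive
    # 0-missed fragments
    for (k in 1:3) {
      kk <- d[d$missed == k, ]
      if (nrow(kk) == 0) next
      for (j in seq_len(nrow(kk))) {
        i0 <- which(zero$start == kk$start[j])
        expect_identical(
          paste(zero$peptide[i0:(i0 + k)], collapse = ""), kk$peptide[j])
      }
    }
  }
})

test_that("build_junction_db enforces flank, length and missed rules", {
  db <- build_junction_db(data.frame(id = "toy",
                                     seq = toy_junction_circle()))
  expect_gt(nrow(db), 0)
  # independent re-check of every record
  jt_all <- junction_translations(toy_junction_circle(), "toy")
  for (i in seq_len(nrow(db))) {
    expect_gte(db$left_flank_aa[i], 2L)
    expect_gte(db$right_flank_aa[i], 2L)
    expect_gte(nchar(db$peptide[i]), 8L)
    expect_lte(db$missed_cleavages[i], 3L)
    # the peptide occurs in its frame's junction protein around the junction
    jp <- jt_all[jt_all$frame == db$frame[i], ]
    expect_true(grepl(db$peptide[i], jp$protein, fixed = TRUE))
  }

  # junction-adjacent residue counts: a peptide with a 1-aa flank or
  # length 7 never enters the database
  expect_true(all(db$left_flank_aa >= 2 & db$right_flank_aa >= 2))
  expect_true(all(nchar(db$peptide) >= 8))

  # empty input
  empty <- build_junction_db(data.frame(id = character(0),
                                        seq = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("junction database FASTA round-trips", {
  sim <- simulate_circrnas(n = 8, seed = 41)
  db <- build_junction_db(sim$circs)
  path <- withr::local_tempfile(fileext = ".fa")
  write_junction_db(db, path)
  back <- read_junction_db(path)
  expect_identical(back$peptide, db$peptide)
  expect_identical(back$circ_id, db$circ_id)
  expect_identical(back$frame, db$frame)
  expect_identical(back$junction_offset, db$junction_offset)
})

make_psm <- function(peptide, q = 0.001, mods = "", ions = "b2;y2",
                     lf = 3L, rf = 3L, spanning = TRUE, missed = 0L,
                     id = "s1", sample_id = "HeLa") {
  data.frame(spectrum_id = id, peptide = peptide, q_value = q,
             modifications = mods, sample_id = sample_id,
             matched_ions = ions, circ_id = "c1", frame = 1L,
             left_flank_aa = lf, right_flank_aa = rf,
             missed_cleavages = missed, spanning = spanning,
             stringsAsFactors = FALSE)
}

test_that("filter_psms applies each rule at its step", {
  ref <- c("MAGWDNSTPQRFFYHEDCVKLMNPQ")
  pep <- "WWFYHDNQGA"   # unrelated to ref

  # q >= 0.01 removed at threshold
  fr <- filter_psms(make_psm(pep, q = 0.02), ref)
  expect_identical(nrow(fr$psms), 0L)
  expect_identical(fr$rejected$step, "threshold")
  expect_identical(fr$rejected$reason, "q_value")

  # short / thin-flank / excess-missed / bad modification
  fr2 <- filter_psms(rbind(
    make_psm("WWFYHDN", id = "len"),        # 7 aa
    make_psm(pep, lf = 1L, id = "flank"),
    make_psm(pep, missed = 4L, id = "mc"),
    make_psm(pep, mods = "2:Deamidated", id = "mod"),
    make_psm(pep, mods = "not-a-mod", id = "malformed")), ref)
  expect_identical(nrow(fr2$psms), 0L)
  expect_true(all(fr2$rejected$step == "threshold"))
  expect_setequal(fr2$rejected$reason,
                  c("length", "flank", "missed_cleavages", "modification",
                    "malformed"))

  # exact reference substring removed at step 2 (I/L equivalent)
  fr3 <- filter_psms(make_psm("GWDNSTPQR", id = "exact"), ref)
  expect_identical(fr3$rejected$step, "reference_exact")
  fr3b <- filter_psms(make_psm("DCVKIMNPQ", id = "il"), ref)  # L->I
  expect_identical(fr3b$rejected$step, "reference_exact")

  # Hamming distance 2 from a reference subsequence removed at step 3
  fr4 <- filter_psms(make_psm("GWDNSTPWW", id = "h2"), ref)
  expect_identical(fr4$rejected$step, "reference_homology")

  # fragment ions must flank the junction on both sides
  left_only <- make_psm(pep, ions = "b1;b2", id = "left")
  fr5 <- filter_psms(left_only, ref)
  expect_identical(fr5$rejected$step, "fragment_ions")
  both <- make_psm(pep, ions = "b2;y3", id = "both")
  fr6 <- filter_psms(both, ref)
  expect_identical(fr6$psms$spectrum_id, "both")

  # allowed modifications pass
  fr7 <- filter_psms(make_psm(pep, mods = "1:Oxidation;3:Phospho",
                              id = "ok"), ref)
  expect_identical(nrow(fr7$psms), 1L)
})

test_that("filter report is monotone and chains in/out counts", {
  sim <- simulate_circrnas(n = 10, seed = 51)
  db <- build_junction_db(sim$circs)
  ref <- simulate_reference_proteome(seed = 52)
  ps <- simulate_psms(db, ref, n_true = 6, seed = 53)
  fr <- filter_psms(ps$psms, ref)
  rp <- fr$report
  expect_identical(rp$filter, c("threshold", "reference_exact",
                                "reference_homology", "fragment_ions"))
  expect_true(all(rp$n_out <= rp$n_in))
  expect_equal(rp$n_in[-1], rp$n_out[-nrow(rp)])
  expect_equal(rp$n_in[1], nrow(ps$psms))
  expect_equal(rp$n_out[nrow(rp)], nrow(fr$psms))
})

test_that("fragment-site geometry around the junction is exact", {
  # frame 0 (no spanning residue): the site at the junction is neither side
  pep <- "AAAABBBB"  # 4 left, 4 right, no spanning residue
  ps <- make_psm(pep, lf = 4L, rf = 4L, spanning = FALSE,
                 ions = "b4;y4", id = "atj")
  fr <- filter_psms(ps, "WWWWWWWWWW")
  # b4 site == junction (not strictly left); y4 site == junction too
  expect_identical(nrow(fr$psms), 0L)
  ps2 <- make_psm(pep, lf = 4L, rf = 4L, spanning = FALSE,
                  ions = "b3;y3", id = "flank2")
  fr2 <- filter_psms(ps2, "WWWWWWWWWW")
  expect_identical(nrow(fr2$psms), 1L)

  # spanning residue: the site right before it is strictly left
  ps3 <- make_psm("AAAACBBBB", lf = 4L, rf = 4L, spanning = TRUE,
                  ions = "b4;y4", id = "span")
  fr3 <- filter_psms(ps3, "WWWWWWWWWW")
  expect_identical(nrow(fr3$psms), 1L)
})

test_that("linear_control_peptides mirrors the back-splice rules", {
  # 3-exon toy transcript; circle over exon 2 -> two control junctions
  set.seed(61)
  aa2codon <- c(A = "GCT", R = "CGT", K = "AAA", G = "GGT", S = "TCT")
  exon <- function(aas) paste(aa2codon[aas], collapse = "")
  e1 <- exon(c("G", "S", "A", "A", "R"))
  e2 <- exon(c("A", "A", "A", "K", "G", "A", "A", "A", "R"))
  e3 <- exon(c("A", "A", "G", "S", "K"))
  tx <- paste0(e1, e2, e3)
  ends <- cumsum(nchar(c(e1, e2, e3)))
  ctl <- linear_control_peptides(tx, ends, c(2L, 2L), min_len = 6,
                                 min_flank = 2)
  expect_true(all(c("upstream", "downstream") %in% ctl$junction))
  expect_true(all(ctl$left_flank_aa >= 2 & ctl$right_flank_aa >= 2))
  expect_true(all(nchar(ctl$peptide) >= 6))
  expect_true(all(ctl$missed_cleavages <= 3))

  # single-exon host: no adjacent junction, empty control set
  ctl2 <- linear_control_peptides(e2, nchar(e2), c(1L, 1L))
  expect_identical(nrow(ctl2), 0L)
})

test_that("junction residue statistics count K/R correctly", {
  jp <- data.frame(circ_id = c("a", "b", "c", "d"), frame = 0L,
                   protein = c("AAKAAA", "AARAAA", "AAAAAA", "KAAAAA"),
                   junction_pos = 4L, n_left = c(3L, 3L, 3L, 0L),
                   spanning = FALSE)
  st <- junction_residue_stats(jp)
  # d is skipped (junction at boundary); a and b have K/R at -1
  expect_identical(st$n_used, 3L)
  expect_identical(st$n_skipped, 1L)
  expect_equal(st$frac_kr_minus1, 2 / 3)
  expect_equal(st$frac_any_kr, 3 / 4)
})

test_that("spectra_summaries aggregates per junction", {
  ps <- rbind(make_psm("WWFYHDNQGA", id = "s1"),
              make_psm("WWFYHDNQGA", id = "s2", sample_id = "Liver"),
              make_psm("WWFYHDNQGA", id = "s3", sample_id = "Liver"))
  sm <- spectra_summaries(ps)
  expect_identical(sm$spectra, 3L)
  expect_identical(sm$samples, 2L)
  empty <- spectra_summaries(ps[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("PSM tables round-trip through TSV", {
  sim <- simulate_circrnas(n = 6, seed = 71)
  db <- build_junction_db(sim$circs)
  ref <- simulate_reference_proteome(seed = 72)
  ps <- simulate_psms(db, ref, n_true = 4, seed = 73)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(ps$psms, path)
  back <- read_psm_table(path)
  expect_identical(back$peptide, ps$psms$peptide)
  expect_identical(back$modifications, ps$psms$modifications)
  expect_identical(back$matched_ions, ps$psms$matched_ions)
  expect_equal(back$q_value, ps$psms$q_value, tolerance = 1e-12)
})
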
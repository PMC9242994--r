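ctx <- vector_context()
up <- ctx$upstream_flank
dn <- ctx$downstream_flank

test_that("extract_inserts recovers inserts only between exact flanks", {
  good <- paste0(up, "ACGTACGTAC", dn)
  expect_identical(extract_inserts(good, ctx)$inserts, "ACGTACGTAC")

  # one mismatch in the upstream 24-nt flank kills recovery
  up24_start <- nchar(up) - 23L
  bad <- good
  substr(bad, up24_start, up24_start) <-
    setdiff(c("A", "C", "G", "T"), substr(good, up24_start, up24_start))[1]
  expect_identical(extract_inserts(bad, ctx)$n_reads_matched, 0L)

  # mismatch in the downstream flank likewise
  bad2 <- paste0(up, "ACGTACGTAC", "T", substr(dn, 2, nchar(dn)))
  if (substr(dn, 1, 1) == "T")
    bad2 <- paste0(up, "ACGTACGTAC", "A", substr(dn, 2, nchar(dn)))
  expect_identical(extract_inserts(bad2, ctx)$n_reads_matched, 0L)

  # inserts containing N are dropped; empty input is fine
  withN <- paste0(up, "ACGTNCGTAC", dn)
  expect_identical(extract_inserts(withN, ctx)$n_reads_matched, 0L)
  empty <- extract_inserts(character(0), ctx)
  expect_identical(empty$n_reads_total, 0L)
  expect_identical(empty$inserts, character(0))
})

test_that("extract_inserts agrees with a naive substring-search oracle", {
  set.seed(101)
  n <- 1000
  inserts <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10,
                                       replace = TRUE), collapse = ""))
  good <- sample(n, 900)
  reads <- vapply(seq_len(n), function(i) {
    if (i %in% good) paste0(up, inserts[i], dn)
    else paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
               collapse = "")
  }, character(1))
  got <- extract_inserts(reads, ctx)
  want <- oracle_insert_search(reads, up, dn)
  expect_gte(got$n_reads_matched, 900L)  # random reads can match by chance
  expect_identical(sort(got$inserts), sort(want))
  expect_true(all(grepl("^[ACGT]{10}$", got$inserts)))
})

test_that("count_hexamers decomposes the 14-mer extension correctly", {
  cx <- vector_context(paste0(strrep("G", 22), "AA"),
                       paste0("AT", strrep("G", 28)))
  tab <- count_hexamers("AAAAAAAAAA", cx)
  expect_identical(unname(tab["AAAAAA"]), 8L)
  expect_identical(unname(tab["AAAAAT"]), 1L)
  expect_identical(attr(tab, "total"), 9L)

  # empty set and window arithmetic: total = 9k
  empty <- count_hexamers(character(0), cx)
  expect_identical(attr(empty, "total"), 0L)
  expect_true(all(empty == 0L))
  k <- 17L
  many <- count_hexamers(replicate(k, paste(sample(c("A", "C", "G", "T"),
                                                   10, replace = TRUE),
                                            collapse = "")), cx)
  expect_identical(attr(many, "total"), 9L * k)
  expect_identical(sum(many), 9L * k)

  # non-decamer inserts are rejected and tallied
  mixed <- count_hexamers(c("AAAAAAAAAA", "AAA"), cx)
  expect_identical(attr(mixed, "rejected"), 1L)
  expect_identical(attr(mixed, "total"), 9L)
})

test_that("score_enrichment matches the pooled two-proportion form", {
  g <- make_count_table(c(AAAAAA = 100), total = 1000)
  d <- make_count_table(c(AAAAAA = 10), total = 1000)
  sc <- score_enrichment(g, d)
  z <- sc$z[sc$hexamer == "AAAAAA"]
  expect_equal(z, oracle_two_prop_z(100, 1000, 10, 1000), tolerance = 1e-12)
  expect_equal(z, 8.83, tolerance = 1e-2)
  expect_identical(sc$class[sc$hexamer == "AAAAAA"], "enriched")

  g2 <- make_count_table(c(CCCCCC = 0), total = 1000)
  d2 <- make_count_table(c(CCCCCC = 50), total = 1000)
  sc2 <- score_enrichment(g2, d2)
  z2 <- sc2$z[sc2$hexamer == "CCCCCC"]
  expect_equal(z2, oracle_two_prop_z(0, 1000, 50, 1000), tolerance = 1e-12)
  expect_equal(z2, -7.16, tolerance = 1e-2)
  expect_identical(sc2$class[sc2$hexamer == "CCCCCC"], "depleted")

  # identical tables: all z = 0, all neutral; zero-zero convention
  sc3 <- score_enrichment(g, g)
  expect_true(all(sc3$z == 0))
  expect_true(all(sc3$class == "neutral"))

  expect_error(score_enrichment(make_count_table(c(), total = 0), d),
               "positive totals")
})

test_that("score_enrichment is antisymmetric and matches the oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x1 <- setNames(as.integer(rmultinom(1, 5000, rep(1, 4096))),
                   all_hexamers())
    x2 <- setNames(as.integer(rmultinom(1, 8000, runif(4096))),
                   all_hexamers())
    a <- structure(x1, total = sum(x1), class = "hexamer_counts")
    b <- structure(x2, total = sum(x2), class = "hexamer_counts")
    ab <- score_enrichment(a, b)
    ba <- score_enrichment(b, a)
    expect_equal(ab$z, -ba$z, tolerance = 1e-12)
    want <- oracle_two_prop_z(as.numeric(x1), sum(x1),
                              as.numeric(x2), sum(x2))
    want[x1 + x2 == 0] <- 0
    expect_equal(ab$z, want, tolerance = 1e-9)
  }
})

test_that("composition_stats matches hand enumeration", {
  st <- composition_stats("ACACACACAC")
  expect_equal(unname(st$base_freq[c("A", "C")]), c(0.5, 0.5))
  expect_equal(st$dinuc_freq["A", "C"], 5 / 9)
  expect_equal(st$odds["A", "C"], 20 / 9)

  st2 <- composition_stats("AAAAAAAAAA")
  expect_equal(unname(st2$base_freq["A"]), 1)
  expect_equal(st2$odds["A", "A"], 1)
  expect_true(is.na(st2$odds["C", "C"]))  # zero-frequency denominator

  # large uniform library: odds ~ 1 within 3 SE
  set.seed(11)
  lib <- replicate(3000, paste(sample(c("A", "C", "G", "T"), 10,
                                      replace = TRUE), collapse = ""))
  st3 <- composition_stats(lib)
  nwin <- 9 * 3000
  for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T")) {
    p <- 1 / 16
    se <- sqrt(p * (1 - p) / nwin) / p  # relative SE of the odds numerator
    expect_lt(abs(st3$odds[x, y] - 1), 3 * se + 0.05)
  }
})

test_that("cluster_hexamers is deterministic with sane consensus matrices", {
  # identical members collapse to one-hot columns
  cl1 <- cluster_hexamers(rep("ACGTAC", 5), 1)
  expect_length(cl1, 1)
  expect_true(all(apply(cl1[[1]]$consensus_matrix, 2, max) == 1))
  expect_identical(cl1[[1]]$label, "ACGTAC")

  # maximally distant pair separates
  cl2 <- cluster_hexamers(c("AAAAAA", "TTTTTT"), 2)
  expect_length(cl2, 2)
  expect_true(all(lengths(lapply(cl2, `[[`, "members")) == 1))

  expect_error(cluster_hexamers(c("AAAAAA"), 3), "n_clusters")

  # requested cluster count is honoured; columns sum to 1; deterministic
  set.seed(3)
  hx <- unique(replicate(97, paste(sample(c("A", "C", "G", "T"), 6,
                                          replace = TRUE), collapse = "")))
  cl3 <- cluster_hexamers(hx, 11)
  expect_length(cl3, 11)
  for (cl in cl3)
    expect_true(all(abs(colSums(cl$consensus_matrix) - 1) < 1e-9))
  cl3b <- cluster_hexamers(sample(hx), 11)
  expect_identical(lapply(cl3, `[[`, "members"),
                   lapply(cl3b, `[[`, "members"))
})

test_that("vector_context validates its flanks", {
  expect_error(vector_context("ACGT", strrep("A", 30)), "24")
  expect_error(vector_context(strrep("A", 24), "ACGT"), "30")
  cx <- vector_context(paste0(strrep("A", 23), "G"),
                       paste0("TC", strrep("A", 28)))
  expect_identical(cx$extension_left, "AG")
  expect_identical(cx$extension_right, "TC")
})
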
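# Independent oracles used to cross-check package implementations. These are
# written against the definitions only and deliberately share no code with
# the package internals.

# pooled two-proportion z statistic
oracle_two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
}

# two-sample KS D statistic by direct ECDF evaluation
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# brute-force circular ORF caller: translate from every NTG in every
# rotation of the literal circle, walking cycle by cycle for 4 cycles
oracle_circorfs <- function(seq, min_aa = 20L) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  starts <- c("ATG", "CTG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  if (L < 3L) {
    return(data.frame(start_offset = integer(0), type = character(0),
                      length_aa = numeric(0)))
  }
  for (r in 0:(L - 1L)) {
    codon_idx <- function(k) ((r + 3L * k):(r + 3L * k + 2L)) %% L + 1L
    first <- paste(chars[codon_idx(0L)], collapse = "")
    if (!(first %in% starts)) next
    max_codons <- (4L * L) %/% 3L
    stop_k <- NA_integer_
    for (k in seq_len(max_codons) - 1L) {
      cd <- paste(chars[codon_idx(k)], collapse = "")
      if (cd %in% stops) { stop_k <- k; break }
    }
    if (is.na(stop_k)) {
      out[[length(out) + 1L]] <-
        data.frame(start_offset = r, type = "rcORF", length_aa = Inf)
    } else if (stop_k >= min_aa) {
      out[[length(out) + 1L]] <-
        data.frame(start_offset = r, type = "cORF", length_aa = stop_k)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start_offset = integer(0), type = character(0),
                      length_aa = numeric(0)))
  do.call(rbind, out)
}

# naive tryptic cut-site enumeration (cleave after K/R not before P)
oracle_tryptic_fragments <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cuts <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (aa[i] %in% c("K", "R") && aa[i + 1L] != "P") cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  substring(protein, starts, ends)
}

# naive substring search for library inserts: exact 24/30-nt flanks
oracle_insert_search <- function(reads, up, dn) {
  up24 <- substr(up, nchar(up) - 23L, nchar(up))
  dn30 <- substr(dn, 1L, 30L)
  found <- character(0)
  for (r in reads) {
    i <- 1L
    repeat {
      hit <- regexpr(up24, substr(r, i, nchar(r)), fixed = TRUE)
      if (hit < 0) break
      pos <- i + hit - 1L
      ins <- substr(r, pos + 24L, pos + 33L)
      rest <- substr(r, pos + 34L, pos + 63L)
      if (nchar(ins) == 10L && rest == dn30 && !grepl("[^ACGT]", ins)) {
        found <- c(found, ins)
        break
      }
      i <- pos + 1L
    }
  }
  found
}

# deterministic small fixtures ------------------------------------------------

make_count_table <- function(counts_named, total = sum(counts_named)) {
  space <- all_hexamers()
  v <- setNames(integer(4096), space)
  v[names(counts_named)] <- as.integer(counts_named)
  structure(v, total = total, class = "hexamer_counts")
}

# a circle with one tryptic junction peptide with wide flanks: frame 0,
# junction between the R-terminated upstream and K-terminated downstream
toy_junction_circle <- function() {
  # codons (frame 0, junction before position 0):
  # upstream of junction: ... A A A R | junction | A A A A K ...
  # build the circle so translation is stop-free around the junction but
  # stops far away, keeping the protein small
  aa2codon <- c(A = "GCT", R = "CGT", K = "AAA", G = "GGT", S = "TCT")
  up <- c("G", "S", "A", "A", "A", "R")      # ends upstream of junction
  dn <- c("A", "A", "A", "A", "K", "G", "S") # starts at junction
  paste0(paste(aa2codon[dn], collapse = ""),
         "TAATAA",                            # stop block away from junction
         paste(aa2codon[up], collapse = ""))
}
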
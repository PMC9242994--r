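#' @keywords internal
"_PACKAGE"

#' @importFrom stats hclust cutree as.dist ks.test runif setNames aggregate
#' @importFrom utils write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
NTG_STARTS <- c("ATG", "CTG", "GTG", "TTG")

# codon -> amino acid lookup ("*" for stops), from the standard genetic code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.pkg_cache <- new.env(parent = emptyenv())

codon_aa <- function() {
  if (is.null(.pkg_cache$codon_aa)) .pkg_cache$codon_aa <- codon_table()
  .pkg_cache$codon_aa
}

#' Enumerate the full hexamer space
#'
#' All 4^6 = 4096 DNA hexamers in lexicographic order. This fixed ordering is
#' used as the index of every hexamer count table and score table in the
#' package.
#'
#' @return Character vector of length 4096.
#' @export
all_hexamers <- function() {
  g <- expand.grid(rep(list(DNA_BASES), 6), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; flip for lexicographic order
  sort(do.call(paste0, g))
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: e.g. '%s'",
                 what, if (allow_n) ",N" else "", x[which(bad)[1]]),
         call. = FALSE)
  }
  invisible(x)
}

# all overlapping k-mer windows of a single string (step 1)
kmer_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# translate a vector of codons; stops become "*"
translate_codons <- function(codons) {
  aa <- codon_aa()[codons]
  aa[is.na(aa)] <- "X"
  aa
}

# run an expression with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random DNA strings: n sequences of the given lengths
random_dna <- function(n, len, alphabet = DNA_BASES) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  chars <- sample(alphabet, sum(len), replace = TRUE)
  vapply(split(chars, rep.int(seq_len(n), len)), paste, collapse = "",
         FUN.VALUE = character(1), USE.NAMES = FALSE)
}

rotate_string <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1L, n), substr(s, 1L, r))
}
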
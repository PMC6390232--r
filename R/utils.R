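# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars internally; Biostrings objects appear only at
# I/O boundaries and for alignment/translation.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

gc_fraction <- function(x) {
  ch <- seq_chars(x)
  sum(ch %in% c("G", "C")) / length(ch)
}

is_dna <- function(x, allow_n = TRUE) {
  ch <- seq_chars(x)
  ok <- c("A", "C", "G", "T", if (allow_n) "N")
  all(ch %in% ok)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(names(p), n, replace = TRUE, prob = p))
}

# Match a character vector of subject bases against one IUPAC motif
# character. Subject 'N' (or anything non-ACGT) matches nothing: a window
# containing N never qualifies as a site.
iupac_char_match <- function(subject_chars, motif_char) {
  allowed <- IUPAC_SETS[[motif_char]]
  if (is.null(allowed)) stop("invalid IUPAC code in motif: ", motif_char)
  subject_chars %in% allowed
}

# All start positions (1-based) in `chars` where the IUPAC `motif` matches.
iupac_match_starts <- function(chars, motif) {
  m <- seq_chars(motif)
  L <- length(chars)
  k <- length(m)
  if (L < k) return(integer(0))
  ok <- rep(TRUE, L - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & iupac_char_match(chars[j:(L - k + j)], m[j])
  }
  which(ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
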
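#' Build a strain haplotype from a reference locus and a variant table
#'
#' Applies substitutions in place and indels with exact downstream
#' coordinate shifts, producing the strain's copy of the locus together
#' with a bidirectional coordinate map:
#'
#' * `hap2ref[i]` — reference position of haplotype base `i`, `NA` for
#'   inserted bases (no reference homolog);
#' * `ref2hap[j]` — haplotype position of reference base `j`, `NA` for
#'   deleted bases.
#'
#' Outside indel footprints the two maps are exact inverses. The anchor
#' base of a left-anchored indel maps normally.
#'
#' @param gene_model reference [gene_model()].
#' @param variants a [variant_table()] validated against that model (an
#'   empty table yields a haplotype identical to the reference).
#' @param strain label for the strain the haplotype represents.
#' @return An object of class `haplotype` with fields `strain`, `sequence`,
#'   `hap2ref`, `ref2hap`, `variants`.
#' @examples
#' gm <- gene_model("toy", "ACGTCCGTAC", data.frame(start = 1, end = 9))
#' vt <- variant_table(5, "C", "G", gm, source = "donor")
#' build_haplotype(gm, vt, "donor")$sequence  # "ACGTGCGTAC"
#' @export
build_haplotype <- function(gene_model, variants = NULL, strain = "strain") {
  ref_chars <- seq_chars(gene_model$sequence)
  nref <- length(ref_chars)
  if (is.null(variants) || nrow(variants) == 0) {
    variants <- variant_table(gene_model = gene_model, source = strain)
    hap <- list(strain = strain, sequence = gene_model$sequence,
                hap2ref = seq_len(nref), ref2hap = seq_len(nref),
                variants = variants)
    class(hap) <- "haplotype"
    return(hap)
  }
  # revalidate against this model (sortedness, overlap, REF match)
  variants <- variant_table(variants$pos, variants$ref, variants$alt,
                            gene_model = gene_model,
                            source = attr(variants, "source") %||% strain)

  seq_out <- character(0)
  map_out <- integer(0)
  cursor <- 1L  # next reference position to copy
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    refl <- nchar(variants$ref[i])
    altc <- seq_chars(variants$alt[i])
    if (p > cursor) {
      seg <- cursor:(p - 1L)
      seq_out <- c(seq_out, ref_chars[seg])
      map_out <- c(map_out, seg)
    }
    kind <- variants$kind[i]
    if (kind == "SNP") {
      seq_out <- c(seq_out, altc)
      map_out <- c(map_out, p)
    } else if (kind == "INS") {
      # anchor base maps; inserted bases have no reference homolog
      seq_out <- c(seq_out, altc)
      map_out <- c(map_out, p, rep(NA_integer_, length(altc) - 1L))
    } else { # DEL: keep anchor, skip deleted reference bases
      seq_out <- c(seq_out, altc)
      map_out <- c(map_out, p)
    }
    cursor <- p + refl
  }
  if (cursor <= nref) {
    seg <- cursor:nref
    seq_out <- c(seq_out, ref_chars[seg])
    map_out <- c(map_out, seg)
  }
  ref2hap <- rep(NA_integer_, nref)
  covered <- !is.na(map_out)
  ref2hap[map_out[covered]] <- which(covered)
  hap <- list(strain = strain, sequence = chars_seq(seq_out),
              hap2ref = map_out, ref2hap = ref2hap, variants = variants)
  class(hap) <- "haplotype"
  hap
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("haplotype '%s': %d nt (%+d vs reference), %d variant(s)\n",
              x$strain, nchar(x$sequence),
              nchar(x$sequence) - length(x$ref2hap), nrow(x$variants)))
  invisible(x)
}

#' Project a run of haplotype positions onto another haplotype
#'
#' Maps `positions` (on `from`) through the reference onto `to`. Returns a
#' vector of the same length with `NA` where a position has no homolog
#' (inside an insertion on `from` or a deletion on `to`).
#'
#' @param from,to [build_haplotype()] objects over the same reference.
#' @param positions integer positions on `from`.
#' @export
project_positions <- function(from, to, positions) {
  refp <- from$hap2ref[positions]
  out <- rep(NA_integer_, length(positions))
  ok <- !is.na(refp)
  out[ok] <- to$ref2hap[refp[ok]]
  out
}

#' Check strain variants against confirmation reads
#'
#' Confirmation reads (e.g. Sanger fragments from the actual animals used)
#' are matched exactly against both the haplotype and the reference, on both
#' strands. A variant is
#'
#' * `confirmed` when some read matches the haplotype across the variant's
#'   footprint (it carries the ALT allele) and no read contradicts it;
#' * `contradicted` when some read matches the *reference* across the
#'   footprint (the animal carries REF where ALT was expected);
#' * `uncovered` otherwise — including reads that match both sequences
#'   equally, which cover no diagnostic position.
#'
#' @param haplotype a [build_haplotype()] result.
#' @param reads character vector of read sequences, or a path to a FASTA
#'   file, or a [Biostrings::DNAStringSet].
#' @param confirmed_only_warning warn when any variant is left unconfirmed.
#' @return data.frame with columns `pos`, `ref`, `alt`, `status`.
#' @export
confirm_variants <- function(haplotype, reads, confirmed_only_warning = TRUE) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads)
  }
  reads <- toupper(as.character(reads))
  vt <- haplotype$variants
  status <- rep("uncovered", nrow(vt))
  if (nrow(vt) == 0) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), status = character(0)))
  }
  hapseq <- haplotype$sequence
  # footprints on each sequence
  hap_lo <- haplotype$ref2hap[vt$pos]
  hap_hi <- hap_lo + nchar(vt$alt) - 1L
  ref_lo <- vt$pos
  ref_hi <- vt$pos + nchar(vt$ref) - 1L

  covers <- function(sequence, lo, hi, read) {
    for (r in c(read, revcomp(read))) {
      m <- gregexpr(r, sequence, fixed = TRUE)[[1]]
      m <- m[m > 0]
      for (s in m) if (s <= lo && s + nchar(r) - 1L >= hi) return(TRUE)
    }
    FALSE
  }
  ref_sequence <- ref_from_haplotype(haplotype)
  for (i in seq_len(nrow(vt))) {
    conf <- any(vapply(reads, function(r)
      covers(hapseq, hap_lo[i], hap_hi[i], r), TRUE))
    contra <- any(vapply(reads, function(r)
      covers(ref_sequence, ref_lo[i], ref_hi[i], r), TRUE))
    status[i] <- if (contra) "contradicted" else if (conf) "confirmed"
                 else "uncovered"
  }
  if (confirmed_only_warning && any(status != "confirmed")) {
    warning(sum(status != "confirmed"),
            " variant(s) not confirmed; guide design should use confirmed variants only")
  }
  data.frame(pos = vt$pos, ref = vt$ref, alt = vt$alt, status = status,
             stringsAsFactors = FALSE)
}

# Rebuild the reference sequence from a haplotype by inverting its variants.
ref_from_haplotype <- function(haplotype) {
  hap_chars <- seq_chars(haplotype$sequence)
  vt <- haplotype$variants
  out <- character(length(haplotype$ref2hap))
  covered <- !is.na(haplotype$ref2hap)
  out[covered] <- hap_chars[haplotype$ref2hap[covered]]
  for (i in seq_len(nrow(vt))) {
    ref <- seq_chars(vt$ref[i])
    out[vt$pos[i]:(vt$pos[i] + length(ref) - 1L)] <- ref
  }
  chars_seq(out)
}
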
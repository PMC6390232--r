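#' Build a strain variant table
#'
#' Variants are stored VCF-style: `pos` is the 1-based position of the first
#' REF base on the locus sequence, and insertions/deletions are
#' left-anchored (`ref = "A", alt = "ATTG"` inserts TTG after the anchor
#' base). Every record's REF must match the gene sequence, records must be
#' sorted and their REF footprints must not overlap — the haplotype builder
#' relies on both.
#'
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of REF/ALT alleles (A/C/G/T only).
#' @param gene_model the [gene_model()] the positions refer to.
#' @param source label for the variant source (e.g. the strain name).
#' @return A `variant_table`: a data.frame with columns `pos`, `ref`, `alt`,
#'   `kind` (`SNP`/`INS`/`DEL`) and a `source` attribute.
#' @export
variant_table <- function(pos = integer(0), ref = character(0),
                          alt = character(0), gene_model = NULL,
                          source = "strain") {
  stopifnot(length(pos) == length(ref), length(pos) == length(alt))
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(pos) && !all(vapply(c(ref, alt), is_dna, TRUE, allow_n = FALSE))) {
    stop("variant alleles must be plain A/C/G/T strings")
  }
  kind <- ifelse(nchar(ref) == nchar(alt), "SNP",
                 ifelse(nchar(ref) < nchar(alt), "INS", "DEL"))
  if (any(kind == "SNP" & nchar(ref) != 1L)) {
    stop("multi-nucleotide substitutions are not supported")
  }
  if (any(kind != "SNP" & pmin(nchar(ref), nchar(alt)) != 1L)) {
    stop("indels must be left-anchored with a single shared anchor base")
  }
  o <- order(pos)
  tab <- data.frame(pos = pos[o], ref = ref[o], alt = alt[o], kind = kind[o],
                    stringsAsFactors = FALSE)
  if (nrow(tab) > 1) {
    fend <- tab$pos + nchar(tab$ref) - 1L
    ov <- which(tab$pos[-1] <= fend[-nrow(tab)])
    if (length(ov)) {
      stop(sprintf("overlapping variants at positions %d and %d",
                   tab$pos[ov[1]], tab$pos[ov[1] + 1]))
    }
  }
  if (!is.null(gene_model)) {
    chars <- seq_chars(gene_model$sequence)
    for (i in seq_len(nrow(tab))) {
      want <- seq_chars(tab$ref[i])
      got <- chars[tab$pos[i]:(tab$pos[i] + length(want) - 1L)]
      if (any(is.na(got)) || !identical(got, want)) {
        stop(sprintf(
          "REF mismatch at position %d: variant says '%s', sequence has '%s' (wrong reference build?)",
          tab$pos[i], tab$ref[i], chars_seq(got)))
      }
      if (any(got == "N")) {
        stop(sprintf("variant at position %d overlaps an N base", tab$pos[i]))
      }
    }
  }
  attr(tab, "source") <- source
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' Read strain variants from a VCF file
#'
#' Keeps records whose footprint lies inside the locus; out-of-locus records
#' are dropped with a message. Multi-allelic records are split into
#' biallelic ones (or rejected with `multiallelic = "reject"`); symbolic or
#' breakend ALT alleles are always rejected. Records with a heterozygous
#' sample genotype — not fixed in the inbred strain — are excluded by
#' default and admitted with a warning when `keep_het = TRUE`.
#'
#' A REF allele that does not match the gene sequence is a hard error: it
#' signals that the variant file and reference belong to different builds.
#'
#' @param vcf_path path to a VCF v4.x file (plain or bgzipped).
#' @param gene_model the target [gene_model()]; the VCF's positions must be
#'   on this sequence's coordinates.
#' @param source label recorded on the returned table; defaults to the VCF
#'   sample name if there is exactly one.
#' @param multiallelic `"split"` or `"reject"`.
#' @param keep_het admit records with heterozygous sample genotypes.
#' @return A [variant_table()].
#' @export
read_variants <- function(vcf_path, gene_model, source = NULL,
                          multiallelic = c("split", "reject"),
                          keep_het = FALSE) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_table(gene_model = gene_model, source = source %||% "strain"))
  }
  if (is.null(source)) {
    smp <- colnames(vcf@gt)[-1]
    source <- if (length(smp) == 1) smp else "strain"
  }
  gt <- if (!is.null(vcf@gt) && ncol(vcf@gt) >= 2) {
    sub(":.*$", "", vcf@gt[, 2])
  } else rep(NA_character_, nrow(fix))

  pos <- integer(0); ref <- character(0); alt <- character(0)
  n_out <- 0L; n_het <- 0L
  locus_len <- nchar(gene_model$sequence)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1 && multiallelic == "reject") {
      stop("multi-allelic record at position ", fix$POS[i])
    }
    g <- gt[i]
    if (!is.na(g)) {
      a <- strsplit(g, "[/|]")[[1]]
      if (length(unique(a[a != "."])) > 1) {
        if (!keep_het) { n_het <- n_het + 1L; next }
        warning("keeping heterozygous (non-fixed) record at position ",
                fix$POS[i])
      }
    }
    for (a in alts) {
      if (grepl("[^ACGTacgt]", a)) {
        stop("symbolic ALT allele '", a, "' at position ", fix$POS[i],
             " is not supported")
      }
      p <- as.integer(fix$POS[i])
      if (p < 1 || p + nchar(fix$REF[i]) - 1L > locus_len) {
        n_out <- n_out + 1L
        next
      }
      pos <- c(pos, p); ref <- c(ref, fix$REF[i]); alt <- c(alt, a)
    }
  }
  if (n_out > 0) message(n_out, " record(s) outside the locus dropped")
  if (n_het > 0) message(n_het, " non-fixed (heterozygous) record(s) excluded")
  variant_table(pos, ref, alt, gene_model = gene_model, source = source)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table [%s]: %d record(s) (%d SNP, %d INS, %d DEL)\n",
              attr(x, "source"), nrow(x), sum(x$kind == "SNP"),
              sum(x$kind == "INS"), sum(x$kind == "DEL")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
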
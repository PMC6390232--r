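#' Construct a gene model for one locus
#'
#' A gene model bundles the locus sequence with an ordered, non-overlapping
#' exon table. Coordinates are 1-based closed positions on the locus
#' sequence. Coding exons carry a frame offset (0/1/2) giving the phase of
#' their first base in the concatenated CDS, computed from the running coding
#' length; a CDS whose total length is not a multiple of 3 triggers a
#' warning because frame arithmetic downstream presumes a clean ORF.
#'
#' @param locus_id character scalar naming the locus.
#' @param sequence DNA string over A/C/G/T/N.
#' @param exons data.frame with columns `start`, `end` (1-based closed) and
#'   optionally `coding` (logical, default all `TRUE`).
#' @param cds_strand `"+"` or `"-"`: strand of the coding sequence relative
#'   to the locus sequence.
#' @return An object of class `gene_model`.
#' @seealso [read_gene_model()] for construction from FASTA + BED/GFF3.
#' @export
gene_model <- function(locus_id, sequence, exons, cds_strand = "+") {
  sequence <- toupper(sequence)
  if (!is_dna(sequence)) stop("sequence contains non-IUPAC DNA characters")
  if (!cds_strand %in% c("+", "-")) stop("cds_strand must be '+' or '-'")
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    stop("exons must have columns 'start' and 'end'")
  }
  if (is.null(exons$coding)) exons$coding <- TRUE
  exons <- exons[order(exons$start), c("start", "end", "coding")]
  rownames(exons) <- NULL
  n <- nchar(sequence)
  bad <- exons$start < 1 | exons$end > n | exons$start > exons$end
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("exon [%d, %d] outside locus '%s' (length %d)",
                 exons$start[i], exons$end[i], locus_id, n))
  }
  if (nrow(exons) > 1) {
    ov <- which(exons$start[-1] <= exons$end[-nrow(exons)])
    if (length(ov)) {
      stop(sprintf("overlapping exons: [%d, %d] and [%d, %d]",
                   exons$start[ov[1]], exons$end[ov[1]],
                   exons$start[ov[1] + 1], exons$end[ov[1] + 1]))
    }
  }
  # frame offset of each coding exon's first base in transcription order
  exons$frame <- NA_integer_
  cod <- which(exons$coding)
  ord <- if (cds_strand == "+") cod else rev(cod)
  lens <- exons$end[ord] - exons$start[ord] + 1L
  if (length(ord)) {
    exons$frame[ord] <- as.integer(cumsum(c(0L, lens[-length(lens)])) %% 3L)
    if (sum(lens) %% 3L != 0L) {
      warning(sprintf("coding length of '%s' (%d nt) is not a multiple of 3",
                      locus_id, sum(lens)))
    }
  }
  structure(
    list(locus_id = locus_id, sequence = sequence, exons = exons,
         cds_strand = cds_strand),
    class = "gene_model"
  )
}

#' Read a gene model from a FASTA record plus exon annotation
#'
#' The annotation may be BED (0-based half-open, converted on read) or GFF3
#' (1-based closed); the dialect is chosen from the file extension or forced
#' via `format`. GFF3 rows are restricted to `type %in% c("exon", "CDS")`
#' unless `feature_type` says otherwise.
#'
#' @param fasta_path FASTA file with one record, or several if `record` names
#'   the one to use.
#' @param annotation_path BED or GFF3 file of exon intervals on that record.
#' @param record optional record name when the FASTA holds several.
#' @param format `"auto"`, `"bed"` or `"gff"`.
#' @param feature_type GFF3 feature types treated as exons.
#' @param cds_strand strand of the CDS on the locus sequence.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(fasta_path, annotation_path, record = NULL,
                            format = c("auto", "bed", "gff"),
                            feature_type = c("exon", "CDS"),
                            cds_strand = "+") {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("no records in ", fasta_path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (is.null(record)) {
    if (length(seqs) > 1) {
      stop("FASTA has ", length(seqs), " records; name one via `record`")
    }
    idx <- 1L
  } else {
    idx <- match(record, nms)
    if (is.na(idx)) stop("record '", record, "' not found in ", fasta_path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)$", annotation_path, ignore.case = TRUE))
      "gff" else "bed"
  }
  gr <- if (format == "bed") {
    rtracklayer::import(annotation_path, format = "BED")
  } else {
    g <- rtracklayer::import(annotation_path, format = "GFF")
    if (!is.null(g$type)) g[as.character(g$type) %in% feature_type] else g
  }
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == nms[idx]]
  if (length(gr) == 0) stop("no exon intervals for record '", nms[idx], "'")
  exons <- data.frame(start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr))
  gene_model(nms[idx], as.character(seqs[[idx]]), exons,
             cds_strand = cds_strand)
}

#' @export
print.gene_model <- function(x, ...) {
  ncod <- sum(x$exons$coding)
  cat(sprintf("gene_model '%s': %d nt, %d exons (%d coding), CDS strand %s\n",
              x$locus_id, nchar(x$sequence), nrow(x$exons), ncod,
              x$cds_strand))
  invisible(x)
}

# total coding length, in nt
cds_length <- function(gm) {
  with(gm$exons[gm$exons$coding, ], sum(end - start + 1L))
}
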
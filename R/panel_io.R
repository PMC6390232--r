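# Plain-text dialects for the tables the toolkit exchanges: N2 panels,
# fragment peak tables and clone FASTA.  All TSV, no quoting.

#' Read / write an N2 panel TSV
#'
#' Layout: columns `id`, `phenotype`, then one column per marker with
#' header `marker@chr:pos` (pos in cM). Genotype codes are `A`
#' (homozygous recurrent), `H` (heterozygous) and `-` (missing).
#'
#' @param path file path.
#' @param panel an [n2_panel()] (for writing).
#' @return [read_panel()] returns an [n2_panel()].
#' @export
read_panel <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "phenotype") %in% names(tab))) {
    stop("panel file must have 'id' and 'phenotype' columns")
  }
  mcols <- setdiff(names(tab), c("id", "phenotype"))
  m <- regmatches(mcols, regexec("^(.*)@([^@:]+):([-0-9.eE+]+)$", mcols))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed marker header: ", mcols[which(bad)[1]])
  markers <- data.frame(
    marker = vapply(m, `[`, "", 2),
    chr = vapply(m, `[`, "", 3),
    pos = as.numeric(vapply(m, `[`, "", 4)),
    stringsAsFactors = FALSE)
  geno <- as.matrix(tab[, mcols, drop = FALSE])
  code <- matrix(NA_real_, nrow(geno), ncol(geno))
  code[geno == "A"] <- 0
  code[geno == "H"] <- 1
  if (any(!geno %in% c("A", "H", "-"))) {
    stop("genotype codes must be A, H or -")
  }
  n2_panel(markers, code, as.integer(tab$phenotype), ids = tab$id)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  mk <- panel$markers
  code <- matrix("-", nrow(panel$geno), ncol(panel$geno))
  code[!is.na(panel$geno) & panel$geno == 0] <- "A"
  code[!is.na(panel$geno) & panel$geno == 1] <- "H"
  out <- data.frame(id = panel$ids, phenotype = panel$phenotype,
                    code, check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- sprintf("%s@%s:%g", mk$marker, mk$chr, mk$pos)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write fragment-analysis peak tables
#'
#' TSV with columns `sample_id`, `assay_id`, `size` (bp, fractional
#' allowed), `height`.
#'
#' @param path file path.
#' @param peaks data.frame of peaks (for writing).
#' @export
read_peaks <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "size", "height")
  if (!all(need %in% names(tab))) {
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$size <= 0) || any(tab$height <= 0)) {
    stop("peak sizes and heights must be positive")
  }
  tab
}

#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write clone reads as FASTA
#'
#' Headers follow `sample_id|assay_id|clone_n`.
#'
#' @param path file path.
#' @param clones named character vector of clone sequences (for writing).
#' @return [read_clones()] returns a data.frame with columns `sample_id`,
#'   `assay_id`, `clone`, `sequence`.
#' @export
read_clones <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) {
    stop("clone header not in sample_id|assay_id|clone_n form: ",
         names(ss)[which(bad)[1]])
  }
  data.frame(sample_id = vapply(parts, `[`, "", 1),
             assay_id = vapply(parts, `[`, "", 2),
             clone = vapply(parts, `[`, "", 3),
             sequence = as.character(ss), stringsAsFactors = FALSE)
}

#' @rdname read_clones
#' @export
write_clones <- function(clones, path) {
  ss <- Biostrings::DNAStringSet(unname(clones))
  names(ss) <- names(clones)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
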
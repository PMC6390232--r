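#' Predict per-allele amplicon lengths for a fluorescent PCR assay
#'
#' Locates the forward primer on the plus strand and the reverse primer on
#' the minus strand of each haplotype. Each primer must match exactly once
#' per haplotype; anything else (absent, multi-mapping, or a strain SNP
#' under the primer making it allele-restricted) is an error naming the
#' primer, because sizing calls are meaningless without a unique product.
#'
#' @param forward_primer,reverse_primer primer sequences 5'->3' (the
#'   reverse primer as ordered, i.e. the reverse complement of the plus
#'   strand).
#' @param target_hap,other_hap the two [build_haplotype()] alleles.
#' @param assay_id label for the amplicon.
#' @return An object of class `amplicon_assay`: per-allele expected product
#'   lengths (inclusive of both primers) and product spans on each
#'   haplotype.
#' @export
predict_amplicons <- function(forward_primer, reverse_primer,
                              target_hap, other_hap, assay_id = "assay1") {
  fwd <- toupper(forward_primer)
  rev_plus <- revcomp(toupper(reverse_primer))
  locate <- function(hap, primer, name) {
    hits <- find_all(hap$sequence, primer)
    rc_hits <- find_all(hap$sequence, revcomp(primer))
    n <- length(hits) + length(rc_hits)
    if (length(hits) != 1 || n != 1) {
      stop(sprintf("primer '%s' (%s) matches %d time(s) on haplotype '%s'; need exactly one plus-strand match",
                   name, primer, n, hap$strain))
    }
    hits
  }
  span_on <- function(hap) {
    fs <- locate(hap, fwd, "forward")
    rs <- locate(hap, rev_plus, "reverse")
    if (rs <= fs) stop("reverse primer site is not downstream of forward primer")
    c(start = fs, end = rs + nchar(rev_plus) - 1L)
  }
  spans <- list(target = span_on(target_hap), other = span_on(other_hap))
  lens <- vapply(spans, function(s) unname(s["end"] - s["start"] + 1L), 0L)
  structure(list(
    assay_id = assay_id, forward_primer = fwd,
    reverse_primer = toupper(reverse_primer),
    expected_length = c(target = unname(lens["target"]),
                        non_target = unname(lens["other"])),
    span = list(target = spans$target, non_target = spans$other),
    strains = c(target = target_hap$strain, non_target = other_hap$strain)),
    class = "amplicon_assay")
}

find_all <- function(sequence, pattern) {
  m <- gregexpr(pattern, sequence, fixed = TRUE)[[1]]
  m[m > 0]
}

#' @export
print.amplicon_assay <- function(x, ...) {
  cat(sprintf("amplicon_assay '%s': expected %d bp (%s) / %d bp (%s)\n",
              x$assay_id, x$expected_length["target"], x$strains["target"],
              x$expected_length["non_target"], x$strains["non_target"]))
  invisible(x)
}

#' Call founder genotypes from fragment-analysis peak tables
#'
#' Emulates sizing-based indel screening of CRISPR founders: capillary
#' electrophoresis peaks are compared with the per-allele expected product
#' lengths. Within each sample/assay, peaks below `min_rel_height` of the
#' tallest peak are discarded as noise. Each retained peak is assigned to
#' the allele with the nearest expected length; a deviation within
#' `tolerance_bp` is a wild-type product, anything larger is an indel of
#' net size `round(observed - expected)`. When the two alleles' expected
#' lengths differ by less than `2 * tolerance_bp` they cannot be resolved
#' and the allele of origin is `ambiguous`. A sample with two resolvable
#' alleles but fewer than two retained peaks yields calls flagged
#' `low_confidence` (allele dropout cannot be excluded).
#'
#' @param peaks data.frame with columns `sample_id`, `assay_id`, `size`
#'   (bp, may be fractional), `height`.
#' @param assay an [predict_amplicons()] result.
#' @param tolerance_bp sizing tolerance in bp (default 1).
#' @param min_rel_height minimum peak height relative to the tallest peak
#'   of the sample/assay (default 0.10).
#' @return data.frame of genotype calls with columns `sample_id`,
#'   `assay_id`, `allele_of_origin`, `call` (`wild_type`/`indel`/`no_call`),
#'   `indel_size`, `frame_class`, `evidence`, `low_confidence`. Frame class
#'   here is length-based only (`frameshift` when the net size is not a
#'   multiple of 3, else `in_frame`); sequence-aware classification is done
#'   by [classify_frame()] on clone calls.
#' @export
call_fragment_genotype <- function(peaks, assay, tolerance_bp = 1.0,
                                   min_rel_height = 0.10) {
  stopifnot(tolerance_bp >= 0)
  peaks <- peaks[peaks$assay_id == assay$assay_id, , drop = FALSE]
  exp_len <- assay$expected_length
  resolvable <- abs(exp_len["target"] - exp_len["non_target"]) >=
    2 * tolerance_bp
  out <- list()
  for (sid in unique(peaks$sample_id)) {
    pk <- peaks[peaks$sample_id == sid, , drop = FALSE]
    pk <- pk[pk$height >= min_rel_height * max(pk$height), , drop = FALSE]
    if (nrow(pk) == 0) {
      out[[length(out) + 1L]] <- call_row(sid, assay$assay_id, "ambiguous",
                                          "no_call", NA_integer_, "fragment",
                                          TRUE)
      next
    }
    low_conf <- resolvable && nrow(pk) < 2
    for (i in seq_len(nrow(pk))) {
      dev <- pk$size[i] - exp_len
      j <- which.min(abs(dev))
      allele <- if (!resolvable) "ambiguous" else names(exp_len)[j]
      if (abs(dev[j]) <= tolerance_bp) {
        out[[length(out) + 1L]] <- call_row(sid, assay$assay_id, allele,
                                            "wild_type", NA_integer_,
                                            "fragment", low_conf)
      } else {
        out[[length(out) + 1L]] <- call_row(sid, assay$assay_id, allele,
                                            "indel",
                                            as.integer(round(dev[j])),
                                            "fragment", low_conf)
      }
    }
  }
  do.call(rbind, out)
}

call_row <- function(sample_id, assay_id, allele, call, indel_size,
                     evidence, low_confidence, indel_pos = NA_integer_,
                     inserted = NA_character_) {
  frame_class <- if (call != "indel") {
    if (call == "wild_type") "wild_type" else NA_character_
  } else if (indel_size %% 3L != 0L) "frameshift" else "in_frame"
  data.frame(sample_id = sample_id, assay_id = assay_id,
             allele_of_origin = allele, call = call,
             indel_size = indel_size, indel_pos = indel_pos,
             inserted = inserted, frame_class = frame_class,
             evidence = evidence, low_confidence = low_confidence,
             stringsAsFactors = FALSE)
}

#' Assign a TA-clone Sanger read to its allele of origin and call its indel
#'
#' The clone is aligned (global on the read, local on the subject; affine
#' gap penalties with opening much larger than extension, so one contiguous
#' indel is preferred over scattered gaps) against both alleles. The allele
#' of origin is decided by majority vote over the diagnostic inter-strain
#' variant positions the read covers; a 0:0 or tied vote is `ambiguous`.
#' The indel is then extracted from the alignment against the assigned
#' allele, and only indels within `cut_window` bp of a provided cut site
#' are attributed to editing (more distant gaps are natural strain indels
#' or artifacts and leave the call wild-type, flagged).
#'
#' @param clone_read DNA string of the clone insert.
#' @param target_hap,other_hap the two alleles.
#' @param cut_sites integer positions (`cut_after` on the target haplotype)
#'   of the designed cuts; projected onto the other allele internally.
#' @param assay optional [predict_amplicons()] result restricting the
#'   alignment subject to the amplicon (strongly recommended: faster and
#'   more robust than aligning against the whole locus).
#' @param cut_window attribution window around a cut site, bp (default 10).
#' @param min_identity reject the clone as an artifact below this aligned
#'   identity (default 0.9).
#' @param sample_id,assay_id labels copied into the call.
#' @return one-row data.frame in the layout of [call_fragment_genotype()],
#'   with `evidence = "clone_sequence"`; `indel_pos` is the position on the
#'   assigned allele's haplotype.
#' @export
assign_clone <- function(clone_read, target_hap, other_hap, cut_sites,
                         assay = NULL, cut_window = 10, min_identity = 0.9,
                         sample_id = "sample", assay_id = "assay1") {
  clone_read <- toupper(clone_read)
  subj <- function(hap, which_allele) {
    if (is.null(assay)) {
      list(seq = hap$sequence, offset = 0L)
    } else {
      sp <- assay$span[[which_allele]]
      list(seq = substr(hap$sequence, sp["start"], sp["end"]),
           offset = sp["start"] - 1L)
    }
  }
  st <- subj(target_hap, "target")
  so <- subj(other_hap, "non_target")
  al_t <- align_clone(clone_read, st$seq)
  al_o <- align_clone(clone_read, so$seq)

  # diagnostic positions: SNPs distinguishing the two alleles, on target-
  # haplotype coordinates (indel footprints are not used for the vote)
  snp <- target_hap$variants[target_hap$variants$kind == "SNP", , drop = FALSE]
  diag_t <- target_hap$ref2hap[snp$pos]
  diag_o <- other_hap$ref2hap[snp$pos]
  vote_t <- count_matching_bases(al_t, diag_t - st$offset,
                                 seq_chars(target_hap$sequence)[diag_t])
  vote_o <- count_matching_bases(al_o, diag_o - so$offset,
                                 seq_chars(other_hap$sequence)[diag_o])
  if (vote_t$covered + vote_o$covered == 0 ||
      vote_t$matches == vote_o$matches) {
    return(call_row(sample_id, assay_id, "ambiguous", "no_call",
                    NA_integer_, "clone_sequence", TRUE))
  }
  to_target <- vote_t$matches > vote_o$matches
  al <- if (to_target) al_t else al_o
  offset <- if (to_target) st$offset else so$offset
  allele <- if (to_target) "target" else "non_target"
  if (al$identity < min_identity) {
    return(call_row(sample_id, assay_id, allele, "no_call", NA_integer_,
                    "clone_sequence", TRUE))
  }
  cuts <- if (to_target) cut_sites else
    project_positions(target_hap, other_hap, cut_sites)
  cuts <- cuts[!is.na(cuts)] - offset
  near_cut <- function(pos, len) {
    any(vapply(cuts, function(cc)
      pos - cut_window <= cc + 1 && pos + max(len, 1) - 1 >= cc - cut_window + 1,
      TRUE))
  }
  ind <- al$indels
  if (nrow(ind)) ind <- ind[vapply(seq_len(nrow(ind)), function(i)
    near_cut(ind$subject_pos[i], abs(ind$size[i])), TRUE), , drop = FALSE]
  if (nrow(ind) == 0) {
    return(call_row(sample_id, assay_id, allele, "wild_type", NA_integer_,
                    "clone_sequence", FALSE))
  }
  net <- sum(ind$size)
  if (net == 0L) net <- ind$size[1]  # balanced complex edit: report first gap
  inserted <- paste(ind$inserted[ind$size > 0], collapse = "")
  call_row(sample_id, assay_id, allele, "indel", as.integer(net),
           "clone_sequence", FALSE,
           indel_pos = as.integer(ind$subject_pos[1] + offset),
           inserted = if (nzchar(inserted)) inserted else NA_character_)
}

.askit_cache <- new.env(parent = emptyenv())

clone_submat <- function() {
  if (is.null(.askit_cache$submat)) {
    .askit_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE)
  }
  .askit_cache$submat
}

# Global-local affine alignment of a clone against a subject window.
# Returns gapped strings, subject offset, identity, and an indel table with
# subject coordinates (position = first subject base affected by a
# deletion, or the anchor base preceding an insertion).  A read identical
# to the subject short-circuits without aligning.
align_clone <- function(read, subject) {
  if (read == subject) {
    p <- seq_chars(read)
    return(list(pattern = p, subject = p, s_start = 1L, identity = 1,
                indels = empty_indels()))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = clone_submat(),
    gapOpening = 12, gapExtension = 0.5)
  p <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  s_start <- Biostrings::start(Biostrings::subject(al))
  gap_p <- p == "-"
  gap_s <- s == "-"
  # subject coordinate of each column (gap columns inherit the previous base)
  scoord <- cumsum(!gap_s) + s_start - 1L
  aligned <- !gap_p & !gap_s
  identity <- if (any(aligned)) mean(p[aligned] == s[aligned]) else 0
  runs <- rle(ifelse(gap_s, "I", ifelse(gap_p, "D", "M")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  indels <- empty_indels()
  for (j in which(runs$values != "M")) {
    if (runs$values[j] == "I") {
      indels <- rbind(indels, data.frame(
        subject_pos = scoord[starts[j]], size = runs$lengths[j],
        inserted = chars_seq(p[starts[j]:ends[j]]), stringsAsFactors = FALSE))
    } else {
      indels <- rbind(indels, data.frame(
        subject_pos = scoord[starts[j]], size = -runs$lengths[j],
        inserted = NA_character_, stringsAsFactors = FALSE))
    }
  }
  list(pattern = p, subject = s, s_start = s_start, identity = identity,
       indels = indels)
}

empty_indels <- function() {
  data.frame(subject_pos = integer(0), size = integer(0),
             inserted = character(0), stringsAsFactors = FALSE)
}

# How many of the diagnostic subject positions covered by the alignment
# carry the subject's (allele's) base in the read.
count_matching_bases <- function(al, subject_positions, expected_bases) {
  keep <- !is.na(subject_positions)
  subject_positions <- subject_positions[keep]
  if (!length(subject_positions)) return(list(covered = 0L, matches = 0L))
  gap_s <- al$subject == "-"
  base_cols <- which(!gap_s)
  idx <- subject_positions - al$s_start + 1L
  ok <- idx >= 1L & idx <= length(base_cols)
  cols <- base_cols[idx[ok]]
  cols <- cols[al$pattern[cols] != "-"]
  list(covered = length(cols),
       matches = sum(al$pattern[cols] == al$subject[cols]))
}

#' Classify the reading-frame consequence of an indel
#'
#' Net sizes that are not a multiple of 3 are frameshifts outright. For
#' in-frame sizes with sequence context available (clone calls), the edited
#' CDS is reconstructed and translated: a stop codon appearing before 50%
#' of the protein length is a `premature_stop`; otherwise `in_frame`.
#' Indels entirely outside coding exons are `non_coding` (wild-type
#' equivalent for frame purposes). ORF loss = `frameshift` or
#' `premature_stop`.
#'
#' @param call a one-row genotype call (see [call_fragment_genotype()] /
#'   [assign_clone()]).
#' @param gene_model the reference [gene_model()].
#' @param haplotype the allele the call's `indel_pos` refers to; needed for
#'   sequence-aware classification, otherwise length-only rules are used.
#' @param stop_fraction premature-stop cutoff as a fraction of the intact
#'   protein length (default 0.5).
#' @return character scalar frame class.
#' @export
classify_frame <- function(call, gene_model, haplotype = NULL,
                           stop_fraction = 0.5) {
  if (call$call != "indel") return("wild_type")
  size <- call$indel_size
  if (!is.null(haplotype) && !is.na(call$indel_pos)) {
    # coding-exon overlap of the edit footprint, via haplotype coords
    fp <- call$indel_pos:(call$indel_pos + max(abs(size) - 1L, 0L))
    refp <- haplotype$hap2ref[fp]
    refp <- refp[!is.na(refp)]
    ex <- gene_model$exons[gene_model$exons$coding, , drop = FALSE]
    in_cds <- length(refp) > 0 &&
      any(ex$start <= max(refp) & ex$end >= min(refp))
    if (!in_cds && size < 0) return("non_coding")
    if (!in_cds && size > 0) {
      # insertion: footprint is the anchor; test the anchor itself
      rp <- haplotype$hap2ref[call$indel_pos]
      in_cds <- !is.na(rp) && any(ex$start <= rp & ex$end >= rp)
      if (!in_cds) return("non_coding")
    }
  }
  if (abs(size) %% 3L != 0L) return("frameshift")
  if (is.null(haplotype) || is.na(call$indel_pos)) return("in_frame")
  prot_intact <- translate_cds(haplotype$sequence, haplotype, gene_model)
  edited <- apply_indel(haplotype$sequence, call$indel_pos, size,
                        call$inserted)
  prot_edit <- translate_cds(edited$sequence, haplotype, gene_model,
                             shift_from = edited$shift_from,
                             shift_by = edited$shift_by)
  stop_at <- regexpr("*", prot_edit, fixed = TRUE)
  if (stop_at > 0 && stop_at < stop_fraction * nchar(prot_intact)) {
    return("premature_stop")
  }
  "in_frame"
}

# apply one indel to a haplotype sequence; returns the edited sequence plus
# the coordinate shift rule (positions >= shift_from move by shift_by)
apply_indel <- function(sequence, pos, size, inserted = NA) {
  if (size > 0) {
    ins <- if (!is.na(inserted) && nchar(inserted) == size) inserted else
      chars_seq(rep("A", size))
    list(sequence = paste0(substr(sequence, 1, pos), ins,
                           substr(sequence, pos + 1, nchar(sequence))),
         shift_from = pos + 1L, shift_by = size)
  } else {
    k <- -size
    list(sequence = paste0(substr(sequence, 1, pos - 1),
                           substr(sequence, pos + k, nchar(sequence))),
         shift_from = pos + k, shift_by = size)
  }
}

# translate the coding sequence of a (possibly edited) haplotype; exon
# coordinates come from the gene model mapped through the haplotype, with
# an optional downstream shift from an applied indel
translate_cds <- function(sequence, haplotype, gene_model,
                          shift_from = NULL, shift_by = 0L) {
  ex <- gene_model$exons[gene_model$exons$coding, , drop = FALSE]
  pieces <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    span <- haplotype$ref2hap[ex$start[i]:ex$end[i]]
    span <- span[!is.na(span)]
    if (!length(span)) { pieces[i] <- ""; next }
    lo <- min(span); hi <- max(span)
    if (!is.null(shift_from)) {
      if (lo >= shift_from) lo <- lo + shift_by
      if (hi >= shift_from) hi <- hi + shift_by
    }
    lo <- max(1L, lo); hi <- min(nchar(sequence), hi)
    pieces[i] <- substr(sequence, lo, hi)
  }
  cds <- paste(pieces, collapse = "")
  if (gene_model$cds_strand == "-") cds <- revcomp(cds)
  cds <- substr(cds, 1, 3 * (nchar(cds) %/% 3))
  if (nchar(cds) < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

#' Summarize founder editing outcomes
#'
#' An animal is an ORF-loss carrier when at least one of its calls is a
#' target-allele indel classified `frameshift` or `premature_stop`; it is
#' mistargeted when at least one call is a non-target-allele indel (counted
#' per animal, not per clone). Efficiency is the percentage of newborns
#' carrying a target-allele ORF-loss.
#'
#' @param calls data.frame of genotype calls (fragment and/or clone rows).
#' @param n_newborns total number of newborns screened; must be at least
#'   the number of distinct samples in `calls`.
#' @return An object of class `founder_summary` with fields `n_newborns`,
#'   `n_indel_carriers`, `n_orf_loss`, `n_mistargeted`,
#'   `efficiency_percent`.
#' @examples
#' calls <- do.call(rbind, lapply(1:8, function(i)
#'   data.frame(sample_id = paste0("F", i), assay_id = "a1",
#'              allele_of_origin = "target", call = "indel",
#'              indel_size = -7L, indel_pos = NA, inserted = NA,
#'              frame_class = "frameshift", evidence = "fragment",
#'              low_confidence = FALSE)))
#' summarize_founders(calls, n_newborns = 10)  # 80% efficiency
#' @export
summarize_founders <- function(calls, n_newborns) {
  samples <- unique(calls$sample_id)
  if (n_newborns < length(samples)) {
    stop("n_newborns is smaller than the number of samples with calls")
  }
  is_indel <- calls$call == "indel"
  orf <- calls$frame_class %in% c("frameshift", "premature_stop")
  carriers <- unique(calls$sample_id[is_indel])
  orf_loss <- unique(calls$sample_id[is_indel & orf &
                                       calls$allele_of_origin == "target"])
  mistarget <- unique(calls$sample_id[is_indel &
                                        calls$allele_of_origin == "non_target"])
  structure(list(
    n_newborns = n_newborns,
    n_indel_carriers = length(carriers),
    n_orf_loss = length(orf_loss),
    n_mistargeted = length(mistarget),
    efficiency_percent = 100 * length(orf_loss) / n_newborns,
    orf_loss_samples = orf_loss, mistargeted_samples = mistarget),
    class = "founder_summary")
}

#' @export
print.founder_summary <- function(x, ...) {
  cat(sprintf(
    "founder_summary: %d newborns | %d indel carriers | %d ORF-loss (%.1f%%) | %d mistargeted\n",
    x$n_newborns, x$n_indel_carriers, x$n_orf_loss, x$efficiency_percent,
    x$n_mistargeted))
  invisible(x)
}
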
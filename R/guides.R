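#' Describe a Cas nuclease PAM requirement
#'
#' Defaults describe SpCas9: a 20-nt protospacer followed immediately (3'
#' side) by 5'-NGG-3'. Other IUPAC motifs are accepted, but only 3'-PAM
#' geometry is implemented.
#'
#' @param motif IUPAC DNA pattern for the PAM (default `"NGG"`).
#' @param guide_length protospacer length in nt (default 20).
#' @return An object of class `pam_spec`.
#' @export
pam_spec <- function(motif = "NGG", guide_length = 20L) {
  motif <- toupper(motif)
  if (nchar(motif) < 1 || !all(seq_chars(motif) %in% names(IUPAC_SETS))) {
    stop("PAM motif must be a non-empty IUPAC DNA pattern")
  }
  guide_length <- as.integer(guide_length)
  if (guide_length < 1) stop("guide_length must be positive")
  structure(list(motif = motif, guide_length = guide_length,
                 pam_side = "3prime"),
            class = "pam_spec")
}

pam_matches <- function(pam, spec) {
  ch <- seq_chars(pam)
  m <- seq_chars(spec$motif)
  length(ch) == length(m) && all(mapply(function(c, mm)
    iupac_char_match(c, mm), ch, m))
}

#' Scan a sequence for protospacer + PAM sites on both strands
#'
#' Every window `[protospacer][PAM]` matching the PAM motif is reported.
#' Site coordinates (`start`, `end`, 1-based closed) always refer to the
#' plus strand of the scanned sequence and span the full window; the
#' `protospacer` and `pam` strings are given in guide orientation (5'->3'),
#' i.e. reverse-complemented for minus-strand sites. `cut_after` is the
#' plus-strand coordinate of the base immediately 5' of the blunt Cas9 cut
#' (3 bp 5' of the PAM). Windows containing N never match.
#'
#' @param x a [build_haplotype()] object or a DNA string.
#' @param spec a [pam_spec()].
#' @param region optional `c(start, end)` restriction (on `x`'s
#'   coordinates); a region shorter than one window yields an empty result.
#' @return data.frame with columns `start`, `end`, `strand`, `protospacer`,
#'   `pam`, `pam_start`, `cut_after`, plus unset `specificity`.
#' @export
scan_protospacers <- function(x, spec = pam_spec(), region = NULL) {
  seqstr <- if (inherits(x, "haplotype")) x$sequence else toupper(x)
  chars <- seq_chars(seqstr)
  L <- length(chars)
  gl <- spec$guide_length
  ml <- nchar(spec$motif)
  lo <- 1L; hi <- L
  if (!is.null(region)) {
    lo <- max(1L, as.integer(region[1])); hi <- min(L, as.integer(region[2]))
    if (lo > hi) stop("empty region")
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protospacer = character(0),
                      pam = character(0), pam_start = integer(0),
                      cut_after = integer(0), specificity = character(0),
                      stringsAsFactors = FALSE)
  if (hi - lo + 1L < gl + ml) return(empty)

  ncum <- c(0L, cumsum(chars == "N"))
  clean <- function(s, e) s >= lo & e <= hi & (ncum[e + 1L] - ncum[s]) == 0L
  rc_many <- function(x) {
    if (!length(x)) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  # forward strand: PAM at p..p+ml-1, protospacer ends at p-1
  fw <- iupac_match_starts(chars, spec$motif)
  fw <- fw[fw - gl >= 1L]
  if (length(fw)) fw <- fw[clean(fw - gl, fw + ml - 1L)]
  fw_df <- if (!length(fw)) empty[, 1:7] else data.frame(
    start = fw - gl, end = fw + ml - 1L,
    strand = rep("+", length(fw)),
    protospacer = substring(seqstr, fw - gl, fw - 1L),
    pam = substring(seqstr, fw, fw + ml - 1L),
    pam_start = fw, cut_after = fw - 4L, stringsAsFactors = FALSE)
  # reverse strand: plus-strand image of the PAM is revcomp(motif) at
  # p..p+ml-1 with the protospacer on p+ml..p+ml+gl-1
  rv <- iupac_match_starts(chars, revcomp(spec$motif))
  rv <- rv[rv + ml + gl - 1L <= L]
  if (length(rv)) rv <- rv[clean(rv, rv + ml + gl - 1L)]
  rv_df <- if (!length(rv)) empty[, 1:7] else data.frame(
    start = rv, end = rv + ml + gl - 1L,
    strand = rep("-", length(rv)),
    protospacer = rc_many(substring(seqstr, rv + ml, rv + ml + gl - 1L)),
    pam = rc_many(substring(seqstr, rv, rv + ml - 1L)),
    pam_start = rv, cut_after = rv + ml + 2L, stringsAsFactors = FALSE)
  out <- rbind(fw_df, rv_df)
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out$specificity <- NA_character_
  out
}

#' Classify the allele specificity of a protospacer site
#'
#' Projects the site's window from the target haplotype onto the other
#' haplotype via the shared reference coordinates and compares:
#'
#' * `TARGET_ONLY_PAM` — the homologous window on the other allele fails
#'   the PAM motif: Cas9 cannot cut the other allele at this site;
#' * `PROTOSPACER_VARIANT` — PAM intact on both alleles but at least one
#'   base differs inside the protospacer;
#' * `SHARED` — the full window is identical on both alleles;
#' * `UNMAPPABLE` — the window crosses an indel or runs off the other
#'   haplotype, so no homologous window exists.
#'
#' Because degenerate motif positions (the N of NGG) match any base, a SNP
#' at such a position never confers specificity.
#'
#' @param site one row of a [scan_protospacers()] result (data.frame).
#' @param target_hap,other_hap [build_haplotype()] objects over the same
#'   reference; the site lies on `target_hap`.
#' @param spec the [pam_spec()] used for scanning.
#' @return list with `class` and `diagnostic_variants` (target-haplotype
#'   positions inside the window where the alleles differ).
#' @export
classify_specificity <- function(site, target_hap, other_hap,
                                 spec = pam_spec()) {
  classify_one(site, target_hap, other_hap, spec,
               seq_chars(target_hap$sequence), seq_chars(other_hap$sequence))
}

classify_one <- function(site, target_hap, other_hap, spec,
                         chars_t, chars_o) {
  posns <- site$start:site$end
  homol <- project_positions(target_hap, other_hap, posns)
  if (any(is.na(homol)) || any(diff(homol) != 1L)) {
    return(list(class = "UNMAPPABLE", diagnostic_variants = integer(0)))
  }
  t_chars <- chars_t[posns]
  o_chars <- chars_o[homol]
  diffs <- posns[t_chars != o_chars]
  ml <- nchar(spec$motif)
  if (site$strand == "+") {
    o_pam <- chars_seq(o_chars[(length(o_chars) - ml + 1L):length(o_chars)])
    o_proto <- chars_seq(o_chars[1:(length(o_chars) - ml)])
  } else {
    o_pam <- revcomp(chars_seq(o_chars[1:ml]))
    o_proto <- revcomp(chars_seq(o_chars[(ml + 1L):length(o_chars)]))
  }
  cls <- if (!pam_matches(o_pam, spec)) {
    "TARGET_ONLY_PAM"
  } else if (o_proto != site$protospacer) {
    "PROTOSPACER_VARIANT"
  } else {
    "SHARED"
  }
  list(class = cls, diagnostic_variants = diffs)
}

#' Classify every site in a scan against the other allele
#'
#' Vectorized wrapper over [classify_specificity()]; fills the
#' `specificity` column and adds `n_diagnostic`.
#'
#' @inheritParams classify_specificity
#' @param sites a [scan_protospacers()] result from `target_hap`.
#' @export
classify_sites <- function(sites, target_hap, other_hap, spec = pam_spec()) {
  if (nrow(sites) == 0) return(sites)
  chars_t <- seq_chars(target_hap$sequence)
  chars_o <- seq_chars(other_hap$sequence)
  cl <- character(nrow(sites)); nd <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    r <- classify_one(sites[i, ], target_hap, other_hap, spec,
                      chars_t, chars_o)
    cl[i] <- r$class
    nd[i] <- length(r$diagnostic_variants)
  }
  sites$specificity <- cl
  sites$n_diagnostic <- nd
  sites
}

#' Default guide quality rules
#'
#' @param gc_min,gc_max protospacer GC-content bounds (fractions).
#' @param forbid_homopolymer substring whose presence rejects a guide
#'   (`"TTTT"` terminates pol-III transcription); `NULL` disables.
#' @param require_coding keep only sites whose protospacer overlaps a
#'   coding exon.
#' @export
guide_rules <- function(gc_min = 0.25, gc_max = 0.75,
                        forbid_homopolymer = "TTTT",
                        require_coding = TRUE) {
  list(gc_min = gc_min, gc_max = gc_max,
       forbid_homopolymer = forbid_homopolymer,
       require_coding = require_coding)
}

#' Filter protospacer sites by quality rules
#'
#' Annotates each site with its exon (via the haplotype-to-reference map)
#' and GC content, then applies [guide_rules()]. The result keeps input
#' order; rejected sites and their reasons are attached as the
#' `"rejections"` attribute.
#'
#' @param sites a (classified) [scan_protospacers()] result.
#' @param gene_model the reference [gene_model()].
#' @param haplotype the haplotype the sites were scanned on.
#' @param rules a [guide_rules()] list.
#' @export
filter_guides <- function(sites, gene_model, haplotype,
                          rules = guide_rules()) {
  if (nrow(sites) == 0) return(sites)
  sites <- annotate_exons(sites, gene_model, haplotype)
  sites$gc <- vapply(sites$protospacer, gc_fraction, 0)
  reason <- rep(NA_character_, nrow(sites))
  low <- sites$gc < rules$gc_min
  high <- sites$gc > rules$gc_max
  reason[low] <- "GC below minimum"
  reason[high & is.na(reason)] <- "GC above maximum"
  if (!is.null(rules$forbid_homopolymer)) {
    hp <- grepl(rules$forbid_homopolymer, sites$protospacer, fixed = TRUE)
    reason[hp & is.na(reason)] <-
      paste0("contains ", rules$forbid_homopolymer)
  }
  if (isTRUE(rules$require_coding)) {
    nc <- is.na(sites$exon) | !sites$coding_exon
    reason[nc & is.na(reason)] <- "no coding-exon overlap"
  }
  keep <- is.na(reason)
  out <- sites[keep, ]
  rownames(out) <- NULL
  rej <- sites[!keep, ]
  rej$reason <- reason[!keep]
  rownames(rej) <- NULL
  attr(out, "rejections") <- rej
  out
}

# exon index (in gene-model order) of the exon each site's protospacer
# overlaps, through the haplotype coordinate map; NA when intronic
annotate_exons <- function(sites, gene_model, haplotype) {
  ex <- gene_model$exons
  exon <- rep(NA_integer_, nrow(sites))
  coding <- rep(NA, nrow(sites))
  ml <- nchar(attr(sites, "pam_motif") %||% "NGG")
  for (i in seq_len(nrow(sites))) {
    # protospacer footprint on the haplotype
    if (sites$strand[i] == "+") {
      span <- sites$start[i]:(sites$end[i] - ml)
    } else {
      span <- (sites$start[i] + ml):sites$end[i]
    }
    refp <- haplotype$hap2ref[span]
    refp <- refp[!is.na(refp)]
    if (!length(refp)) next
    hit <- which(ex$start <= max(refp) & ex$end >= min(refp))
    if (length(hit)) {
      exon[i] <- hit[1]
      coding[i] <- ex$coding[hit[1]]
    }
  }
  sites$exon <- exon
  sites$coding_exon <- coding
  sites
}

#' Select a two-guide, ORF-loss design restricted to one allele
#'
#' Default policy mirrors a two-cut knockout: among `TARGET_ONLY_PAM` sites
#' in coding exons, take the site in the earliest coding exon, then the
#' farthest-downstream qualifying site in a *different* exon, maximizing
#' the span removed if both cuts rejoin. Ties break toward the 5'-most
#' coordinate. Sites whose specificity rests only on protospacer variants
#' are excluded unless `allow_protospacer_variant = TRUE`.
#'
#' When fewer than two qualifying sites exist in two distinct exons the
#' design is reported infeasible (`feasible = FALSE`) with the best single
#' sites listed — an answer, not an error: it means this locus cannot be
#' knocked out allele-specifically with this nuclease.
#'
#' @param sites classified + filtered sites (see [filter_guides()]).
#' @param allow_protospacer_variant admit `PROTOSPACER_VARIANT` sites.
#' @return An object of class `guide_pair`.
#' @export
select_guide_pair <- function(sites, allow_protospacer_variant = FALSE) {
  ok_class <- c("TARGET_ONLY_PAM",
                if (allow_protospacer_variant) "PROTOSPACER_VARIANT")
  cand <- sites[!is.na(sites$specificity) & sites$specificity %in% ok_class &
                  !is.na(sites$exon), ]
  fail <- function(msg) {
    structure(list(feasible = FALSE, reason = msg,
                   best_singles = utils::head(cand, 5)),
              class = "guide_pair")
  }
  if (nrow(cand) < 2) {
    return(fail("fewer than 2 allele-specific sites in coding exons"))
  }
  first_exon <- min(cand$exon)
  in_first <- cand[cand$exon == first_exon, ]
  site_a <- in_first[order(in_first$start)[1], ]
  rest <- cand[cand$exon != first_exon, ]
  if (nrow(rest) == 0) {
    return(fail("no allele-specific pair: all qualifying sites in one exon"))
  }
  # farthest downstream by cut position; tie -> 5'-most start
  rest <- rest[order(-rest$cut_after, rest$start), ]
  site_b <- rest[1, ]
  del_span <- c(min(site_a$cut_after, site_b$cut_after) + 1L,
                max(site_a$cut_after, site_b$cut_after))
  structure(list(
    feasible = TRUE, site_a = site_a, site_b = site_b,
    expected_deletion_span = del_span,
    rationale = sprintf(
      "earliest coding exon (%d) paired with farthest downstream site (exon %d); expected dropout %d bp",
      site_a$exon, site_b$exon, del_span[2] - del_span[1] + 1L)),
    class = "guide_pair")
}

#' @export
print.guide_pair <- function(x, ...) {
  if (!x$feasible) {
    cat("guide_pair: INFEASIBLE -", x$reason, "\n")
    if (nrow(x$best_singles)) {
      cat("best single sites:\n")
      print.data.frame(x$best_singles[, c("start", "strand", "protospacer",
                                          "pam", "exon", "specificity")])
    }
    return(invisible(x))
  }
  cat("guide_pair (allele-specific two-cut design)\n")
  for (nm in c("site_a", "site_b")) {
    s <- x[[nm]]
    cat(sprintf("  %s: exon %d %s%d-%d (%s) %s | PAM %s | cut after %d\n",
                nm, s$exon, s$strand, s$start, s$end, s$specificity,
                s$protospacer, s$pam, s$cut_after))
  }
  cat("  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Count candidate off-target sites by Hamming distance
#'
#' Counts windows in `background` (both strands) whose PAM matches the
#' motif and whose protospacer is within `max_mismatches` mismatches of
#' `protospacer`. The on-target site itself, if present in the background,
#' is included in the count. This is a plain mismatch counter, not an
#' activity score.
#'
#' @param protospacer guide sequence, 5'->3'.
#' @param background DNA string (or haplotype) to search.
#' @param max_mismatches Hamming radius.
#' @param spec a [pam_spec()].
#' @return integer count.
#' @export
count_offtargets <- function(protospacer, background, max_mismatches = 3,
                             spec = pam_spec()) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != spec$guide_length) {
    stop("protospacer length does not match pam_spec guide_length")
  }
  sites <- scan_protospacers(background, spec)
  if (nrow(sites) == 0) return(0L)
  g <- seq_chars(protospacer)
  mm <- vapply(sites$protospacer, function(p) {
    sum(seq_chars(p) != g)
  }, 0L)
  sum(mm <= max_mismatches)
}

#' One-call allele-specific design for a locus
#'
#' Convenience pipeline: scan the target haplotype, classify every site
#' against the other allele, filter by [guide_rules()], select a pair, and
#' count locus-internal off-targets for the chosen guides on both alleles.
#'
#' @inheritParams classify_sites
#' @param gene_model reference [gene_model()].
#' @param rules a [guide_rules()] list.
#' @param spec a [pam_spec()].
#' @param max_mismatches Hamming radius for the off-target counts.
#' @param allow_protospacer_variant see [select_guide_pair()].
#' @return list with `sites` (all classified sites), `filtered`, `pair`,
#'   and `offtargets` (per selected guide, counts on both haplotypes).
#' @export
design_guides <- function(target_hap, other_hap, gene_model,
                          rules = guide_rules(), spec = pam_spec(),
                          max_mismatches = 3,
                          allow_protospacer_variant = FALSE) {
  sites <- scan_protospacers(target_hap, spec)
  sites <- classify_sites(sites, target_hap, other_hap, spec)
  filtered <- filter_guides(sites, gene_model, target_hap, rules)
  pair <- select_guide_pair(filtered, allow_protospacer_variant)
  off <- NULL
  if (pair$feasible) {
    off <- lapply(list(a = pair$site_a, b = pair$site_b), function(s) {
      c(target = count_offtargets(s$protospacer, target_hap,
                                  max_mismatches, spec),
        other = count_offtargets(s$protospacer, other_hap,
                                 max_mismatches, spec))
    })
  }
  list(sites = sites, filtered = filtered, pair = pair, offtargets = off)
}
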
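#' Simulation configuration
#'
#' One bag of knobs for the three generators, with defaults emulating the
#' study design the toolkit is built around: a ~19-exon gene locus between
#' two inbred strains diverged at about 7 SNPs/kb, with PAM-gain SNPs
#' planted in two coding exons; an N2 backcross of 559 animals segregating
#' a single fully penetrant dominant donor locus; and 10 injected founders
#' with strongly allele-restricted editing.
#'
#' @param seed integer seed; every generator restores the caller's RNG
#'   state afterwards.
#' @param locus_length locus size in bp.
#' @param n_exons number of exons (all coding by default).
#' @param snp_rate background per-bp SNP probability between the strains.
#' @param planted_pam_gain_snps list of `c(exon_index, count)` pairs: SNPs
#'   that create an NGG PAM on the donor allele where the reference fails
#'   the motif.
#' @param planted_strain_indel optional `c(position, size)` natural strain
#'   indel (negative size = deletion).
#' @param n_individuals backcross panel size.
#' @param penetrance P(phenotype | heterozygous at the causal locus).
#' @param phenocopy_rate P(phenotype | homozygous recurrent).
#' @param n_embryos founder animals simulated by [simulate_editing()].
#' @param p_edit_target,p_edit_nontarget per-allele, per-guide cutting
#'   probabilities.
#' @param indel_size_distribution data.frame with columns `size` (in
#'   `-12..6`, no 0) and `prob`; default favors small deletions.
#' @param peak_noise_sd Gaussian sizing noise on fragment peaks, bp.
#' @param n_clones TA clones sequenced per sample and amplicon.
#' @export
sim_config <- function(seed = NULL,
                       locus_length = 9000L,
                       n_exons = 19L,
                       snp_rate = 0.007,
                       planted_pam_gain_snps = list(c(5L, 1L), c(12L, 1L)),
                       planted_strain_indel = NULL,
                       n_individuals = 559L,
                       penetrance = 1.0,
                       phenocopy_rate = 0.0,
                       n_embryos = 10L,
                       p_edit_target = 0.8,
                       p_edit_nontarget = 0.0,
                       indel_size_distribution = NULL,
                       peak_noise_sd = 0.3,
                       n_clones = 10L) {
  if (is.null(indel_size_distribution)) {
    sizes <- c(-10:-1, 1:3)
    w <- c(0.3^(abs(-10:-1) / 3), 0.05, 0.03, 0.02)
    indel_size_distribution <- data.frame(size = sizes, prob = w / sum(w))
  }
  stopifnot(all(indel_size_distribution$size != 0),
            all(indel_size_distribution$size >= -12),
            all(indel_size_distribution$size <= 6),
            penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            p_edit_target >= 0, p_edit_target <= 1,
            p_edit_nontarget >= 0, p_edit_nontarget <= 1,
            snp_rate >= 0)
  cfg <- list(seed = seed, locus_length = as.integer(locus_length),
              n_exons = as.integer(n_exons), snp_rate = snp_rate,
              planted_pam_gain_snps = planted_pam_gain_snps,
              planted_strain_indel = planted_strain_indel,
              n_individuals = as.integer(n_individuals),
              penetrance = penetrance, phenocopy_rate = phenocopy_rate,
              n_embryos = as.integer(n_embryos),
              p_edit_target = p_edit_target,
              p_edit_nontarget = p_edit_nontarget,
              indel_size_distribution = indel_size_distribution,
              peak_noise_sd = peak_noise_sd,
              n_clones = as.integer(n_clones))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-strain gene locus with planted PAM-gain SNPs
#'
#' Generates a reference locus and a donor-strain variant table in which
#' each planted SNP provably creates a 5'-NGG-3' PAM on the donor
#' haplotype at a position where the reference fails the motif, inside the
#' requested coding exon, with a protospacer that passes the default
#' [guide_rules()]. Background SNPs fall outside the planted windows so
#' the truth labels stay exact. Optionally plants a natural strain indel.
#'
#' @param config a [sim_config()].
#' @return list with `gene_model`, `variants`, `truth` (one row per
#'   planted site: exon, plus-strand PAM position on the donor haplotype,
#'   protospacer, cut position), and the two built haplotypes `target_hap`
#'   (donor) and `other_hap` (reference strain).
#' @export
make_strain_pair <- function(config = sim_config()) {
  with_local_seed(config$seed, make_strain_pair_impl(config))
}

make_strain_pair_impl <- function(config) {
  L <- config$locus_length
  nex <- config$n_exons
  chars <- seq_chars(random_dna(L))

  # exon scaffold: exon lengths 90-180 bp, introns sized to fill
  ex_len <- sample(90:180, nex, replace = TRUE)
  total_cds <- sum(ex_len)
  ex_len[nex] <- ex_len[nex] - (total_cds %% 3L)  # clean ORF
  gap <- (L - sum(ex_len)) %/% (nex + 1L)
  if (gap < 40) stop("locus too short for ", nex, " exons")
  starts <- integer(nex)
  pos <- gap
  for (i in seq_len(nex)) {
    starts[i] <- pos + 1L
    pos <- pos + ex_len[i] + gap
  }
  exons <- data.frame(start = starts, end = starts + ex_len - 1L,
                      coding = TRUE)
  # ATG at CDS start, avoid premature stops later by construction? a random
  # ORF will contain stops; frame classification only compares edited vs
  # intact protein, so in-frame stops in the reference are harmless for the
  # generator's purposes, but a clean start helps sanity checks
  chars[starts[1]:(starts[1] + 2L)] <- c("A", "T", "G")

  masked <- rep(FALSE, L)
  pos_v <- integer(0); ref_v <- character(0); alt_v <- character(0)
  truth <- list()
  for (spec_i in config$planted_pam_gain_snps) {
    ei <- spec_i[1]; cnt <- spec_i[2]
    if (ei > nex) stop("planted exon index ", ei, " exceeds n_exons")
    for (k in seq_len(cnt)) {
      lo <- exons$start[ei] + 24L   # protospacer mostly inside the exon
      hi <- exons$end[ei] - 2L
      cand <- setdiff(lo:hi, which(masked))
      cand <- cand[cand - 20L >= 1L]
      if (!length(cand)) {
        stop("cannot place a PAM-gain SNP in exon ", ei, " (too short)")
      }
      p <- sample(cand, 1L)
      # rewrite the protospacer to pass default quality rules
      proto <- repeat_until(function() random_dna(20, gc = 0.5), function(s) {
        gc <- gc_fraction(s)
        gc >= 0.3 && gc <= 0.7 && !grepl("TTTT", s, fixed = TRUE)
      })
      chars[(p - 20L):(p - 1L)] <- seq_chars(proto)
      chars[p] <- sample(c("A", "C", "G", "T"), 1L)
      chars[p + 1L] <- "G"
      chars[p + 2L] <- sample(c("A", "C", "T"), 1L)  # reference fails NGG
      if (p + 3L <= L) {
        # no G right after the planted PAM, so the SNP cannot create a
        # second overlapping donor-only site one base downstream
        chars[p + 3L] <- sample(c("A", "C", "T"), 1L)
      }
      pos_v <- c(pos_v, p + 2L)
      ref_v <- c(ref_v, chars[p + 2L])
      alt_v <- c(alt_v, "G")
      masked[max(1L, p - 24L):min(L, p + 6L)] <- TRUE
      truth[[length(truth) + 1L]] <- data.frame(
        exon = ei, pam_start_ref = p, protospacer = proto,
        stringsAsFactors = FALSE)
    }
  }
  # optional natural strain indel
  if (!is.null(config$planted_strain_indel)) {
    ip <- config$planted_strain_indel[1]
    isz <- config$planted_strain_indel[2]
    foot <- ip:(ip + max(-isz, 0L))
    if (any(masked[foot])) stop("planted indel overlaps a planted PAM site")
    if (isz < 0) {
      pos_v <- c(pos_v, ip)
      ref_v <- c(ref_v, chars_seq(chars[ip:(ip - isz)]))
      alt_v <- c(alt_v, chars[ip])
    } else {
      pos_v <- c(pos_v, ip)
      ref_v <- c(ref_v, chars[ip])
      alt_v <- c(alt_v, paste0(chars[ip], random_dna(isz)))
    }
    masked[foot] <- TRUE
  }
  # background SNPs
  if (config$snp_rate > 0) {
    hits <- which(runif(L) < config$snp_rate & !masked)
    hits <- setdiff(hits, pos_v)
    for (p in hits) {
      pos_v <- c(pos_v, p)
      ref_v <- c(ref_v, chars[p])
      alt_v <- c(alt_v, sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L))
    }
  }
  gm <- gene_model("sim_locus", chars_seq(chars), exons)
  vt <- variant_table(pos_v, ref_v, alt_v, gene_model = gm, source = "donor")
  target_hap <- build_haplotype(gm, vt, strain = "donor")
  other_hap <- build_haplotype(gm, NULL, strain = "recurrent")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(exon = integer(0), pam_start_ref = integer(0),
               protospacer = character(0))
  if (nrow(truth)) {
    truth$pam_start_hap <- target_hap$ref2hap[truth$pam_start_ref]
    truth$cut_after_hap <- truth$pam_start_hap - 4L
  }
  list(gene_model = gm, variants = vt, truth = truth,
       target_hap = target_hap, other_hap = other_hap)
}

repeat_until <- function(gen, ok, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- gen()
    if (ok(x)) return(x)
  }
  stop("rejection sampling failed")
}

#' Default genome-wide marker map for backcross simulations
#'
#' 19 autosomes with equally spaced markers, emulating a genome-wide STR
#' panel (default about 120 markers at roughly 12 cM spacing).
#'
#' @param n_chr number of autosomes.
#' @param markers_per_chr markers per chromosome.
#' @param chr_length_cM chromosome length.
#' @export
make_marker_map <- function(n_chr = 19, markers_per_chr = 6,
                            chr_length_cM = 60) {
  do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    pos <- seq(0, chr_length_cM, length.out = markers_per_chr)
    data.frame(marker = sprintf("D%dM%d", ch, seq_along(pos)),
               chr = as.character(ch), pos = pos,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate an N2 backcross panel with one dominant causal locus
#'
#' Each individual receives one recombinant F1 gamete per chromosome:
#' the allele at the first locus is donor or recurrent with probability
#' 1/2 and switches between adjacent loci with the Haldane recombination
#' fraction of their map distance (no interference). The phenotype is
#' Bernoulli(`penetrance`) for carriers of the donor allele at the causal
#' position and Bernoulli(`phenocopy_rate`) otherwise.
#'
#' @param map_truth marker map data.frame (`marker`, `chr`, `pos` in cM),
#'   e.g. from [make_marker_map()].
#' @param causal list with `chr` and `pos`; the position need not coincide
#'   with a marker but must lie on a mapped chromosome.
#' @param config a [sim_config()]; uses `n_individuals`, `penetrance`,
#'   `phenocopy_rate`, `seed`.
#' @return An [n2_panel()] with attribute `"truth"` holding the causal
#'   specification and the simulated causal genotypes.
#' @export
simulate_backcross <- function(map_truth, causal, config = sim_config()) {
  with_local_seed(config$seed,
                  simulate_backcross_impl(map_truth, causal, config))
}

simulate_backcross_impl <- function(map_truth, causal, config) {
  n <- config$n_individuals
  if (!causal$chr %in% map_truth$chr) {
    stop("causal position is on an unmapped chromosome")
  }
  map_truth <- map_truth[order(match(map_truth$chr, unique(map_truth$chr)),
                               map_truth$pos), ]
  geno <- NULL
  causal_geno <- NULL
  for (ch in unique(map_truth$chr)) {
    mi <- which(map_truth$chr == ch)
    pos <- map_truth$pos[mi]
    is_causal <- ch == causal$chr
    loci <- if (is_causal) sort(unique(c(pos, causal$pos))) else pos
    K <- length(loci)
    g <- matrix(0L, n, K)
    g[, 1] <- rbinom(n, 1, 0.5)
    if (K > 1) {
      for (k in 2:K) {
        r <- haldane_r(loci[k] - loci[k - 1])
        sw <- rbinom(n, 1, r)
        g[, k] <- ifelse(sw == 1L, 1L - g[, k - 1], g[, k - 1])
      }
    }
    if (is_causal) {
      causal_geno <- g[, match(causal$pos, loci)]
    }
    geno <- cbind(geno, g[, match(pos, loci), drop = FALSE])
  }
  p_pheno <- ifelse(causal_geno == 1L, config$penetrance,
                    config$phenocopy_rate)
  phenotype <- rbinom(n, 1, p_pheno)
  panel <- n2_panel(map_truth, geno, phenotype)
  attr(panel, "truth") <- list(causal = causal, causal_geno = causal_geno)
  panel
}

#' Simulate allele-restricted CRISPR editing of founder embryos
#'
#' For each embryo, each guide cuts the donor allele with probability
#' `p_edit_target` and the other allele with `p_edit_nontarget`; a cut
#' receives one indel drawn from the configured size distribution at the
#' cut site (deletions span the blunt cut 3 bp 5' of the PAM, insertions
#' open at it). Fragment peaks are the per-allele amplicon lengths shifted
#' by the indel plus Gaussian sizing noise, and TA clones are sampled from
#' the two alleles with a fair coin. Each embryo is scored as a single
#' germline genotype (no mosaicism).
#'
#' @param target_hap,other_hap the two alleles (donor first).
#' @param guide_pair a feasible [select_guide_pair()] result; one amplicon
#'   assay is designed per guide.
#' @param config a [sim_config()].
#' @return list with `peaks` (data.frame), `clones` (named character
#'   vector, `sample|assay|clone` headers), `truth` (per embryo x guide x
#'   allele indel table), `assays` (list of [predict_amplicons()] objects)
#'   and `cut_sites` (target-haplotype cut positions).
#' @export
simulate_editing <- function(target_hap, other_hap, guide_pair,
                             config = sim_config()) {
  if (!guide_pair$feasible) stop("guide pair is infeasible")
  with_local_seed(config$seed,
                  simulate_editing_impl(target_hap, other_hap, guide_pair,
                                        config))
}

simulate_editing_impl <- function(target_hap, other_hap, guide_pair, config) {
  cuts <- c(guide_pair$site_a$cut_after, guide_pair$site_b$cut_after)
  assays <- lapply(seq_along(cuts), function(i) {
    design_flanking_assay(target_hap, other_hap, cuts[i],
                          assay_id = paste0("assay", i))
  })
  dist <- config$indel_size_distribution
  haps <- list(target = target_hap, non_target = other_hap)
  p_edit <- c(target = config$p_edit_target,
              non_target = config$p_edit_nontarget)
  peaks <- list(); clones <- character(0); truth <- list()
  for (e in seq_len(config$n_embryos)) {
    sid <- sprintf("F%03d", e)
    # germline outcome per allele x guide
    edits <- list(target = list(), non_target = list())
    for (al in names(haps)) {
      cuts_al <- if (al == "target") cuts else
        project_positions(target_hap, other_hap, cuts)
      for (gi in seq_along(cuts_al)) {
        if (is.na(cuts_al[gi]) || runif(1) >= p_edit[al]) next
        size <- sample(dist$size, 1, prob = dist$prob)
        ca <- cuts_al[gi]
        if (size < 0) {
          start <- ca - (-size) %/% 2L
          ins <- NA_character_
        } else {
          start <- ca
          ins <- random_dna(size)
        }
        edits[[al]][[length(edits[[al]]) + 1L]] <-
          list(guide = gi, pos = start, size = as.integer(size),
               inserted = ins)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, guide = gi, allele = al,
          pos = start, size = as.integer(size), stringsAsFactors = FALSE)
      }
    }
    # realized allele sequences
    seqs <- lapply(names(haps), function(al) {
      s <- haps[[al]]$sequence
      evs <- edits[[al]]
      if (length(evs)) {
        o <- order(vapply(evs, `[[`, 0, "pos"), decreasing = TRUE)
        for (ev in evs[o]) {
          s <- apply_indel(s, ev$pos, ev$size, ev$inserted)$sequence
        }
      }
      s
    })
    names(seqs) <- names(haps)
    for (ai in seq_along(assays)) {
      as_ <- assays[[ai]]
      for (al in names(haps)) {
        prod <- pcr_product(seqs[[al]], as_)
        if (is.null(prod)) next
        peaks[[length(peaks) + 1L]] <- data.frame(
          sample_id = sid, assay_id = as_$assay_id,
          size = nchar(prod) + rnorm(1, 0, config$peak_noise_sd),
          height = runif(1, 900, 1100), stringsAsFactors = FALSE)
      }
      for (cl in seq_len(config$n_clones)) {
        al <- if (runif(1) < 0.5) "target" else "non_target"
        prod <- pcr_product(seqs[[al]], as_)
        if (is.null(prod)) next
        clones[sprintf("%s|%s|clone%02d", sid, as_$assay_id, cl)] <- prod
      }
    }
  }
  list(peaks = do.call(rbind, peaks), clones = clones,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(sample_id = character(0), guide = integer(0),
                    allele = character(0), pos = integer(0),
                    size = integer(0)),
       assays = assays, cut_sites = cuts)
}

# in-silico PCR on an (edited) allele sequence; NULL when a primer no
# longer matches uniquely
pcr_product <- function(sequence, assay) {
  fs <- find_all(sequence, assay$forward_primer)
  rs <- find_all(sequence, revcomp(assay$reverse_primer))
  if (length(fs) != 1 || length(rs) != 1 || rs <= fs) return(NULL)
  substr(sequence, fs, rs + nchar(assay$reverse_primer) - 1L)
}

# choose primer pairs flanking a cut site that match both alleles uniquely
design_flanking_assay <- function(target_hap, other_hap, cut_after,
                                  assay_id, flank = 100L,
                                  primer_len = 20L, max_shift = 60L) {
  for (shift in 0:max_shift) {
    for (sgn in if (shift == 0) 1 else c(1, -1)) {
      off <- flank + sgn * shift
      fs <- cut_after - off - primer_len + 1L
      rs <- cut_after + off
      if (fs < 1L || rs + primer_len - 1L > nchar(target_hap$sequence)) next
      fwd <- substr(target_hap$sequence, fs, fs + primer_len - 1L)
      rev_plus <- substr(target_hap$sequence, rs, rs + primer_len - 1L)
      res <- tryCatch(
        predict_amplicons(fwd, revcomp(rev_plus), target_hap, other_hap,
                          assay_id = assay_id),
        error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
  }
  stop("could not design a flanking assay around cut position ", cut_after)
}

#' Run the founder genotyping pipeline on simulated (or real) screen data
#'
#' Fragment peaks are called for every sample and assay; samples with at
#' least one indel call are then confirmed by clone sequencing
#' ([assign_clone()] on each of their clones), whose sequence-aware calls
#' replace the fragment calls for those animals. Alleles are declared
#' intact only when enough clones assign to them and all are wild-type.
#'
#' @param peaks fragment peak data.frame.
#' @param clones named character vector of clone sequences (headers
#'   `sample|assay|clone`) or the data.frame from [read_clones()].
#' @param assays list of [predict_amplicons()] objects.
#' @param target_hap,other_hap the two alleles.
#' @param cut_sites designed cut positions on the target haplotype.
#' @param gene_model reference [gene_model()] for frame classification.
#' @param n_newborns total animals screened.
#' @param tolerance_bp,min_rel_height fragment-calling parameters.
#' @param min_clones_intact minimum concordant wild-type clones to declare
#'   an allele intact (default 3).
#' @return list with `calls`, `summary` (a [summarize_founders()] object)
#'   and `allele_status` (per sample/allele clone tallies).
#' @export
genotype_founders <- function(peaks, clones, assays, target_hap, other_hap,
                              cut_sites, gene_model, n_newborns,
                              tolerance_bp = 1.0, min_rel_height = 0.10,
                              min_clones_intact = 3L) {
  frag <- do.call(rbind, lapply(assays, function(a)
    call_fragment_genotype(peaks, a, tolerance_bp, min_rel_height)))
  carriers <- unique(frag$sample_id[frag$call == "indel"])
  if (is.character(clones)) {
    parts <- strsplit(names(clones), "|", fixed = TRUE)
    clones <- data.frame(sample_id = vapply(parts, `[`, "", 1),
                         assay_id = vapply(parts, `[`, "", 2),
                         clone = vapply(parts, `[`, "", 3),
                         sequence = unname(clones), stringsAsFactors = FALSE)
  }
  assay_by_id <- setNames(assays, vapply(assays, `[[`, "", "assay_id"))
  clone_calls <- list()
  # identical clone sequences recur across clones and animals (every intact
  # amplicon is the same string, and so is every copy of a given edit), so
  # calls are memoized per (assay, sequence)
  call_memo <- new.env(parent = emptyenv())
  cl <- clones[clones$sample_id %in% carriers, , drop = FALSE]
  for (i in seq_len(nrow(cl))) {
    key <- paste(cl$assay_id[i], cl$sequence[i], sep = "|")
    cc <- call_memo[[key]]
    if (is.null(cc)) {
      cc <- assign_clone(cl$sequence[i], target_hap, other_hap, cut_sites,
                         assay = assay_by_id[[cl$assay_id[i]]],
                         sample_id = "", assay_id = cl$assay_id[i])
      if (cc$call == "indel" && cc$allele_of_origin != "ambiguous") {
        hap <- if (cc$allele_of_origin == "target") target_hap else other_hap
        cc$frame_class <- classify_frame(cc, gene_model, hap)
      }
      call_memo[[key]] <- cc
    }
    cc$sample_id <- cl$sample_id[i]
    clone_calls[[length(clone_calls) + 1L]] <- cc
  }
  clone_calls <- if (length(clone_calls)) do.call(rbind, clone_calls) else
    frag[0, ]
  calls <- rbind(clone_calls,
                 frag[!frag$sample_id %in% carriers, , drop = FALSE])
  # allele-intact tallies from clones
  allele_status <- NULL
  if (nrow(clone_calls)) {
    tab <- clone_calls[clone_calls$allele_of_origin != "ambiguous", ]
    if (nrow(tab)) {
      agg <- stats::aggregate(
        list(n = rep(1L, nrow(tab)), n_wt = as.integer(tab$call == "wild_type")),
        by = list(sample_id = tab$sample_id, allele = tab$allele_of_origin),
        FUN = sum)
      agg$intact <- agg$n >= min_clones_intact & agg$n == agg$n_wt
      allele_status <- agg
    }
  }
  list(calls = calls, summary = summarize_founders(calls, n_newborns),
       allele_status = allele_status)
}
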
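test_that("protospacer scanner matches format examples on both strands", {
  spec <- pam_spec()
  expect_equal(nrow(scan_protospacers(strrep("A", 30), spec)), 0)

  fwd23 <- "ACGTACGTACGTACGTACGTTGG"
  s1 <- scan_protospacers(fwd23, spec)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$strand, "+")
  expect_equal(s1$protospacer, substr(fwd23, 1, 20))
  expect_equal(s1$pam, "TGG")
  expect_equal(s1$cut_after, 17)

  rev23 <- oracle_revcomp(fwd23)   # starts CCA...
  s2 <- scan_protospacers(rev23, spec)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$strand, "-")
  expect_equal(s2$protospacer, oracle_revcomp(substr(rev23, 4, 23)))
  expect_equal(s2$pam, "TGG")

  # region shorter than one window is empty, not an error
  expect_equal(nrow(scan_protospacers(fwd23, spec, region = c(1, 10))), 0)
  # N voids a window
  n_seq <- paste0(substr(fwd23, 1, 10), "N", substr(fwd23, 12, 23))
  expect_equal(nrow(scan_protospacers(n_seq, spec)), 0)
})

test_that("scanner equals the exhaustive window oracle and is strand-symmetric", {
  set.seed(402)
  spec <- pam_spec()
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    got <- scan_protospacers(s, spec)
    want <- oracle_scan(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$protospacer, want$protospacer)
    expect_equal(got$pam, want$pam)
    # strand symmetry: scanning the reverse complement yields the same
    # guides with reflected coordinates
    rcs <- scan_protospacers(oracle_revcomp(s), spec)
    expect_equal(sort(paste(rcs$protospacer, rcs$pam)),
                 sort(paste(got$protospacer, got$pam)))
    expect_equal(sort(nchar(s) - got$end + 1L), sort(rcs$start))
  }
})

# small locus in which every specificity class is realized by construction:
# exon covers everything; variants are placed relative to a known + site
specificity_fixture <- function() {
  set.seed(403)
  base <- paste(sample(c("A", "C", "T"), 200, replace = TRUE),
                collapse = "")   # no G: no accidental NGG PAMs
  # plant one forward site at 61..83: protospacer 61..80, PAM 81..83
  proto <- "ACCTGTAGCATCGATCCTGA"
  sub <- function(s, at) paste0(substr(s, 1, at - 1), proto,
                                substr(s, at + nchar(proto), nchar(s)))
  seqstr <- sub(base, 61)
  seqstr <- paste0(substr(seqstr, 1, 80), "TGG",
                   substr(seqstr, 84, nchar(seqstr)))
  gm <- suppressWarnings(
    gene_model("fix", seqstr, data.frame(start = 1, end = 198)))
  gm
}

test_that("specificity classes follow the PAM rule, N degeneracy included", {
  gm <- specificity_fixture()
  spec <- pam_spec()
  other <- build_haplotype(gm, NULL, "recurrent")

  # donor gains nothing; the REFERENCE here carries the PAM, so classify
  # from the reference side with donor variants breaking the motif
  # case 1: SNP at PAM position 3 (G->A) on the other allele -> TARGET_ONLY
  vt1 <- variant_table(83, substr(gm$sequence, 83, 83), "A", gm)
  target <- build_haplotype(gm, NULL, "donor")
  other1 <- build_haplotype(gm, vt1, "recurrent")
  sites <- scan_protospacers(target, spec)
  site <- sites[sites$strand == "+" & sites$pam_start == 81, ]
  expect_equal(nrow(site), 1)
  expect_equal(classify_specificity(site, target, other1, spec)$class,
               "TARGET_ONLY_PAM")

  # case 2: SNP at PAM position 1 (the degenerate N) never breaks the motif
  vt2 <- variant_table(81, substr(gm$sequence, 81, 81), "C", gm)
  other2 <- build_haplotype(gm, vt2, "recurrent")
  expect_equal(classify_specificity(site, target, other2, spec)$class,
               "SHARED")

  # case 3: SNP inside the protospacer with an intact PAM
  p10 <- 70  # protospacer position 10
  vt3 <- variant_table(p10, substr(gm$sequence, p10, p10),
                       setdiff(c("A", "C", "G", "T"),
                               substr(gm$sequence, p10, p10))[1], gm)
  other3 <- build_haplotype(gm, vt3, "recurrent")
  r3 <- classify_specificity(site, target, other3, spec)
  expect_equal(r3$class, "PROTOSPACER_VARIANT")
  expect_equal(r3$diagnostic_variants, p10)

  # case 4: a deletion under the window leaves no homologous window
  vt4 <- variant_table(70, substr(gm$sequence, 70, 75),
                       substr(gm$sequence, 70, 70), gm)
  other4 <- build_haplotype(gm, vt4, "recurrent")
  expect_equal(classify_specificity(site, target, other4, spec)$class,
               "UNMAPPABLE")

  # identical alleles share every site
  expect_equal(classify_specificity(site, target, other, spec)$class,
               "SHARED")
})

test_that("every TARGET_ONLY_PAM call fails the motif on the other allele", {
  for (seed in 1:12) {
    sp <- make_strain_pair(sim_config(
      seed = seed, locus_length = 2500L, n_exons = 6L,
      planted_pam_gain_snps = list(c(2L, 1L), c(5L, 1L))))
    sites <- classify_sites(scan_protospacers(sp$target_hap),
                            sp$target_hap, sp$other_hap)
    tops <- sites[sites$specificity == "TARGET_ONLY_PAM", ]
    expect_gt(nrow(tops), 1)
    for (i in seq_len(nrow(tops))) {
      posns <- tops$start[i]:tops$end[i]
      homol <- project_positions(sp$target_hap, sp$other_hap, posns)
      win <- paste(strsplit(sp$other_hap$sequence, "")[[1]][homol],
                   collapse = "")
      pam <- if (tops$strand[i] == "+") {
        substr(win, nchar(win) - 2, nchar(win))
      } else {
        oracle_revcomp(substr(win, 1, 3))
      }
      expect_false(oracle_pam_ok(pam, "NGG"))
    }
  }
})

test_that("quality filters reject by GC, homopolymer and exon overlap", {
  # locus: intron 1..50, coding exon 51..130, intron 131..200
  set.seed(404)
  backbone <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
  plant <- function(s, proto, at) {
    s <- paste0(substr(s, 1, at - 1), proto, "TGG",
                substr(s, at + nchar(proto) + 3, nchar(s)))
    s
  }
  s <- backbone
  s <- plant(s, strrep("AT", 10), 60)           # GC 0% inside the exon
  s <- plant(s, paste0(strrep("GC", 6), "ACGT", "TTTT"), 95)  # TTTT, GC 70%
  s <- plant(s, "ACGTACGTACGTACGTACGT", 150)    # clean but intronic
  gm <- suppressWarnings(gene_model(
    "flt", s, data.frame(start = 51, end = 130)))
  hap <- build_haplotype(gm, NULL, "donor")
  sites <- scan_protospacers(hap)
  sites$specificity <- "TARGET_ONLY_PAM"
  kept <- filter_guides(sites, gm, hap)
  rej <- attr(kept, "rejections")
  expect_true(any(grepl("GC below", rej$reason)))
  expect_true(any(grepl("TTTT", rej$reason)))
  expect_true(any(grepl("coding", rej$reason)))
  expect_false(any(kept$gc < 0.25 | kept$gc > 0.75))
  expect_false(any(grepl("TTTT", kept$protospacer)))
})

test_that("pair selection pairs the earliest exon with the farthest downstream exon", {
  fake_site <- function(start, exon, spc = "TARGET_ONLY_PAM") {
    data.frame(start = start, end = start + 22L, strand = "+",
               protospacer = strrep("A", 20), pam = "TGG",
               pam_start = start + 20L, cut_after = start + 16L,
               specificity = spc, exon = exon, coding_exon = TRUE,
               gc = 0.5, stringsAsFactors = FALSE)
  }
  sites <- rbind(fake_site(100, 2), fake_site(160, 2), fake_site(900, 7))
  pair <- select_guide_pair(sites)
  expect_true(pair$feasible)
  expect_equal(pair$site_a$exon, 2)
  expect_equal(pair$site_a$start, 100)  # 5'-most in the earliest exon
  expect_equal(pair$site_b$exon, 7)
  expect_equal(pair$expected_deletion_span, c(117, 916))

  mono <- rbind(fake_site(100, 2), fake_site(160, 2))
  res <- select_guide_pair(mono)
  expect_false(res$feasible)
  expect_match(res$reason, "one exon")

  # protospacer-variant sites are excluded unless explicitly admitted
  mixed <- rbind(fake_site(100, 2),
                 fake_site(900, 7, spc = "PROTOSPACER_VARIANT"))
  expect_false(select_guide_pair(mixed)$feasible)
  expect_true(select_guide_pair(mixed,
                                allow_protospacer_variant = TRUE)$feasible)
})

test_that("the designed pair covers planted PAM-gain sites on a clean locus", {
  sp <- make_strain_pair(sim_config(
    seed = 31, locus_length = 3000L, n_exons = 6L, snp_rate = 0,
    planted_pam_gain_snps = list(c(2L, 1L), c(5L, 1L))))
  expect_identical(nrow(sp$truth), 2L)
  d <- design_guides(sp$target_hap, sp$other_hap, sp$gene_model)
  expect_true(d$pair$feasible)
  expect_setequal(c(d$pair$site_a$cut_after, d$pair$site_b$cut_after),
                  sp$truth$cut_after_hap)
  expect_setequal(c(d$pair$site_a$protospacer, d$pair$site_b$protospacer),
                  sp$truth$protospacer)
  # with no planted sites and no SNPs the two alleles are identical and no
  # allele-specific design exists
  sp0 <- make_strain_pair(sim_config(
    seed = 32, locus_length = 3000L, n_exons = 6L, snp_rate = 0,
    planted_pam_gain_snps = list()))
  expect_identical(sp0$target_hap$sequence, sp0$other_hap$sequence)
  d0 <- design_guides(sp0$target_hap, sp0$other_hap, sp0$gene_model)
  expect_false(d0$pair$feasible)
  expect_equal(sum(d0$sites$specificity == "TARGET_ONLY_PAM"), 0)
})

test_that("off-target counting is an exact Hamming count, monotone in the radius", {
  guide <- "ACGTACGTACGTACGTACGT"
  site <- paste0(guide, "TGG")
  expect_gte(count_offtargets(guide, site, 0), 1)
  expect_equal(count_offtargets(guide, strrep("A", 100), 0), 0)

  near <- paste0("ACGTACGTACCTACGTACGT", "AGG")  # one mismatch, valid PAM
  bg <- paste0(strrep("T", 10), site, strrep("T", 10), near, strrep("T", 10))
  expect_equal(count_offtargets(guide, bg, 0), 1)
  expect_equal(count_offtargets(guide, bg, 1), 2)
  expect_equal(count_offtargets(guide, bg, 1),
               oracle_hamming_offtargets(guide, bg, 1))

  set.seed(405)
  rbg <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")
  counts <- vapply(c(0, 2, 5, 9, 20), function(m)
    count_offtargets(guide, rbg, m), 0L)
  expect_true(all(diff(counts) >= 0))
  expect_equal(count_offtargets(guide, rbg, 3),
               oracle_hamming_offtargets(guide, rbg, 3))
})
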
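# shared fixture: a 600-bp locus with two diagnostic SNPs and a natural
# 6-bp strain deletion downstream, one coding exon covering the amplicon
geno_fixture <- function(with_deletion = FALSE) {
  set.seed(406)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                  collapse = "")
  gm <- gene_model("geno", seqstr, data.frame(start = 101, end = 400))
  chars <- strsplit(seqstr, "")[[1]]
  pos <- c(230, 260)
  ref <- chars[pos]
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  if (with_deletion) {
    pos <- c(pos, 320)
    ref <- c(ref, paste(chars[320:326], collapse = ""))
    alt <- c(alt, chars[320])
  }
  vt <- variant_table(pos, ref, alt, gm, source = "donor")
  list(gm = gm,
       target = build_haplotype(gm, vt, "donor"),
       other = build_haplotype(gm, NULL, "recurrent"))
}

test_that("amplicon prediction computes per-allele lengths from primer footprints", {
  fx <- geno_fixture()
  fwd <- substr(fx$other$sequence, 150, 169)
  rev_plus <- substr(fx$other$sequence, 331, 350)
  a <- predict_amplicons(fwd, oracle_revcomp(rev_plus), fx$target, fx$other)
  expect_equal(unname(a$expected_length["target"]), 201)
  expect_equal(unname(a$expected_length["non_target"]), 201)

  # a 6-bp strain deletion between the primers shifts one allele's length
  fxd <- geno_fixture(with_deletion = TRUE)
  ad <- predict_amplicons(fwd, oracle_revcomp(rev_plus), fxd$target,
                          fxd$other)
  expect_equal(unname(ad$expected_length["non_target"] -
                        ad$expected_length["target"]), 6)

  # a primer over a diagnostic SNP cannot match both alleles exactly
  fwd_snp <- substr(fx$other$sequence, 221, 240)  # covers SNP at 230
  expect_error(
    predict_amplicons(fwd_snp, oracle_revcomp(rev_plus), fx$target,
                      fx$other),
    "matches 0 time")
})

test_that("fragment peaks call indels against the nearest expected length", {
  assay_eq <- structure(list(assay_id = "a1",
                             expected_length = c(target = 200,
                                                 non_target = 200)),
                        class = "amplicon_assay")
  pk <- data.frame(sample_id = "s1", assay_id = "a1", size = 200.3,
                   height = 1000)
  call <- call_fragment_genotype(pk, assay_eq)
  expect_equal(call$call, "wild_type")
  expect_equal(call$allele_of_origin, "ambiguous")

  assay_df <- structure(list(assay_id = "a1",
                             expected_length = c(target = 200,
                                                 non_target = 214)),
                        class = "amplicon_assay")
  pk2 <- data.frame(sample_id = "s1", assay_id = "a1",
                    size = c(193, 214), height = c(1000, 900))
  c2 <- call_fragment_genotype(pk2, assay_df)
  del <- c2[c2$call == "indel", ]
  expect_equal(del$allele_of_origin, "target")
  expect_equal(del$indel_size, -7L)
  expect_equal(del$frame_class, "frameshift")
  wt <- c2[c2$call == "wild_type", ]
  expect_equal(wt$allele_of_origin, "non_target")
  expect_false(any(c2$low_confidence))

  # one peak where two should resolve: nearest-expected call, low confidence
  pk3 <- data.frame(sample_id = "s1", assay_id = "a1", size = 207,
                    height = 1000)
  c3 <- call_fragment_genotype(pk3, assay_df)
  expect_equal(c3$call, "indel")
  expect_equal(c3$allele_of_origin, "target")
  expect_equal(c3$indel_size, 7L)
  expect_true(c3$low_confidence)

  # short peaks below the relative height threshold give a no-call
  pk4 <- data.frame(sample_id = c("s1", "s1"), assay_id = "a1",
                    size = c(200, 205), height = c(1000, 20))
  c4 <- call_fragment_genotype(pk4, assay_df)
  expect_equal(nrow(c4), 1)  # noise peak dropped
})

test_that("raising the sizing tolerance never converts wild-type into indel calls", {
  assay <- structure(list(assay_id = "a1",
                          expected_length = c(target = 200,
                                              non_target = 212)),
                     class = "amplicon_assay")
  set.seed(407)
  pk <- data.frame(sample_id = paste0("s", 1:60), assay_id = "a1",
                   size = runif(60, 190, 220), height = 1000)
  tols <- c(0.5, 1, 2, 4)
  calls <- lapply(tols, function(tl)
    call_fragment_genotype(pk, assay, tolerance_bp = tl))
  for (k in seq_along(tols)[-1]) {
    wt_before <- calls[[k - 1]]$sample_id[calls[[k - 1]]$call == "wild_type"]
    ind_after <- calls[[k]]$sample_id[calls[[k]]$call == "indel"]
    expect_length(intersect(wt_before, ind_after), 0)
  }
})

test_that("clone reads are assigned to their allele and their indel extracted", {
  fx <- geno_fixture()
  cut <- 300L
  amp <- function(hap) substr(hap$sequence, 150, 350)

  # clone identical to the other allele
  c1 <- assign_clone(amp(fx$other), fx$target, fx$other, cut)
  expect_equal(c1$allele_of_origin, "non_target")
  expect_equal(c1$call, "wild_type")

  # target clone with a 5-bp deletion 3 bp upstream of the cut
  tseq <- fx$target$sequence
  delseq <- paste0(substr(tseq, 1, cut - 8), substr(tseq, cut - 2, 600))
  c2 <- assign_clone(substr(delseq, 150, 345), fx$target, fx$other, cut)
  expect_equal(c2$allele_of_origin, "target")
  expect_equal(c2$call, "indel")
  expect_equal(c2$indel_size, -5L)
  expect_equal(classify_frame(c2, fx$gm, fx$target), "frameshift")

  # diagnostic bases split 1:1 between the alleles: ambiguous
  mixed <- amp(fx$target)
  # revert the second SNP (position 260 -> amplicon offset 111) to reference
  ref_base <- substr(fx$other$sequence, 260, 260)
  substr(mixed, 111, 111) <- ref_base
  c3 <- assign_clone(mixed, fx$target, fx$other, cut)
  expect_equal(c3$allele_of_origin, "ambiguous")

  # an indel far from any cut site is not attributed to editing
  farseq <- paste0(substr(tseq, 1, 199), substr(tseq, 205, 600))
  c4 <- assign_clone(substr(farseq, 150, 340), fx$target, fx$other, cut)
  expect_equal(c4$call, "wild_type")
})

test_that("frame classification distinguishes frameshift, in-frame and premature stop", {
  fx <- geno_fixture()
  mk_call <- function(pos, size, inserted = NA_character_) {
    data.frame(sample_id = "s", assay_id = "a1", allele_of_origin = "target",
               call = "indel", indel_size = size, indel_pos = pos,
               inserted = inserted, frame_class = NA, evidence = "clone",
               low_confidence = FALSE, stringsAsFactors = FALSE)
  }
  expect_equal(classify_frame(mk_call(220, -7L), fx$gm, fx$target),
               "frameshift")
  # 6-bp deletion inside the exon: translate and verify no early stop by an
  # independent route before trusting in_frame
  cl6 <- mk_call(220, -6L)
  got <- classify_frame(cl6, fx$gm, fx$target)
  cds <- substr(fx$target$sequence, 101, 400)
  edited <- paste0(substr(fx$target$sequence, 101, 219),
                   substr(fx$target$sequence, 226, 400))
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(edited)))
  early <- regexpr("*", prot, fixed = TRUE)
  want <- if (early > 0 && early < 0.5 * nchar(cds) / 3) "premature_stop"
          else "in_frame"
  expect_equal(got, want)

  # planting TAA in frame right after the exon start forces an early stop
  ins_call <- mk_call(103, 3L, inserted = "TAA")
  # only a valid premature-stop context: position 103 is the end of codon 1
  expect_equal(classify_frame(ins_call, fx$gm, fx$target), "premature_stop")

  # intronic deletion is flagged non-coding
  expect_equal(classify_frame(mk_call(20, -7L), fx$gm, fx$target),
               "non_coding")
  expect_equal(classify_frame(mk_call(220, -7L), fx$gm, NULL), "frameshift")
})

test_that("founder summaries count animals, not clones, and match definitions", {
  # 10 newborns, 8 with target-allele ORF loss: 80% efficiency
  calls8 <- do.call(rbind, lapply(1:8, function(i)
    founder_call(sprintf("F%02d", i), "target", -7L, "frameshift")))
  s <- summarize_founders(calls8, n_newborns = 10)
  expect_equal(s$efficiency_percent, 80)
  expect_equal(s$n_mistargeted, 0)

  # no indels at all
  wt <- data.frame(sample_id = "F01", assay_id = "a1",
                   allele_of_origin = "ambiguous", call = "wild_type",
                   indel_size = NA_integer_, indel_pos = NA_integer_,
                   inserted = NA_character_, frame_class = "wild_type",
                   evidence = "fragment", low_confidence = FALSE)
  s0 <- summarize_founders(wt, n_newborns = 10)
  expect_equal(s0$efficiency_percent, 0)
  expect_equal(s0$n_indel_carriers, 0)

  # mixed outcome: 2 ORF loss, 1 in-frame only, 1 mistargeted
  mixed <- rbind(founder_call("F1", "target", -7L, "frameshift"),
                 founder_call("F2", "target", -1L, "frameshift"),
                 founder_call("F3", "target", -6L, "in_frame"),
                 founder_call("F4", "non_target", -2L, "frameshift"))
  sm <- summarize_founders(mixed, n_newborns = 4)
  expect_equal(sm$efficiency_percent, 50)
  expect_equal(sm$n_mistargeted, 1)
  expect_equal(sm$n_indel_carriers, 4)
  # conservation: ORF-loss carriers + remaining animals = newborns
  expect_equal(sm$n_orf_loss +
                 (sm$n_newborns - length(sm$orf_loss_samples)), 4)

  expect_error(summarize_founders(mixed, n_newborns = 2), "smaller")
})
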
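# Independent oracles and fixture builders. These reimplement the checked
# operations by the most transparent route available (splicing, exhaustive
# window enumeration, brute-force grid maximization) and must stay
# independent of the package internals they verify.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_pam_ok <- function(window, motif) {
  w <- strsplit(window, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  if (length(w) != length(m)) return(FALSE)
  all(mapply(function(b, mm) b %in% ORACLE_IUPAC[[mm]], w, m))
}

# exhaustive window-by-window protospacer scan, both strands
oracle_scan <- function(seqstr, motif = "NGG", gl = 20L) {
  L <- nchar(seqstr)
  ml <- nchar(motif)
  hits <- list()
  for (s in seq_len(L - gl - ml + 1L)) {
    win <- substr(seqstr, s, s + gl + ml - 1L)
    if (grepl("N", win, fixed = TRUE)) next
    if (oracle_pam_ok(substr(win, gl + 1L, gl + ml), motif)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, strand = "+", protospacer = substr(win, 1, gl),
        pam = substr(win, gl + 1L, gl + ml), stringsAsFactors = FALSE)
    }
    rcwin <- oracle_revcomp(win)
    if (oracle_pam_ok(substr(rcwin, gl + 1L, gl + ml), motif)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, strand = "-", protospacer = substr(rcwin, 1, gl),
        pam = substr(rcwin, gl + 1L, gl + ml), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), ]
}

# rebuild a haplotype by splicing VCF-style variants right to left
oracle_splice <- function(refseq, vt) {
  out <- refseq
  if (nrow(vt) == 0) return(out)
  for (i in rev(seq_len(nrow(vt)))) {
    p <- vt$pos[i]
    out <- paste0(substr(out, 1, p - 1), vt$alt[i],
                  substr(out, p + nchar(vt$ref[i]), nchar(out)))
  }
  out
}

oracle_hamming_offtargets <- function(guide, background, mm_max,
                                      motif = "NGG") {
  sites <- oracle_scan(background, motif, nchar(guide))
  if (nrow(sites) == 0) return(0L)
  g <- strsplit(guide, "")[[1]]
  sum(vapply(sites$protospacer, function(p) {
    sum(strsplit(p, "")[[1]] != g) <= mm_max
  }, TRUE))
}

# brute-force two-penetrance likelihood maximization on a grid of
# (p1, p0), 0.001 steps with two local refinement passes
oracle_lod <- function(q, y) {
  ll_grid <- function(p1g, p0g) {
    M <- matrix(0, length(p1g), length(p0g))
    for (i in seq_along(y)) {
      t1 <- if (y[i] == 1) p1g else 1 - p1g
      t0 <- if (y[i] == 1) p0g else 1 - p0g
      M <- M + log(outer(q[i] * t1, (1 - q[i]) * t0, "+"))
    }
    M
  }
  p1g <- seq(0, 1, by = 0.001); p0g <- p1g
  best <- -Inf; c1 <- 0.5; c0 <- 0.5; width <- 0.001
  for (pass in 1:3) {
    M <- ll_grid(p1g, p0g)
    k <- arrayInd(which.max(M), dim(M))
    best <- max(M)
    c1 <- p1g[k[1]]; c0 <- p0g[k[2]]
    width <- if (pass == 1) 0.002 else width / 25
    p1g <- seq(max(0, c1 - width), min(1, c1 + width), length.out = 101)
    p0g <- seq(max(0, c0 - width), min(1, c0 + width), length.out = 101)
  }
  ybar <- mean(y)
  ll0 <- sum(log(ifelse(y == 1, ybar, 1 - ybar)))
  max((best - ll0) / log(10), 0)
}

# random small locus with non-overlapping VCF-style variants
random_locus_fixture <- function(len = 1500L, n_var = 15L) {
  seqstr <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
  gm <- gene_model("rand", seqstr,
                   data.frame(start = 51,
                              end = 50 + 3L * ((len - 100L) %/% 3L)))
  pos <- sort(sample(seq(20, len - 20, by = 18), n_var))
  ref <- character(0); alt <- character(0); keep <- integer(0)
  chars <- strsplit(seqstr, "")[[1]]
  for (p in pos) {
    kind <- sample(c("SNP", "INS", "DEL"), 1, prob = c(0.6, 0.2, 0.2))
    if (kind == "SNP") {
      ref <- c(ref, chars[p])
      alt <- c(alt, sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1))
    } else if (kind == "INS") {
      ref <- c(ref, chars[p])
      alt <- c(alt, paste0(chars[p],
                           paste(sample(c("A", "C", "G", "T"),
                                        sample(1:6, 1), replace = TRUE),
                                 collapse = "")))
    } else {
      k <- sample(1:6, 1)
      ref <- c(ref, paste(chars[p:(p + k)], collapse = ""))
      alt <- c(alt, chars[p])
    }
    keep <- c(keep, p)
  }
  list(gene_model = gm,
       variants = variant_table(keep, ref, alt, gm, source = "donor"))
}

# deterministic founder-call table builder for summary tests
founder_call <- function(sample_id, allele, size, frame) {
  data.frame(sample_id = sample_id, assay_id = "a1",
             allele_of_origin = allele, call = "indel",
             indel_size = size, indel_pos = NA_integer_,
             inserted = NA_character_, frame_class = frame,
             evidence = "fragment", low_confidence = FALSE,
             stringsAsFactors = FALSE)
}
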
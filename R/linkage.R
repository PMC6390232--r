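#' Haldane map function
#'
#' Converts a recombination fraction to map distance (`haldane_d`) and back
#' (`haldane_r`) assuming no crossover interference:
#' `d = -50 ln(1 - 2r)` cM, `r = (1 - exp(-d/50)) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM.
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * r)

#' @rdname haldane_d
#' @export
haldane_r <- function(d) (1 - exp(-d / 50)) / 2

#' Construct an N2 backcross panel
#'
#' A backcross of F1 hybrids to the recurrent parent: each autosomal locus
#' is either homozygous recurrent (code 0) or heterozygous (code 1), and a
#' fully penetrant dominant donor allele segregates 1:1 with the phenotype.
#'
#' @param markers data.frame with columns `marker`, `chr`, `pos` (cM).
#' @param geno individuals x markers matrix with entries 0 (homozygous
#'   recurrent), 1 (heterozygous) or `NA` (missing); backcross design
#'   admits no donor homozygotes.
#' @param phenotype binary vector, 1 = donor-like phenotype.
#' @param ids optional individual identifiers.
#' @return An object of class `n2_panel`.
#' @export
n2_panel <- function(markers, geno, phenotype, ids = NULL) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker", "chr", "pos") %in% names(markers)))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(markers)) {
    stop("geno must have one column per marker")
  }
  if (nrow(geno) != length(phenotype)) {
    stop("phenotype length must match the number of individuals")
  }
  if (!all(geno %in% c(0, 1, NA))) {
    stop("genotype codes must be 0 (hom recurrent), 1 (het) or NA")
  }
  if (!all(phenotype %in% c(0, 1))) stop("phenotype must be binary 0/1")
  # markers sorted by position within chromosomes (appearance order)
  o <- order(match(markers$chr, unique(markers$chr)), markers$pos)
  markers <- markers[o, ]
  rownames(markers) <- NULL
  geno <- geno[, o, drop = FALSE]
  colnames(geno) <- markers$marker
  if (is.null(ids)) ids <- paste0("N2_", seq_len(nrow(geno)))
  structure(list(markers = markers, geno = geno,
                 phenotype = as.integer(phenotype), ids = ids),
            class = "n2_panel")
}

#' @export
print.n2_panel <- function(x, ...) {
  cat(sprintf("n2_panel: %d individuals x %d markers on %d chromosome(s); %d/%d phenotypic\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$markers$chr)),
              sum(x$phenotype), length(x$phenotype)))
  invisible(x)
}

#' Chi-square test of 1:1 phenotype segregation
#'
#' One-degree-of-freedom goodness of fit of the phenotypic count against
#' the 1:1 ratio expected for a single fully penetrant dominant locus in a
#' backcross.
#'
#' @param n_phenotypic number of phenotypic individuals.
#' @param n_total total individuals (> 0).
#' @return An `htest`-like list with `statistic`, `p.value` and the
#'   observed phenotypic `fraction`.
#' @examples
#' test_segregation(275, 559)
#' @export
test_segregation <- function(n_phenotypic, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_phenotypic < 0 || n_phenotypic > n_total) {
    stop("n_phenotypic must lie in [0, n_total]")
  }
  e <- n_total / 2
  chi <- (n_phenotypic - e)^2 / e + ((n_total - n_phenotypic) - e)^2 / e
  structure(list(
    statistic = c("X-squared" = chi),
    parameter = c(df = 1),
    p.value = pchisq(chi, df = 1, lower.tail = FALSE),
    estimate = c(fraction = n_phenotypic / n_total),
    method = "Chi-square goodness of fit against 1:1 segregation",
    data.name = sprintf("%d of %d phenotypic", n_phenotypic, n_total)),
    class = "htest")
}

#' Estimate a genetic map from an N2 panel
#'
#' Adjacent-marker recombination fractions are estimated as the fraction of
#' recombinant pairs among pairwise-informative individuals (both genotypes
#' observed) and converted to cM with the Haldane map function. Fractions
#' at or above 0.49 are capped there with a warning — such marker pairs are
#' effectively unlinked and their distance is not estimable. Positions
#' start at 0 on each chromosome, preserving the input marker order.
#'
#' @param panel an [n2_panel()].
#' @return A `genetic_map`: data.frame with columns `marker`, `chr`, `pos`
#'   (cM) and an `r_hat` column for the interval to the previous marker.
#' @export
estimate_map <- function(panel) {
  mk <- panel$markers
  out <- mk[, c("marker", "chr")]
  out$pos <- NA_real_
  out$r_hat <- NA_real_
  for (ch in unique(mk$chr)) {
    idx <- which(mk$chr == ch)
    all_missing <- vapply(idx, function(j) all(is.na(panel$geno[, j])), TRUE)
    if (any(all_missing)) {
      stop("marker '", mk$marker[idx[which(all_missing)[1]]],
           "' has no genotypes")
    }
    pos <- 0
    out$pos[idx[1]] <- 0
    for (k in seq_along(idx)[-1]) {
      g1 <- panel$geno[, idx[k - 1]]
      g2 <- panel$geno[, idx[k]]
      ok <- !is.na(g1) & !is.na(g2)
      if (!any(ok)) {
        stop(sprintf("no informative pairs between '%s' and '%s'",
                     mk$marker[idx[k - 1]], mk$marker[idx[k]]))
      }
      r <- mean(g1[ok] != g2[ok])
      if (r >= 0.49) {
        warning(sprintf("r-hat %.3f between '%s' and '%s' capped at 0.49 (effectively unlinked)",
                        r, mk$marker[idx[k - 1]], mk$marker[idx[k]]))
        r <- 0.49
      }
      pos <- pos + haldane_d(r)
      out$pos[idx[k]] <- pos
      out$r_hat[idx[k]] <- r
    }
  }
  class(out) <- c("genetic_map", "data.frame")
  out
}

# -------------------------------------------------------------------------
# Genotype probabilities at grid positions: 2-state (hom/het) HMM per
# chromosome with Haldane transition probabilities, flat 1/2:1/2 prior and
# near-deterministic emissions at typed markers.  Missing genotypes emit
# nothing, so individuals missing a marker are marginalized over the
# flanking informative markers; an individual missing every marker on a
# chromosome ends up at the population prior, P(het) = 1/2.

genoprob_grid <- function(panel, map, step_cM = 1, error_prob = 1e-10) {
  n <- nrow(panel$geno)
  grids <- list(); probs <- list()
  for (ch in unique(map$chr)) {
    sel <- which(map$chr == ch)
    # align map rows with panel genotype columns by marker name
    mi <- match(map$marker[sel], colnames(panel$geno))
    if (anyNA(mi)) {
      stop("map marker(s) absent from the panel: ",
           paste(map$marker[sel][is.na(mi)], collapse = ", "))
    }
    o <- order(map$pos[sel])
    mi <- mi[o]
    mpos <- map$pos[sel][o]
    gpos <- sort(unique(c(mpos, seq(min(mpos), max(mpos), by = step_cM))))
    is_mk <- match(round(gpos, 9), round(mpos, 9))
    K <- length(gpos)
    emit <- function(k) {
      # n x 2 emission matrix (cols: hom, het) at grid point k
      e <- matrix(1, n, 2)
      if (!is.na(is_mk[k])) {
        g <- panel$geno[, mi[is_mk[k]]]
        obs <- !is.na(g)
        e[obs, 1] <- ifelse(g[obs] == 0, 1 - error_prob, error_prob)
        e[obs, 2] <- ifelse(g[obs] == 1, 1 - error_prob, error_prob)
      }
      e
    }
    # forward
    alpha <- vector("list", K)
    a <- matrix(0.5, n, 2) * emit(1)
    alpha[[1]] <- a / rowSums(a)
    for (k in seq_len(K)[-1]) {
      r <- haldane_r(gpos[k] - gpos[k - 1])
      a <- cbind(alpha[[k - 1]][, 1] * (1 - r) + alpha[[k - 1]][, 2] * r,
                 alpha[[k - 1]][, 1] * r + alpha[[k - 1]][, 2] * (1 - r))
      a <- a * emit(k)
      alpha[[k]] <- a / rowSums(a)
    }
    # backward
    beta <- matrix(1, n, 2)
    post <- matrix(NA_real_, n, K)
    post[, K] <- alpha[[K]][, 2] / rowSums(alpha[[K]])
    if (K > 1) {
      for (k in (K - 1):1) {
        r <- haldane_r(gpos[k + 1] - gpos[k])
        e <- emit(k + 1)
        b1 <- (1 - r) * e[, 1] * beta[, 1] + r * e[, 2] * beta[, 2]
        b2 <- r * e[, 1] * beta[, 1] + (1 - r) * e[, 2] * beta[, 2]
        beta <- cbind(b1, b2)
        beta <- beta / rowSums(beta)
        num <- alpha[[k]] * beta
        post[, k] <- num[, 2] / rowSums(num)
      }
    }
    grids[[length(grids) + 1L]] <- data.frame(chr = ch, pos = gpos)
    probs[[length(probs) + 1L]] <- post
  }
  list(grid = do.call(rbind, grids), probs = do.call(cbind, probs))
}

#' Genome scan for a dominant binary trait by EM interval mapping
#'
#' At every grid position the probability of carrying the donor allele is
#' computed from flanking markers under the Haldane (no-interference) map;
#' a two-penetrance binomial likelihood — `p1 = P(phenotype | het)`,
#' `p0 = P(phenotype | hom recurrent)` — is maximized by EM over the latent
#' genotype, and the LOD is the log10 ratio against the single-probability
#' null. LOD is non-negative by construction.
#'
#' @param panel an [n2_panel()].
#' @param map a [estimate_map()] result (or any data.frame with `marker`,
#'   `chr`, `pos`); defaults to the panel's own marker positions.
#' @param step_cM grid step between pseudomarkers (default 1 cM).
#' @return An object of class `lod_curve`: the grid with LOD scores, the
#'   peak, and a `threshold` slot filled by [permutation_threshold()].
#' @export
interval_scan <- function(panel, map = NULL, step_cM = 1) {
  if (is.null(map)) map <- panel$markers
  if (step_cM <= 0) stop("step_cM must be positive")
  y <- panel$phenotype
  gp <- genoprob_grid(panel, map, step_cM)
  if (length(unique(y)) < 2) {
    warning("monomorphic phenotype: LOD is identically 0")
    lod <- rep(0, nrow(gp$grid))
  } else {
    lod <- .scan_em_cpp(gp$probs, as.integer(y))
  }
  grid <- gp$grid
  grid$lod <- lod
  pk <- which.max(lod)
  structure(list(grid = grid,
                 peak = list(chr = grid$chr[pk], pos = grid$pos[pk],
                             lod = grid$lod[pk]),
                 threshold = NA_real_, alpha = NA_real_,
                 n = length(y), step_cM = step_cM),
            class = "lod_curve")
}

#' Genome-wide significance threshold by phenotype permutation
#'
#' Shuffles phenotype labels `n_perm` times with a seeded generator,
#' records the genome-wide maximum LOD of each permuted scan, and returns
#' the empirical right-continuous `(1 - alpha)` quantile. Genotype
#' probabilities are computed once and reused, so only the EM scans are
#' repeated.
#'
#' @inheritParams interval_scan
#' @param n_perm number of permutations (>= 100 recommended).
#' @param alpha genome-wide significance level.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return numeric threshold with the permuted maxima as attribute
#'   `"maxima"`.
#' @export
permutation_threshold <- function(panel, map = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, step_cM = 1) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (is.null(map)) map <- panel$markers
  y <- as.integer(panel$phenotype)
  gp <- genoprob_grid(panel, map, step_cM)
  # permuted maxima only feed an empirical quantile: a lighter EM (single
  # data-driven start, looser tolerance) leaves the threshold unchanged to
  # far below its Monte-Carlo error
  maxima <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      max(.scan_em_cpp(gp$probs, sample(y), maxit = 200L, tol = 1e-9,
                       n_extra_starts = 0L))
    }, 0)
  })
  thr <- as.numeric(quantile(maxima, probs = 1 - alpha, type = 1))
  attr(thr, "maxima") <- maxima
  thr
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Screen a panel for recombinants between two markers
#'
#' Returns the individuals whose genotypes at the two markers differ
#' (0/1 or 1/0). Individuals missing either marker are excluded with a
#' message. The markers must lie on the same chromosome with `left` before
#' `right`.
#'
#' @param panel an [n2_panel()].
#' @param left_marker,right_marker marker ids.
#' @return character vector of individual ids.
#' @export
find_recombinants <- function(panel, left_marker, right_marker) {
  mk <- panel$markers
  i <- match(left_marker, mk$marker)
  j <- match(right_marker, mk$marker)
  if (is.na(i) || is.na(j)) stop("marker not found in panel")
  if (mk$chr[i] != mk$chr[j]) {
    stop("markers are on different chromosomes: ", mk$chr[i], " vs ", mk$chr[j])
  }
  if (mk$pos[i] >= mk$pos[j]) stop("left_marker must precede right_marker")
  g1 <- panel$geno[, i]; g2 <- panel$geno[, j]
  miss <- is.na(g1) | is.na(g2)
  if (any(miss)) {
    message(sum(miss), " individual(s) missing a flanking genotype excluded")
  }
  panel$ids[!miss & g1 != g2]
}

#' Minimal causal interval from recombinant constraints
#'
#' For a fully penetrant dominant donor allele in a backcross, a phenotypic
#' individual must be heterozygous at the causal position and a
#' non-phenotypic individual homozygous recurrent. Each individual
#' therefore permits a set of positions: a typed marker is permitted when
#' its genotype equals the required one, and the gap between two adjacent
#' markers is permitted when either flank matches (a single crossover in
#' the gap can reconcile the other flank). The causal position must lie in
#' the intersection of all permitted sets; the returned interval is the
#' tightest flanking-marker pair containing that intersection.
#'
#' Individuals permitting no position at all (e.g. a phenotypic animal
#' homozygous across the whole region) contradict the single-locus model —
#' phenocopies or genotyping errors. They are reported in
#' `inconsistent_ids`; with `exclude_inconsistent = TRUE` the interval is
#' recomputed without them, otherwise an empty intersection is an error.
#'
#' @param panel an [n2_panel()].
#' @param chromosome chromosome to fine-map.
#' @param candidate_region optional `c(left, right)` cM bounds restricting
#'   the marker set (default: the whole chromosome).
#' @param exclude_inconsistent drop contradictory individuals and
#'   recompute.
#' @return An object of class `interval_result` with `left_marker`,
#'   `right_marker`, their positions, the permitted marker set,
#'   `recombinant_ids` (individuals recombinant across the region) and
#'   `inconsistent_ids`.
#' @export
minimal_interval <- function(panel, chromosome, candidate_region = NULL,
                             exclude_inconsistent = FALSE) {
  mk <- panel$markers
  sel <- which(mk$chr == chromosome)
  if (!is.null(candidate_region)) {
    sel <- sel[mk$pos[sel] >= candidate_region[1] &
                 mk$pos[sel] <= candidate_region[2]]
  }
  if (length(sel) < 2) stop("need at least two markers in the region")
  sel <- sel[order(mk$pos[sel])]
  M <- length(sel)
  G <- panel$geno[, sel, drop = FALSE]
  y <- panel$phenotype
  n <- nrow(G)

  # items 1..(2M-1): odd = marker (k+1)/2, even = gap k/2
  permitted_of <- function(i) {
    t <- y[i]
    g <- G[i, ]
    ok_m <- is.na(g) | g == t
    items <- logical(2 * M - 1)
    items[seq(1, 2 * M - 1, by = 2)] <- ok_m
    if (M > 1) {
      items[seq(2, 2 * M - 2, by = 2)] <- ok_m[-M] | ok_m[-1]
    }
    items
  }
  perm <- t(vapply(seq_len(n), permitted_of, logical(2 * M - 1)))
  inconsistent <- panel$ids[rowSums(perm) == 0]
  use <- rep(TRUE, n)
  if (length(inconsistent)) {
    if (!exclude_inconsistent) {
      stop("individuals inconsistent with every position in the region ",
           "(phenocopies or genotyping errors?): ",
           paste(inconsistent, collapse = ", "),
           "; rerun with exclude_inconsistent = TRUE to drop them")
    }
    use <- rowSums(perm) > 0
  }
  inter <- colSums(!perm[use, , drop = FALSE]) == 0
  if (!any(inter)) {
    stop("empty intersection of recombinant constraints even after ",
         "excluding individually inconsistent animals")
  }
  lo_item <- min(which(inter)); hi_item <- max(which(inter))
  # flanking markers strictly outside the permitted run
  lo_mk <- if (lo_item %% 2 == 1) max((lo_item + 1) %/% 2 - 1, 1) else
    lo_item %/% 2
  hi_mk <- if (hi_item %% 2 == 1) min((hi_item + 1) %/% 2 + 1, M) else
    hi_item %/% 2 + 1
  rec <- panel$ids[!is.na(G[, 1]) & !is.na(G[, M]) & G[, 1] != G[, M]]
  structure(list(
    left_marker = mk$marker[sel[lo_mk]],
    right_marker = mk$marker[sel[hi_mk]],
    left_pos = mk$pos[sel[lo_mk]], right_pos = mk$pos[sel[hi_mk]],
    chromosome = chromosome,
    permitted_markers = mk$marker[sel[inter[seq(1, 2 * M - 1, 2)]]],
    recombinant_ids = rec,
    inconsistent_ids = inconsistent),
    class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("interval_result: chr %s, %s (%.2f cM) - %s (%.2f cM)\n",
              x$chromosome, x$left_marker, x$left_pos, x$right_marker,
              x$right_pos))
  cat(sprintf("  %d recombinant(s) across the region; %d inconsistent individual(s)\n",
              length(x$recombinant_ids), length(x$inconsistent_ids)))
  invisible(x)
}

#' Filter candidate genes by expression in the relevant cell type
#'
#' Keeps genes whose expression meets `threshold`, preserving the input
#' order. Genes absent from the table are retained with an
#' `unknown expression` flag — absence of evidence is not treated as
#' absence of expression.
#'
#' @param genes character vector of genes inside the mapped interval.
#' @param expression_table data.frame with columns `gene` and `expression`.
#' @param threshold minimum expression to keep a gene.
#' @return data.frame with columns `gene`, `expression`, `status`
#'   (`expressed` / `unknown`), restricted to retained genes.
#' @export
filter_candidates <- function(genes, expression_table, threshold) {
  expr <- expression_table$expression[match(genes, expression_table$gene)]
  status <- ifelse(is.na(expr), "unknown",
                   ifelse(expr >= threshold, "expressed", "below"))
  keep <- status != "below"
  data.frame(gene = genes[keep], expression = expr[keep],
             status = status[keep], stringsAsFactors = FALSE)
}
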
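#' @export
print.lod_curve <- function(x, ...) {
  cat(sprintf("lod_curve: %d grid positions on %d chromosome(s), n = %d, step %.3g cM\n",
              nrow(x$grid), length(unique(x$grid$chr)), x$n, x$step_cM))
  cat(sprintf("  peak: chr %s @ %.2f cM, LOD %.3f\n",
              x$peak$chr, x$peak$pos, x$peak$lod))
  if (!is.na(x$threshold)) {
    cat(sprintf("  genome-wide threshold (alpha %.3g): LOD %.3f -> %s\n",
                x$alpha, x$threshold,
                if (x$peak$lod > x$threshold) "significant" else
                  "not significant"))
  }
  invisible(x)
}

#' @export
summary.lod_curve <- function(object, ...) {
  per_chr <- do.call(rbind, lapply(split(object$grid, object$grid$chr),
                                   function(g) g[which.max(g$lod), ]))
  per_chr <- per_chr[order(-per_chr$lod), ]
  rownames(per_chr) <- NULL
  structure(list(per_chr = per_chr, peak = object$peak,
                 threshold = object$threshold, alpha = object$alpha),
            class = "summary.lod_curve")
}

#' @export
print.summary.lod_curve <- function(x, ...) {
  cat("Per-chromosome LOD maxima (descending):\n")
  print(utils::head(x$per_chr, 10))
  if (!is.na(x$threshold)) {
    cat(sprintf("Genome-wide threshold (alpha %.3g): %.3f\n", x$alpha,
                x$threshold))
  }
  invisible(x)
}

#' Plot a genome scan
#'
#' Base-graphics LOD curve with chromosomes laid side by side in map order
#' and the permutation threshold, if attached, as a dashed line.
#'
#' @param x a [interval_scan()] result.
#' @param ... passed to [plot()].
#' @export
plot.lod_curve <- function(x, ...) {
  g <- x$grid
  chrs <- unique(g$chr)
  offset <- 0
  xs <- numeric(nrow(g))
  mids <- numeric(length(chrs))
  for (i in seq_along(chrs)) {
    idx <- g$chr == chrs[i]
    xs[idx] <- g$pos[idx] - min(g$pos[idx]) + offset
    w <- diff(range(g$pos[idx]))
    mids[i] <- offset + w / 2
    offset <- offset + w + 5
  }
  plot(xs, g$lod, type = "n", xaxt = "n", xlab = "chromosome",
       ylab = "LOD", ...)
  for (ch in chrs) {
    idx <- g$chr == ch
    graphics::lines(xs[idx], g$lod[idx])
  }
  graphics::axis(1, at = mids, labels = chrs, tick = FALSE)
  if (!is.na(x$threshold)) {
    graphics::abline(h = x$threshold, lty = 2)
  }
  invisible(x)
}

#' Attach a permutation threshold to a scan
#'
#' @param curve a [interval_scan()] result.
#' @param threshold value returned by [permutation_threshold()].
#' @param alpha the significance level the threshold was computed at.
#' @export
set_threshold <- function(curve, threshold, alpha = 0.05) {
  curve$threshold <- as.numeric(threshold)
  curve$alpha <- alpha
  curve
}
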
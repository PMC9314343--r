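#' Annotate loop/TAD anchors with peak-class overlaps
#'
#' Each anchor is widened to a `window_bp` window centred on its midpoint;
#' a class flag is true when at least one peak of that class overlaps the
#' widened anchor. Feature-level flags (either anchor) and anchor-level
#' Venn-style combination counts are returned.
#'
#' @param features [features2d()] table.
#' @param peak_sets named list of interval tables (e.g. CTCF, RAD21,
#'   H3K27ac, ATAC).
#' @param window_bp widened anchor width (default 15000, the boundary
#'   window width).
#' @return list with `feature_flags` (one row per feature),
#'   `anchor_flags` (one row per anchor) and `combination_counts`
#'   (anchor-level counts per class combination).
#' @export
annotate_anchors <- function(features, peak_sets, window_bp = 15000) {
  anchors <- feature_anchors(features)
  mid <- (anchors$start + anchors$end) / 2
  widened <- intervals(anchors$chrom, pmax(0, mid - window_bp / 2),
                       mid + window_bp / 2, name = anchors$name)
  flags <- vapply(peak_sets, function(pk)
    overlap_intervals(widened, pk, "count") > 0,
    logical(nrow(widened)))
  flags <- matrix(flags, nrow = nrow(widened),
                  dimnames = list(widened$name, names(peak_sets)))
  nf <- nrow(features)
  feat_flags <- flags[seq_len(nf), , drop = FALSE] |
    flags[nf + seq_len(nf), , drop = FALSE]
  rownames(feat_flags) <- features$name
  combo <- apply(flags, 1, function(r) {
    on <- names(peak_sets)[r]
    if (!length(on)) "none" else paste(on, collapse = "+")
  })
  list(feature_flags = as.data.frame(feat_flags),
       anchor_flags = as.data.frame(flags),
       combination_counts = table(combo))
}

#' Coverage profile around centred regions
#'
#' Bins each region (all of one width) into `binsize` bins relative to the
#' region centre and accumulates track signal (value x overlapped bp) per
#' bin. Profiles of minus-strand regions are flipped so downstream is
#' always to the right. Total signal within the regions is conserved:
#' `sum(matrix) == sum(signal bp)` inside the regions.
#'
#' @param track bedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `value`), or read intervals with `value` missing (counted as 1).
#' @param regions interval table; all widths must be equal and divisible by
#'   `binsize`. Regions exceeding the chromosome are trimmed with a warning
#'   when `layout` is supplied.
#' @param binsize bin width in bp (default 25).
#' @param mode `"aggregate"` (per-bin mean over regions) or
#'   `"per_region_matrix"` (one row per region).
#' @param layout optional [genome_layout()] for trimming.
#' @return numeric vector (aggregate) or matrix.
#' @export
coverage_profile <- function(track, regions, binsize = 25,
                             mode = c("aggregate", "per_region_matrix"),
                             layout = NULL) {
  mode <- match.arg(mode)
  if (!"value" %in% names(track)) track$value <- 1
  width <- unique(regions$end - regions$start)
  if (length(width) != 1) stop("regions must share one width after centring")
  if (width %% binsize != 0) stop("binsize must divide the region width")
  nb <- width / binsize
  if (!is.null(layout)) {
    for (ch in unique(regions$chrom)) {
      len <- chrom_length(layout, ch)
      out_of_range <- regions$chrom == ch &
        (regions$start < 0 | regions$end > len)
      if (any(out_of_range))
        warning("region(s) exceeding ", ch, " are trimmed")
    }
  }
  prof <- matrix(0, nrow(regions), nb)
  for (k in seq_len(nrow(regions))) {
    tr <- track[track$chrom == regions$chrom[k] &
                  track$end > regions$start[k] &
                  track$start < regions$end[k], , drop = FALSE]
    if (!nrow(tr)) next
    for (t in seq_len(nrow(tr))) {
      lo <- max(tr$start[t], regions$start[k]) - regions$start[k]
      hi <- min(tr$end[t], regions$end[k]) - regions$start[k]
      b_lo <- floor(lo / binsize) + 1
      b_hi <- ceiling(hi / binsize)
      for (b in b_lo:b_hi) {
        ov <- min(hi, b * binsize) - max(lo, (b - 1) * binsize)
        if (ov > 0) prof[k, b] <- prof[k, b] + ov * tr$value[t]
      }
    }
    if (!is.null(regions$strand) && regions$strand[k] == "-")
      prof[k, ] <- rev(prof[k, ])
  }
  rownames(prof) <- regions$name
  if (mode == "aggregate") colMeans(prof) else prof
}

#' Call super-enhancers by rank-curve tangent cutoff
#'
#' H3K27ac peaks whose centres lie within `tss_exclusion` of a TSS are
#' removed; the rest are stitched when gaps are strictly below
#' `stitch_gap`. Stitched enhancers get input-corrected signal
#' `y = max(signal - input, 0)`, are ranked ascending, and rank and signal
#' are scaled to the unit square. The cutoff is where the slope of the
#' (lightly smoothed) scaled curve first reaches 1 — the tangential
#' diagonal of the hockey plot; entries above it are super-enhancers.
#'
#' @param peaks H3K27ac peak intervals.
#' @param signal,input_signal per-peak signal and matched input (same
#'   length as `peaks`); input correction floors at 0.
#' @param tss TSS intervals (positions taken as interval starts).
#' @param stitch_gap maximum stitching gap, exclusive (default 12000).
#' @param tss_exclusion centre-to-TSS distance below which a peak is
#'   dropped (default 2000).
#' @param smooth_width moving-average width (ranks) for the slope curve
#'   (default 5).
#' @return object of class `enhancer_ranking`: data.frame `enhancers`
#'   (stitched intervals with `y`, `rank`, `x_scaled`, `y_scaled`,
#'   `is_super`), `cutoff_rank`, `n_super`, `degenerate` flag.
#' @export
call_superenhancers <- function(peaks, signal, input_signal, tss,
                                stitch_gap = 12000, tss_exclusion = 2000,
                                smooth_width = 5) {
  if (length(signal) != nrow(peaks) || length(input_signal) != nrow(peaks))
    stop("signal vectors must match peaks")
  if (any(signal < 0) || any(input_signal < 0)) stop("signals must be >= 0")
  ctr <- (peaks$start + peaks$end) / 2
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(tss)) {
    for (k in seq_len(nrow(peaks))) {
      tt <- tss$start[tss$chrom == peaks$chrom[k]]
      if (length(tt) && min(abs(tt - ctr[k])) < tss_exclusion) keep[k] <- FALSE
    }
  }
  pk <- peaks[keep, , drop = FALSE]
  sg <- signal[keep]; ip <- input_signal[keep]
  if (nrow(pk) == 0) stop("no peaks left after TSS exclusion")
  ord <- order(pk$chrom, pk$start)
  pk <- pk[ord, , drop = FALSE]; sg <- sg[ord]; ip <- ip[ord]
  ## stitch: gap (next start - previous end) strictly below stitch_gap
  grp <- integer(nrow(pk)); grp[1] <- 1
  for (k in seq_len(nrow(pk))[-1]) {
    same <- pk$chrom[k] == pk$chrom[k - 1] &&
      pk$start[k] - max(pk$end[seq_len(k - 1)][grp[seq_len(k - 1)] == grp[k - 1]]) < stitch_gap
    grp[k] <- if (same) grp[k - 1] else grp[k - 1] + 1
  }
  st <- data.frame(
    chrom = tapply(pk$chrom, grp, `[`, 1),
    start = as.numeric(tapply(pk$start, grp, min)),
    end = as.numeric(tapply(pk$end, grp, max)),
    y = pmax(as.numeric(tapply(sg, grp, sum)) -
               as.numeric(tapply(ip, grp, sum)), 0),
    stringsAsFactors = FALSE)
  n <- nrow(st)
  if (n < 3) stop("fewer than 3 stitched enhancers; ranking curve undefined")
  st <- st[order(st$y, st$chrom, st$start), , drop = FALSE]
  st$rank <- seq_len(n)
  st$x_scaled <- (st$rank - 1) / (n - 1)
  yr <- range(st$y)
  if (yr[2] == yr[1]) {
    st$y_scaled <- rep(0, n)
  } else st$y_scaled <- (st$y - yr[1]) / (yr[2] - yr[1])
  ## slope of the smoothed scaled curve, central differences
  ys <- stats::filter(st$y_scaled, rep(1 / smooth_width, smooth_width),
                      sides = 2)
  ys[is.na(ys)] <- st$y_scaled[is.na(ys)]
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) /
    (st$x_scaled[3:n] - st$x_scaled[1:(n - 2)])
  below <- which(slope < 1 - 1e-8)
  reach <- which(slope >= 1 - 1e-8)
  reach <- reach[length(below) > 0 & reach > min(c(below, Inf))]
  if (!length(below) || !length(reach)) {
    ## no sub-diagonal phase (e.g. a straight line) or slope never reaches
    ## 1: the tangent construction is undefined
    st$is_super <- FALSE
    return(structure(list(enhancers = st, cutoff_rank = NA_integer_,
                          n_super = 0L, degenerate = TRUE),
                     class = "enhancer_ranking"))
  }
  cutoff <- min(reach) - 1  # last rank before the slope first reaches 1
  st$is_super <- st$rank > cutoff
  structure(list(enhancers = st, cutoff_rank = cutoff,
                 n_super = sum(st$is_super), degenerate = FALSE),
            class = "enhancer_ranking")
}

#' @export
print.enhancer_ranking <- function(x, ...) {
  cat("enhancer_ranking:", nrow(x$enhancers), "stitched enhancers,",
      x$n_super, "super-enhancers (cutoff rank", x$cutoff_rank, ")\n")
  invisible(x)
}

#' Per-sample track scale factors from top-ranked peaks
#'
#' Uses the union of each sample's `top_n` strongest peaks; each sample's
#' factor is the reference sample's mean signal over that union divided by
#' the sample's own mean. Applying the factors equalises top-peak means
#' (idempotent).
#'
#' @param sample_signals matrix of per-peak signal (peaks x samples).
#' @param top_n number of top peaks per sample (roughly 5% of peaks).
#' @param reference reference sample (index or name, default 1).
#' @return named per-sample factors.
#' @export
scale_tracks_top_peaks <- function(sample_signals, top_n, reference = 1) {
  m <- as.matrix(sample_signals)
  if (top_n > nrow(m)) stop("top_n exceeds the number of peaks")
  sel <- unique(unlist(lapply(seq_len(ncol(m)), function(s)
    order(-m[, s])[seq_len(top_n)])))
  means <- colMeans(m[sel, , drop = FALSE])
  if (any(means == 0)) stop("zero mean over top peaks")
  ref_mean <- means[reference]
  f <- ref_mean / means
  if (is.null(names(f))) names(f) <- colnames(m)
  f
}

#' Fraction of reads in peaks (FRIP)
#'
#' @param reads read intervals.
#' @param peaks peak intervals.
#' @return fraction in `[0, 1]` of reads overlapping at least one peak.
#' @export
frip <- function(reads, peaks) {
  if (nrow(reads) == 0) stop("zero reads")
  mean(overlap_intervals(reads, peaks, "count") > 0)
}

#' Anchor-set overlap enrichment (Fisher)
#'
#' Builds the 2x2 contingency of universe anchors by membership in sets A
#' and B (membership = overlap with any interval of the set) and tests
#' association with Fisher's exact test; odds ratio with Haldane correction
#' when any cell is zero.
#'
#' @param set_a,set_b anchor interval tables.
#' @param universe deduplicated universe of anchor intervals.
#' @return list with `table`, `odds_ratio`, `p`, `degenerate` flag.
#' @export
anchor_overlap_test <- function(set_a, set_b, universe) {
  if (nrow(universe) == 0) stop("empty universe")
  in_a <- overlap_intervals(universe, set_a, "count") > 0
  in_b <- overlap_intervals(universe, set_b, "count") > 0
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  degenerate <- (b + d == 0) || (c + d == 0) || (a + b == 0) || (a + c == 0)
  fe <- fisher_exact(a, b, c, d)
  list(table = fe$table, odds_ratio = fe$odds_ratio, p = fe$p,
       haldane = fe$haldane, degenerate = degenerate)
}
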
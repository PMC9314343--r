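#' Insulation score track
#'
#' Square-window insulation: for bin `i`, the raw score is the mean count
#' over pairs `(u, v)` with `u` in `[i-w, i-1]` and `v` in `[i+1, i+w]`,
#' i.e. the contact flux crossing the bin. Reported values are
#' `log2(IS(i) / mean chromosome IS)`; bins within `w` of either edge are
#' missing. Insulation is invariant under global depth scaling.
#'
#' @param mat a [contact_matrix()] (depth-normalised or raw).
#' @param window_w window half-width in bins (>= 1).
#' @return a [bin_track()]; attribute `raw` holds the unnormalised means.
#' @export
insulation_track <- function(mat, window_w) {
  m <- mat$counts
  n <- nrow(m)
  w <- as.integer(window_w)
  if (w < 1) stop("window_w must be >= 1")
  if (w >= n / 2) stop("window_w must be below half the chromosome")
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    raw[i] <- mean(m[(i - w):(i - 1), (i + 1):(i + w)])
  }
  mu <- mean(raw, na.rm = TRUE)
  vals <- log2(raw / mu)
  vals[!is.na(raw) & raw == 0] <- -Inf
  out <- bin_track(mat$chrom, mat$resolution, vals)
  attr(out, "raw") <- raw
  out
}

#' Directionality index track
#'
#' For bin `i`, with `A` the summed contacts to the `w` upstream bins and
#' `B` to the `w` downstream bins and `E = (A+B)/2`:
#' `DI = sign(B-A) * ((A-E)^2/E + (B-E)^2/E)`. `A == B` gives 0;
#' `A == B == 0` is missing. Invariant under depth scaling up to the
#' overall chi-square scale; sign pattern is scale-free.
#'
#' @inheritParams insulation_track
#' @return a [bin_track()] of DI values.
#' @export
directionality_track <- function(mat, window_w) {
  m <- mat$counts
  n <- nrow(m)
  w <- as.integer(window_w)
  if (w < 1) stop("window_w must be >= 1")
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    up <- max(1, i - w):(i - 1)
    dn <- (i + 1):min(n, i + w)
    a <- if (i > 1) sum(m[i, up]) else 0
    b <- if (i < n) sum(m[i, dn]) else 0
    if (a == 0 && b == 0) next
    e <- (a + b) / 2
    vals[i] <- sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
  }
  bin_track(mat$chrom, mat$resolution, vals)
}

## prominence of a local minimum at index i in x (NA-tolerant):
## walk out on each side until a value lower than x[i] is met; prominence
## is min(highest value seen left, highest value seen right) - x[i].
.min_prominence <- function(x, i) {
  n <- length(x)
  side_max <- function(idx) {
    hi <- -Inf
    for (j in idx) {
      v <- x[j]
      if (is.na(v)) break
      if (v < x[i]) break
      if (v > hi) hi <- v
    }
    hi
  }
  lhs <- side_max(rev(seq_len(i - 1)))
  rhs <- side_max(seq(i + 1, n, length.out = max(0, n - i)))
  min(lhs, rhs) - x[i]
}

#' Call TAD boundaries and TADs from a contact matrix
#'
#' Boundaries are local minima of the insulation track with prominence at
#' least `ins_delta` (log2 units) that also show a directionality-index
#' sign change (negative upstream, positive downstream) within +-2 bins.
#' TADs are the segments between consecutive boundaries (and chromosome
#' ends), scored as mean log2 obs/exp inside the domain triangle minus the
#' mean over equally sized flanking triangles. Ties between equal minima
#' break to the leftmost bin.
#'
#' @param mat a [contact_matrix()].
#' @param window_w insulation/DI window in bins (default 10; a wide
#'   window keeps the per-window count noise well below the gap between a
#'   domain-boundary dip, log2 of the domain enrichment, and the shallower
#'   dip a compartment transition produces).
#' @param min_size minimum TAD size in bins (default 5).
#' @param ins_delta minimum boundary prominence in log2 insulation units
#'   (default 1.2, between the compartment-transition dip and the
#'   domain-boundary dip so compartment flips are not called boundaries).
#' @param boundary_width width (bp) of emitted boundary intervals
#'   (default 15000).
#' @return list with `tads` ([features2d()] of kind `"tad"`; score column
#'   `score`), `boundaries` (interval table centred on boundary bins, with
#'   the bin index in `score`), `insulation` and `directionality` tracks.
#' @export
call_tads <- function(mat, window_w = 10, min_size = 5, ins_delta = 1.2,
                      boundary_width = 15000) {
  ins <- insulation_track(mat, window_w)
  di <- directionality_track(mat, window_w)
  x <- ins$values
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(x[i]) || is.na(x[i - 1]) || is.na(x[i + 1])) next
    if (!(x[i] < x[i - 1] && x[i] <= x[i + 1])) next  # leftmost of a tie
    if (.min_prominence(x, i) < ins_delta) next
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    dil <- di$values[lo:i]; dir <- di$values[i:hi]
    if (!any(dil < 0, na.rm = TRUE) || !any(dir > 0, na.rm = TRUE)) next
    cand <- c(cand, i)
  }
  res <- mat$resolution
  len <- n * res
  boundaries <- if (length(cand)) {
    ctr <- (cand - 0.5) * res  # centre of the boundary bin
    intervals(mat$chrom, pmax(0, ctr - boundary_width / 2),
              pmin(len, ctr + boundary_width / 2),
              name = paste0("boundary_", seq_along(cand)), score = cand - 1)
  } else empty_intervals()
  ## TADs between consecutive boundaries (chromosome ends included)
  cuts <- c(1, cand, n + 1)
  segs <- data.frame(from = utils::head(cuts, -1), to = utils::tail(cuts, -1) - 1)
  segs <- segs[segs$to - segs$from + 1 >= min_size & length(cand) > 0, , drop = FALSE]
  if (nrow(segs)) {
    oe <- obs_exp(mat)
    score <- vapply(seq_len(nrow(segs)), function(k)
      .tad_score(oe, segs$from[k], segs$to[k]), numeric(1))
    tads <- features2d(mat$chrom,
                       (segs$from - 1) * res, segs$from * res,
                       (segs$to - 1) * res, pmin(len, segs$to * res),
                       kind = "tad", name = paste0("tad_", seq_len(nrow(segs))))
    tads$score <- score
  } else {
    tads <- features2d(character(), numeric(), numeric(), numeric(), numeric(),
                       kind = "tad")
    tads$score <- numeric(0)
  }
  list(tads = tads, boundaries = boundaries, insulation = ins,
       directionality = di)
}

.tad_score <- function(oe, from, to, max_d = NULL) {
  n <- nrow(oe)
  idx <- from:to
  tri <- oe[idx, idx]
  inside <- mean(log2(tri[upper.tri(tri)]), na.rm = TRUE)
  w <- to - from + 1
  flanks <- c()
  if (from - w >= 1) flanks <- c(flanks, log2(oe[(from - w):(from - 1), idx]))
  if (to + w <= n) flanks <- c(flanks, log2(oe[idx, (to + 1):(to + w)]))
  fl <- if (length(flanks)) mean(flanks[is.finite(flanks)], na.rm = TRUE) else 0
  inside - fl
}

## sum of m over a centred (2r+1)^2 box at every pixel (zero-padded edges);
## separable: 1D box along rows, then along columns
.box_sum <- function(m, r) {
  n <- nrow(m)
  acc <- matrix(0, n, n)
  for (di in -r:r) {
    si <- max(1, 1 + di):min(n, n + di)
    acc[si - di, ] <- acc[si - di, ] + m[si, ]
  }
  out <- matrix(0, n, n)
  for (dj in -r:r) {
    sj <- max(1, 1 + dj):min(n, n + dj)
    out[, sj - dj] <- out[, sj - dj] + acc[, sj]
  }
  out
}

#' Call chromatin loops by focal enrichment over local background
#'
#' Counts are aggregated over a square window (default 3 x 3 bins,
#' mirroring callers that score a coarse window sliding at finer steps) and
#' compared against two expectations: the distance-decay expectation
#' `E(d)` summed over the window, and a local expectation obtained by
#' scaling the window expectation with the enrichment of a surrounding
#' donut annulus (so broad elevation such as domain interiors is absorbed
#' into the background). A candidate window at anchor distance within
#' `[min_dist, max_dist]` is a loop centre if its fold over both
#' expectations passes `fold_min` / `local_fold_min` and the Poisson
#' upper-tail p-values against both stay below `alpha` after BH correction.
#' The BH test count is the full number of searched pixels, not just the
#' fold-passing candidates — conditioning the correction on fold-selected
#' candidates would be anticonservative. Adjacent called pixels are merged
#' into one loop reported at the strongest pixel.
#'
#' @param mat a [contact_matrix()].
#' @param min_dist minimum anchor distance in bp (default 5 bins).
#' @param max_dist maximum anchor distance in bp (default 2 Mb, the usual
#'   focal-loop search range).
#' @param window aggregation window width in bins (odd; default 3).
#' @param fold_min minimum windowed obs / E(d) fold (default 2).
#' @param local_fold_min minimum fold over the donut-scaled local
#'   expectation (default 2).
#' @param alpha BH level for both Poisson tests (default 0.01; overlapping
#'   windows make called pixels correlated, so the pixel-level level is set
#'   below the intended loop-level false-discovery proportion).
#' @param anchor_width width (bp) of emitted anchors (default one bin).
#' @return [features2d()] of kind `"loop"` with columns `score` (windowed
#'   obs/expected), `count` (windowed count), `q_global`, `q_local`.
#' @export
call_loops <- function(mat, min_dist = NULL, max_dist = 2e6, window = 3,
                       fold_min = 2, local_fold_min = 2, alpha = 0.01,
                       anchor_width = NULL) {
  m <- mat$counts
  n <- nrow(m)
  res <- mat$resolution
  if (is.null(min_dist)) min_dist <- 5 * res
  if (is.null(anchor_width)) anchor_width <- res
  if (window %% 2 != 1) stop("window must be odd")
  r <- (window - 1) / 2
  prof <- expected_by_distance(mat)
  dmin <- ceiling(min_dist / res)
  dmax <- min(n - 1, floor(max_dist / res))
  dpix <- abs(row(m) - col(m))
  emat <- matrix(prof$expected[dpix + 1], n, n)
  w_obs <- .box_sum(m, r)
  w_exp <- .box_sum(emat, r)
  r_out <- 2 * window - 1  # donut outer Chebyshev radius
  donut_obs <- .box_sum(m, r_out) - w_obs
  donut_exp <- .box_sum(emat, r_out) - w_exp
  band <- upper.tri(m) & dpix >= dmin & dpix <= dmax
  n_tested <- sum(band)
  cand <- which(band & w_obs > 0 & w_exp > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(.empty_loops())
  obs <- w_obs[cand]
  ed <- w_exp[cand]
  dfold <- pmax(donut_obs[cand], 0) / pmax(donut_exp[cand], 1e-12)
  eloc <- ed * pmax(dfold, 1e-6)
  sel <- obs / ed >= fold_min & obs >= local_fold_min * eloc
  cand <- cand[sel, , drop = FALSE]
  if (nrow(cand) == 0) return(.empty_loops())
  obs <- obs[sel]; ed <- ed[sel]; eloc <- eloc[sel]
  p_global <- stats::ppois(obs - 1, ed, lower.tail = FALSE)
  p_local <- stats::ppois(obs - 1, eloc, lower.tail = FALSE)
  q_global <- stats::p.adjust(p_global, "BH", n = n_tested)
  q_local <- stats::p.adjust(p_local, "BH", n = n_tested)
  sel <- q_global < alpha & q_local < alpha
  cand <- cand[sel, , drop = FALSE]
  if (nrow(cand) == 0) return(.empty_loops())
  obs <- obs[sel]; ed <- ed[sel]
  qg <- q_global[sel]; ql <- q_local[sel]
  ## merge adjacent called pixels; strongest window represents the loop,
  ## ties broken by the centre-pixel count (sharpest focus)
  mc <- m[cand]
  ord <- order(-obs, -mc, cand[, 1], cand[, 2])
  cluster <- rep(NA_integer_, length(ord))
  centers <- list()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    assigned <- FALSE
    for (c in seq_along(centers)) {
      if (max(abs(centers[[c]][1] - i), abs(centers[[c]][2] - j)) <= window) {
        cluster[k] <- c; assigned <- TRUE; break
      }
    }
    if (!assigned) { centers[[length(centers) + 1]] <- c(i, j); cluster[k] <- length(centers) }
  }
  rep_idx <- vapply(seq_along(centers), function(c) {
    members <- which(cluster == c)
    members[order(-obs[members], -mc[members])[1]]
  }, integer(1))
  i <- cand[rep_idx, 1]; j <- cand[rep_idx, 2]
  half <- anchor_width / 2
  ctr1 <- (i - 0.5) * res; ctr2 <- (j - 0.5) * res
  loops <- features2d(mat$chrom, ctr1 - half, ctr1 + half,
                      ctr2 - half, ctr2 + half, kind = "loop",
                      name = paste0("loop_", seq_along(rep_idx)))
  loops$score <- obs[rep_idx] / ed[rep_idx]
  loops$count <- obs[rep_idx]
  loops$q_global <- qg[rep_idx]
  loops$q_local <- ql[rep_idx]
  loops[order(loops$start1, loops$start2), , drop = FALSE]
}

.empty_loops <- function() {
  l <- features2d(character(), numeric(), numeric(), numeric(), numeric())
  l$score <- l$count <- l$q_global <- l$q_local <- numeric(0)
  l
}

#' Merge 2D feature sets whose anchors nearly coincide
#'
#' Two features merge when both left-anchor and right-anchor midpoints lie
#' within `tolerance_bp`; merging is transitive (connected components) and
#' order-independent. Merged anchors are the unions of the member anchors;
#' member names are recorded in `members`.
#'
#' @param feature_sets list of [features2d()] tables of one kind.
#' @param tolerance_bp anchor distance tolerance in bp.
#' @return merged feature table with a `members` provenance column.
#' @export
merge_2d <- function(feature_sets, tolerance_bp) {
  if (is.data.frame(feature_sets)) feature_sets <- list(feature_sets)
  all <- do.call(rbind, lapply(feature_sets, function(f)
    f[, c("chrom", "start1", "end1", "start2", "end2", "kind", "name")]))
  if (is.null(all) || nrow(all) == 0)
    return(features2d(character(), numeric(), numeric(), numeric(), numeric()))
  if (length(unique(all$kind)) > 1) stop("cannot merge features of mixed kind")
  n <- nrow(all)
  mid1 <- (all$start1 + all$end1) / 2
  mid2 <- (all$start2 + all$end2) / 2
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(all$chrom, mid1, mid2)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (all$chrom[j] != all$chrom[i] || mid1[j] - mid1[i] > tolerance_bp) break
      if (abs(mid2[j] - mid2[i]) <= tolerance_bp) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(g) {
    data.frame(chrom = all$chrom[g[1]],
               start1 = min(all$start1[g]), end1 = max(all$end1[g]),
               start2 = min(all$start2[g]), end2 = max(all$end2[g]),
               kind = all$kind[g[1]],
               members = paste(sort(all$name[g]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start1, out$start2), , drop = FALSE]
  out$name <- paste0(out$kind[1], "_m", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start1", "end1", "start2", "end2", "kind", "name", "members")]
}
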
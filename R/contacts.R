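#' Scale a contact matrix to a target total
#'
#' Multiplies every entry by `target_total / total`, so the matrix total
#' (upper triangle, diagonal counted once) becomes exactly the target.
#' Relative contact structure (obs/exp) is invariant under this scaling.
#'
#' @param mat a [contact_matrix()].
#' @param target_total desired total contact count.
#' @return a depth-normalised `contact_matrix`.
#' @export
normalize_depth <- function(mat, target_total) {
  if (mat$total <= 0) stop("cannot normalise a zero-total matrix")
  contact_matrix(mat$chrom, mat$resolution,
                 mat$counts * (target_total / mat$total))
}

#' Expected contacts by genomic distance
#'
#' The distance-decay profile `E(d)` is the mean count over all bin pairs
#' separated by `d` bins (d = 0 .. n-1).
#'
#' @param mat a [contact_matrix()].
#' @return object of class `decay_profile` with fields `resolution` and
#'   `expected` (`expected[d+1]` is `E(d)`).
#' @export
expected_by_distance <- function(mat) {
  m <- mat$counts
  n <- nrow(m)
  e <- vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    mean(m[cbind(i, i + d)])
  }, numeric(1))
  structure(list(resolution = mat$resolution, expected = e),
            class = "decay_profile")
}

#' Observed/expected transform of a contact matrix
#'
#' Each entry is divided by the expected count at its distance; `0/0`
#' becomes `NA` (missing), a nonzero count over zero expectation cannot
#' occur because `E(d)` averages the observed counts.
#'
#' @param mat a [contact_matrix()].
#' @param profile optional [expected_by_distance()] profile; computed from
#'   `mat` when missing.
#' @return numeric matrix of obs/exp ratios.
#' @export
obs_exp <- function(mat, profile = NULL) {
  if (is.null(profile)) profile <- expected_by_distance(mat)
  n <- nrow(mat$counts)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- matrix(profile$expected[d + 1], n, n)
  oe <- mat$counts / e
  oe[e == 0 & mat$counts == 0] <- NA
  oe
}

.smooth_matrix <- function(m, w) {
  ## 2D moving average over a (2w+1)^2 window, NA-aware
  if (w < 1) return(m)
  n <- nrow(m)
  vals <- ifelse(is.na(m), 0, m)
  cnt <- 1 - is.na(m)
  smooth1 <- function(x) {
    ## running sum along rows then columns via filter
    k <- rep(1, 2 * w + 1)
    t(apply(t(apply(x, 1, function(r) stats::filter(r, k, sides = 2))),
            2, function(r) stats::filter(r, k, sides = 2)))
  }
  sv <- smooth1(vals); sc <- smooth1(cnt)
  out <- sv / sc
  out[is.na(m)] <- NA
  out
}

#' A/B compartment eigenvector (PC1)
#'
#' Computes the Pearson correlation matrix of the (optionally smoothed)
#' obs/exp columns and returns its leading eigenvector. The sign is
#' oriented so that the correlation with `orientation_track` (typically
#' H3K27ac coverage or gene density per bin) is non-negative. Bins with no
#' data are returned as `NA`.
#'
#' When the leading eigenvalue explains less than `min_eigen_share` of the
#' total variance the compartment signal is considered unreliable and the
#' result is flagged (`attr(track, "reliable") == FALSE`).
#'
#' @param mat a [contact_matrix()].
#' @param orientation_track optional numeric per-bin "active chromatin"
#'   signal used only to fix the sign.
#' @param smooth_bins half-width (bins) of the moving-average smoother
#'   applied to obs/exp before correlation; default 1 mirrors a smoothing
#'   window of twice the resolution.
#' @param min_eigen_share reliability threshold on the leading-eigenvalue
#'   share (default 0.1).
#' @return a [bin_track()] of PC1 values with attributes `eigen_share` and
#'   `reliable`.
#' @export
compartment_pc1 <- function(mat, orientation_track = NULL, smooth_bins = 1,
                            min_eigen_share = 0.1) {
  oe <- obs_exp(mat)
  n <- nrow(oe)
  usable <- which(colSums(mat$counts) > 0)
  if (length(usable) < 10) stop("fewer than 10 usable bins")
  oe <- .smooth_matrix(oe, smooth_bins)
  sub <- oe[usable, usable, drop = FALSE]
  sub[is.na(sub)] <- 1  # missing obs/exp carries no compartment signal
  cm <- suppressWarnings(stats::cor(sub))
  cm[is.na(cm)] <- 0
  eig <- eigen(cm, symmetric = TRUE)
  share <- eig$values[1] / sum(abs(eig$values))
  pc1 <- eig$vectors[, 1]
  vals <- rep(NA_real_, n)
  vals[usable] <- pc1
  if (!is.null(orientation_track)) {
    r <- suppressWarnings(stats::cor(vals, orientation_track,
                                     use = "complete.obs"))
    if (!is.na(r) && r < 0) vals <- -vals
  }
  out <- bin_track(mat$chrom, mat$resolution, vals)
  attr(out, "eigen_share") <- share
  attr(out, "reliable") <- share >= min_eigen_share
  out
}

#' Genome-wide binned matrix (inter- and intrachromosomal)
#'
#' Container for coarse whole-genome contact maps (e.g. 2.5-Mb bins) used
#' by interchromosomal comparisons.
#'
#' @param layout a [genome_layout()].
#' @param resolution bin size (bp).
#' @param counts symmetric matrix over the concatenated genome bins.
#' @return object of class `genome_matrix` with a `bins` table.
#' @export
genome_matrix <- function(layout, resolution, counts) {
  bins <- do.call(rbind, lapply(layout$chrom_names, function(ch) {
    nb <- n_bins(layout, ch, resolution)
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * resolution)
  }))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins)) stop("counts do not match genome binning")
  if (max(abs(counts - t(counts))) > 1e-9 * max(1, max(abs(counts))))
    stop("counts matrix is not symmetric")
  structure(list(layout = layout, resolution = resolution,
                 bins = bins, counts = counts, total = matrix_total(counts)),
            class = "genome_matrix")
}

.interchrom_mask <- function(gm) {
  outer(gm$bins$chrom, gm$bins$chrom, "!=") & upper.tri(gm$counts)
}

#' Interchromosomal log2-ratio map
#'
#' Both matrices are depth-normalised to the geometric mean of their totals
#' first; per bin pair the map is `log2((A + eps) / (B + eps))`.
#' Intrachromosomal cells are `NA`.
#'
#' @param gma,gmb [genome_matrix()] objects on the same layout/binning.
#' @param eps pseudocount per normalised bin (default 1).
#' @return matrix of log2 ratios (interchromosomal cells only).
#' @export
interchrom_ratio <- function(gma, gmb, eps = 1) {
  if (!identical(gma$bins, gmb$bins))
    stop("matrices have mismatched layouts or binnings")
  target <- sqrt(gma$total * gmb$total)
  a <- gma$counts * (target / gma$total)
  b <- gmb$counts * (target / gmb$total)
  r <- log2((a + eps) / (b + eps))
  inter <- outer(gma$bins$chrom, gma$bins$chrom, "!=")
  r[!inter] <- NA
  r
}

#' Pearson correlation of samples over interchromosomal bins
#'
#' Each sample's interchromosomal upper-triangle cells are vectorised
#' (after depth normalisation to a common total) and correlated pairwise.
#' Cells whose pooled count falls below `min_count` are excluded — a
#' declared stand-in for "significant" interchromosomal interactions.
#'
#' @param samples named list of [genome_matrix()] objects.
#' @param min_count pooled-count threshold for a cell to enter (default 0).
#' @return correlation matrix across samples.
#' @export
interchrom_sample_correlation <- function(samples, min_count = 0) {
  if (length(samples) < 2) stop("need at least two samples")
  bins0 <- samples[[1]]$bins
  for (s in samples) if (!identical(s$bins, bins0))
    stop("samples have mismatched layouts")
  mask <- .interchrom_mask(samples[[1]])
  target <- exp(mean(log(vapply(samples, function(s) s$total, numeric(1)))))
  vecs <- vapply(samples, function(s) (s$counts * (target / s$total))[mask],
                 numeric(sum(mask)))
  keep <- rowSums(vapply(samples, function(s) s$counts[mask], numeric(sum(mask)))) >= min_count
  stats::cor(vecs[keep, , drop = FALSE])
}
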
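#' Score loops and TADs across replicate samples
#'
#' Loop score: summed contacts in the anchor-pair window divided by the
#' summed distance expectation over the same window (obs/exp fold). TAD
#' score: mean log2 obs/exp inside the domain triangle. When
#' `normalize_total` is given every matrix is additionally rescaled to that
#' total and scored again, mirroring scoring with and without interaction
#' normalisation; raw and normalised score totals are recorded so custom
#' size factors can be derived.
#'
#' Features overlapping more than 50% unusable (zero-coverage) bins are
#' dropped and listed in `dropped`.
#'
#' @param samples named list of [contact_matrix()] objects on one
#'   chromosome; for multi-chromosome data score per chromosome and
#'   combine the tables.
#' @param features a [features2d()] table (one kind).
#' @param anchor_window window width (bp) centred on each anchor midpoint
#'   used for loop scoring (default 15000).
#' @param normalize_total optional target total for the normalised pass.
#' @return object of class `domain_score_table`: fields `features`,
#'   `raw` and `norm` score matrices (feature x sample), `raw_totals`,
#'   `norm_totals`, `dropped`.
#' @export
score_features <- function(samples, features, anchor_window = 15000,
                           normalize_total = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples))) names(samples) <- paste0("s", seq_along(samples))
  kinds <- unique(features$kind)
  if (length(kinds) > 1) stop("features must be of a single kind")
  ## The distance expectation is evaluated at a fixed reference scale (the
  ## normalisation target when given, else each sample's own total), so the
  ## raw pass keeps depth in the scores and the normalised pass removes it;
  ## raw and normalised scores then differ by exactly total_s / target.
  raw <- vapply(samples, function(s)
    .score_one(s, features, anchor_window,
               reference_total = normalize_total %||% s$total),
    numeric(nrow(features)))
  raw <- matrix(raw, nrow = nrow(features),
                dimnames = list(features$name, names(samples)))
  norm <- NULL
  if (!is.null(normalize_total)) {
    norm <- vapply(samples, function(s)
      .score_one(normalize_depth(s, normalize_total), features, anchor_window,
                 reference_total = normalize_total),
      numeric(nrow(features)))
    norm <- matrix(norm, nrow = nrow(features),
                   dimnames = dimnames(raw))
  }
  usable <- .feature_usable_fraction(samples, features, anchor_window)
  keep <- usable >= 0.5
  structure(list(features = features[keep, , drop = FALSE],
                 raw = raw[keep, , drop = FALSE],
                 norm = if (!is.null(norm)) norm[keep, , drop = FALSE],
                 raw_totals = colSums(raw[keep, , drop = FALSE]),
                 norm_totals = if (!is.null(norm)) colSums(norm[keep, , drop = FALSE]),
                 dropped = features$name[!keep]),
            class = "domain_score_table")
}

#' @export
print.domain_score_table <- function(x, ...) {
  cat("domain_score_table:", nrow(x$raw), "features x", ncol(x$raw),
      "samples (", x$features$kind[1], ")\n")
  invisible(x)
}

.feature_bins <- function(feat, res, n, anchor_window) {
  half <- anchor_window / 2
  mid1 <- (feat["start1"] + feat["end1"]) / 2
  mid2 <- (feat["start2"] + feat["end2"]) / 2
  b1 <- max(1, floor((mid1 - half) / res) + 1):min(n, ceiling((mid1 + half) / res))
  b2 <- max(1, floor((mid2 - half) / res) + 1):min(n, ceiling((mid2 + half) / res))
  list(b1 = b1, b2 = b2)
}

.score_one <- function(mat, features, anchor_window, reference_total = NULL) {
  m <- mat$counts
  n <- nrow(m)
  res <- mat$resolution
  prof <- expected_by_distance(mat)
  if (!is.null(reference_total))
    prof$expected <- prof$expected * (reference_total / mat$total)
  oe <- NULL
  vapply(seq_len(nrow(features)), function(k) {
    if (features$kind[k] == "tad") {
      ## TAD scores are obs/exp ratios of the matrix itself (depth-free)
      if (is.null(oe)) oe <<- obs_exp(mat)
      from <- floor(features$start1[k] / res) + 1
      to <- min(n, ceiling(features$end2[k] / res))
      idx <- from:to
      tri <- oe[idx, idx]
      v <- log2(tri[upper.tri(tri)])
      return(mean(v[is.finite(v)], na.rm = TRUE))
    }
    fb <- .feature_bins(c(start1 = features$start1[k], end1 = features$end1[k],
                          start2 = features$start2[k], end2 = features$end2[k]),
                        res, n, anchor_window)
    obs <- sum(m[fb$b1, fb$b2, drop = FALSE])
    ed <- sum(prof$expected[abs(outer(fb$b1, fb$b2, "-")) + 1])
    if (ed == 0) return(NA_real_)
    obs / ed
  }, numeric(1))
}

.feature_usable_fraction <- function(samples, features, anchor_window) {
  pooled <- Reduce(`+`, lapply(samples, function(s) s$counts))
  cov <- colSums(pooled) > 0
  res <- samples[[1]]$resolution
  n <- nrow(pooled)
  vapply(seq_len(nrow(features)), function(k) {
    fb <- .feature_bins(c(start1 = features$start1[k], end1 = features$end1[k],
                          start2 = features$start2[k], end2 = features$end2[k]),
                        res, n, anchor_window)
    mean(cov[unique(c(fb$b1, fb$b2))])
  }, numeric(1))
}

#' Custom per-sample size factors from raw vs normalised score totals
#'
#' `SF_s = total raw score of sample s / total normalised score of sample
#' s`. Dividing raw scores by these factors removes depth differences while
#' keeping the scale of the normalised pass; they are meant to be supplied
#' as external size factors to differential testing.
#'
#' @param table a `domain_score_table` scored with `normalize_total`, or a
#'   list with `raw_totals` and `norm_totals`.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(table) {
  if (is.null(table$norm_totals))
    stop("size factors require both raw and normalised score totals")
  if (any(table$norm_totals == 0)) stop("zero normalised total")
  table$raw_totals / table$norm_totals
}

#' Differential domain analysis
#'
#' Raw per-sample scores are divided by the supplied size factors,
#' log2-transformed with a pseudocount of 0.5 and tested per feature for
#' `|logFC| > log2(fc_threshold)` with the threshold-aware Welch engine
#' (see [differential_test()]); BH correction across features.
#'
#' @param table a `domain_score_table`.
#' @param design per-sample condition labels (two levels).
#' @param fc_threshold fold-change the effect must exceed (default 1:
#'   plain Welch test of any change, the convention for domain-score
#'   comparisons; raise it to demand a minimum fold).
#' @param sf optional size factors (default from [size_factors()], or 1s).
#' @return data.frame with `name`, `logFC`, `p`, `q`, plus the feature
#'   anchors; logFC is condition 2 minus condition 1 (level order).
#' @export
differential_domains <- function(table, design, fc_threshold = 1, sf = NULL) {
  if (is.null(sf))
    sf <- if (!is.null(table$norm_totals)) size_factors(table)
          else stats::setNames(rep(1, ncol(table$raw)), colnames(table$raw))
  scores <- sweep(table$raw, 2, sf, "/")
  res <- welch_treat(log2(scores + 0.5), design, tau = log2(fc_threshold))
  out <- cbind(table$features[, c("chrom", "start1", "end1", "start2", "end2",
                                  "kind", "name")],
               res)
  rownames(out) <- NULL
  out
}

#' Compare loop size distributions between two feature sets
#'
#' Loop size is the anchor separation `start2 - start1`. Returns the
#' two-sided Mann-Whitney test and quartile summaries.
#'
#' @param set_a,set_b [features2d()] tables.
#' @return list with `p`, `U`, `sizes_a`, `sizes_b`, `quartiles_a`,
#'   `quartiles_b`.
#' @export
loop_size_comparison <- function(set_a, set_b) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) stop("empty feature set")
  sa <- set_a$start2 - set_a$start1
  sb <- set_b$start2 - set_b$start1
  if (any(sa <= 0) || any(sb <= 0)) stop("non-positive loop size")
  mw <- mann_whitney_u(sa, sb)
  list(p = mw$p, U = mw$U,
       sizes_a = sa, sizes_b = sb,
       quartiles_a = stats::quantile(sa, c(.25, .5, .75)),
       quartiles_b = stats::quantile(sb, c(.25, .5, .75)))
}
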
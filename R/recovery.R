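#' Recovery of planted TAD boundaries
#'
#' Matches called boundary bins against the truth within a bin tolerance.
#' Recall = matched truth boundaries / planted; precision = calls matching
#' some truth boundary / calls.
#'
#' @param calls named list (per chromosome) of [call_tads()] results, or a
#'   single result for a one-chromosome comparison.
#' @param truth a [sim_truth()].
#' @param tolerance_bins match tolerance (default 1).
#' @return list with `recall`, `precision`, `n_truth`, `n_called`.
#' @export
boundary_recovery <- function(calls, truth, tolerance_bins = 1) {
  if (!is.null(calls$boundaries)) calls <- list(calls)
  if (is.null(names(calls)))
    names(calls) <- truth$layout$chrom_names[seq_along(calls)]
  matched_truth <- 0; n_truth <- 0; matched_call <- 0; n_call <- 0
  for (ch in names(calls)) {
    tb <- truth$boundaries[[ch]]
    cb <- calls[[ch]]$boundaries$score  # 0-based boundary bin index
    n_truth <- n_truth + length(tb)
    n_call <- n_call + length(cb)
    if (length(tb) && length(cb)) {
      ## called minima sit on the last bin of the upstream domain or the
      ## first of the downstream one; truth records the downstream bin
      dmat <- abs(outer(tb, cb, "-"))
      dmat2 <- abs(outer(tb - 1, cb, "-"))
      dmin <- pmin(dmat, dmat2)
      matched_truth <- matched_truth + sum(apply(dmin, 1, min) <= tolerance_bins)
      matched_call <- matched_call + sum(apply(dmin, 2, min) <= tolerance_bins)
    }
  }
  list(recall = matched_truth / max(1, n_truth),
       precision = matched_call / max(1, n_call),
       n_truth = n_truth, n_called = n_call)
}

#' Recovery of planted loops
#'
#' A call matches a planted loop when both anchor bins are within the
#' Chebyshev tolerance of the planted pixel.
#'
#' @param loops called loops (single table or per-chromosome list).
#' @param truth a [sim_truth()].
#' @param tolerance_bins Chebyshev tolerance in bins (default 2; planted
#'   loop signal spans a 3x3 neighbourhood).
#' @return list with `recall`, `fdp` (false-discovery proportion),
#'   `n_truth`, `n_called`, `matched` (truth loop names recovered).
#' @export
loop_recovery <- function(loops, truth, tolerance_bins = 2) {
  if (is.list(loops) && !is.data.frame(loops))
    loops <- do.call(rbind, loops)
  res <- truth$resolution
  tl <- truth$loops
  n_call <- nrow(loops)
  hit_truth <- rep(FALSE, nrow(tl))
  hit_call <- rep(FALSE, n_call)
  if (n_call) {
    cb1 <- floor((loops$start1 + loops$end1) / 2 / res)
    cb2 <- floor((loops$start2 + loops$end2) / 2 / res)
    for (t in seq_len(nrow(tl))) {
      same <- loops$chrom == tl$chrom[t]
      ok <- same & pmax(abs(cb1 - tl$bin1[t]), abs(cb2 - tl$bin2[t])) <=
        tolerance_bins
      if (any(ok)) { hit_truth[t] <- TRUE; hit_call[ok] <- TRUE }
    }
  }
  list(recall = mean(hit_truth), fdp = if (n_call) mean(!hit_call) else 0,
       n_truth = nrow(tl), n_called = n_call,
       matched = tl$name[hit_truth])
}

#' Pool replicate contact maps
#'
#' Sums per-chromosome counts across samples (the donor-merging step used
#' before feature identification).
#'
#' @param maps list of per-chromosome contact-map lists.
#' @return one per-chromosome contact-map list.
#' @export
pool_maps <- function(maps) {
  chroms <- names(maps[[1]])
  out <- lapply(chroms, function(ch) {
    contact_matrix(ch, maps[[1]][[ch]]$resolution,
                   Reduce(`+`, lapply(maps, function(m) m[[ch]]$counts)))
  })
  stats::setNames(out, chroms)
}
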
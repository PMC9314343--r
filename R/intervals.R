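#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `name`, `score`, `strand`, in 0-based half-open coordinates. This
#' constructor validates and recycles its arguments.
#'
#' @param chrom chromosome identifiers.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param name feature names (default `"."`).
#' @param score numeric scores (default `NA`).
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param layout optional [genome_layout()]; if given, intervals are checked
#'   to fit within chromosome bounds.
#' @return data.frame of intervals.
#' @export
intervals <- function(chrom, start, end, name = ".", score = NA_real_,
                      strand = ".", layout = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df, layout)
  df
}

validate_intervals <- function(df, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (!is.null(layout)) {
    for (ch in unique(df$chrom)) {
      len <- chrom_length(layout, ch)
      if (any(df$end[df$chrom == ch] > len))
        stop("interval exceeds length of ", ch)
    }
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

## 0-based half-open -> IRanges (1-based closed); zero-length touch becomes
## a genuinely empty intersection, preserving the half-open convention.
.as_iranges <- function(df) IRanges::IRanges(start = df$start + 1, end = df$end)

#' Overlap two interval sets
#'
#' Half-open overlap semantics: `[a,b)` overlaps `[c,d)` iff `a < d` and
#' `c < b`; intervals that merely touch do not overlap. Delegates to
#' IRanges internally, per chromosome.
#'
#' @param query,subject interval data frames (see [intervals()]).
#' @param mode `"any"` returns a data.frame of overlapping
#'   (query_idx, subject_idx) pairs; `"count"` returns, per query interval,
#'   the number of overlapping subject intervals; `"subtract"` returns the
#'   query intervals minus the base pairs covered by the subject.
#' @return See `mode`.
#' @export
overlap_intervals <- function(query, subject, mode = c("any", "count", "subtract")) {
  mode <- match.arg(mode)
  validate_intervals(query); validate_intervals(subject)
  if (mode %in% c("any", "count")) {
    pairs <- data.frame(query_idx = integer(), subject_idx = integer())
    if (nrow(query) && nrow(subject)) {
      for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
        qi <- which(query$chrom == ch); si <- which(subject$chrom == ch)
        hits <- IRanges::findOverlaps(.as_iranges(query[qi, ]),
                                      .as_iranges(subject[si, ]))
        if (length(hits))
          pairs <- rbind(pairs, data.frame(
            query_idx = qi[S4Vectors::queryHits(hits)],
            subject_idx = si[S4Vectors::subjectHits(hits)]))
      }
      pairs <- pairs[order(pairs$query_idx, pairs$subject_idx), , drop = FALSE]
      rownames(pairs) <- NULL
    }
    if (mode == "any") return(pairs)
    return(tabulate(pairs$query_idx, nbins = nrow(query)))
  }
  ## subtract
  if (nrow(query) == 0) return(empty_intervals())
  out <- vector("list", 0)
  for (ch in unique(query$chrom)) {
    qdf <- query[query$chrom == ch, , drop = FALSE]
    sdf <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sdf) == 0) { out[[length(out) + 1]] <- qdf; next }
    cov <- IRanges::reduce(.as_iranges(sdf))
    for (k in seq_len(nrow(qdf))) {
      kept <- IRanges::setdiff(.as_iranges(qdf[k, ]), cov)
      if (length(kept) == 0) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = IRanges::start(kept) - 1, end = IRanges::end(kept),
        name = qdf$name[k] %||% ".", score = qdf$score[k] %||% NA_real_,
        strand = qdf$strand[k] %||% ".", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_intervals())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct paired-anchor 2D features (loops or TADs)
#'
#' @param chrom chromosome (both anchors on the same chromosome).
#' @param start1,end1 left anchor, 0-based half-open.
#' @param start2,end2 right anchor; `start1 <= start2` enforced by swapping.
#' @param kind `"loop"` or `"tad"`.
#' @param name feature identifiers.
#' @return data.frame of 2D features.
#' @export
features2d <- function(chrom, start1, end1, start2, end2,
                       kind = "loop", name = NULL) {
  n <- length(start1)
  if (is.null(name)) name <- paste0(kind, "_", seq_len(max(n, 1)))[seq_len(n)]
  if (n == 0) {
    chrom <- character(0); kind <- character(0); name <- character(0)
  }
  df <- data.frame(chrom = as.character(chrom),
                   start1 = as.numeric(start1), end1 = as.numeric(end1),
                   start2 = as.numeric(start2), end2 = as.numeric(end2),
                   kind = as.character(kind), name = as.character(name),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start1 >= df$end1 | df$start2 >= df$end2))
      stop("degenerate anchor(s): need start < end on both anchors")
    swap <- df$start1 > df$start2
    if (any(swap)) {
      tmp <- df[swap, c("start1", "end1")]
      df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
      df[swap, c("start2", "end2")] <- tmp
    }
  }
  df
}

#' Anchors of 2D features as an interval table
#'
#' @param feats features from [features2d()].
#' @param which `"both"`, `"left"` or `"right"`.
#' @return interval data.frame; `name` records feature and side.
#' @export
feature_anchors <- function(feats, which = c("both", "left", "right")) {
  which <- match.arg(which)
  left <- intervals(feats$chrom, feats$start1, feats$end1,
                    name = paste0(feats$name, "_L"))
  right <- intervals(feats$chrom, feats$start2, feats$end2,
                     name = paste0(feats$name, "_R"))
  switch(which, left = left, right = right, both = rbind(left, right))
}
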
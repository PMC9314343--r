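#' Position weight matrices (log-odds)
#'
#' A PWM is a 4 x L matrix of log-odds scores versus background base
#' frequencies (rows A, C, G, T). `pwm_from_counts` converts a count or
#' frequency matrix with a pseudocount; `read_jaspar` parses JASPAR-style
#' text (`>name` header, four `A [ ... ]` rows).
#'
#' @param counts 4 x L count/frequency matrix (rows A, C, G, T).
#' @param name motif name.
#' @param background background base frequencies (default uniform 0.25).
#' @param pseudocount added per cell before normalising (default 0.01).
#' @param threshold detection threshold on the log-odds score.
#' @return object of class `pwm`.
#' @export
pwm_from_counts <- function(counts, name = "motif",
                            background = rep(0.25, 4), pseudocount = 0.01,
                            threshold = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  w <- log2(p / background)
  rownames(w) <- c("A", "C", "G", "T")
  pwm(w, name = name, threshold = threshold)
}

#' @rdname pwm_from_counts
#' @param w 4 x L log-odds matrix.
#' @export
pwm <- function(w, name = "motif", threshold = 0) {
  w <- as.matrix(w)
  if (nrow(w) != 4 || ncol(w) < 2) stop("PWM must be 4 x L with L >= 2")
  if (any(!is.finite(w))) stop("PWM entries must be finite")
  rownames(w) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = w, length = ncol(w),
                 threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$name, "length", x$length, "threshold", x$threshold, "\n")
  invisible(x)
}

#' @rdname pwm_from_counts
#' @param path JASPAR-style text file.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01,
                        threshold = 0) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  out <- list()
  for (h in seq_along(heads)) {
    nm <- sub("^>\\s*", "", lines[heads[h]])
    nm <- strsplit(nm, "[ \t]+")[[1]][1]
    rows <- lines[(heads[h] + 1):(heads[h] + 4)]
    m <- t(vapply(rows, function(r) {
      r <- gsub("^[ACGT]\\s*\\[?|\\]$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("^[ACGT]\\s*\\[?|\\]$", "", rows[1])), "\\s+")[[1]]))))
    out[[nm]] <- pwm_from_counts(m, name = nm, background = background,
                                 pseudocount = pseudocount,
                                 threshold = threshold)
  }
  out
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.encode_seq <- function(s) {
  v <- .BASE_CODE[strsplit(toupper(s), "")[[1]]]
  v[is.na(v)] <- 5L
  unname(v)
}

.revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(s, "")[[1]]),
                                           collapse = ""))
}

## score every offset of an encoded sequence on one strand; N scores 0
.scan_one_strand <- function(code, wmat) {
  L <- ncol(wmat)
  n <- length(code)
  if (n < L) return(numeric(0))
  w5 <- rbind(wmat, 0)  # row 5: N contributes 0 log-odds
  vapply(seq_len(n - L + 1), function(o)
    sum(w5[cbind(code[o:(o + L - 1)], seq_len(L))]), numeric(1))
}

#' Scan sequences with a PWM on both strands
#'
#' The score of a placement is the sum of per-position log-odds; `N` bases
#' contribute 0. Reverse-strand hits are reported in forward coordinates.
#'
#' @param sequences named character vector of sequences (or a Biostrings
#'   `DNAStringSet`).
#' @param pwm a [pwm()].
#' @param threshold minimum reported score (default the PWM's threshold).
#' @return data.frame of hits: `seqname`, `start` (0-based), `end`,
#'   `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold = NULL) {
  sequences <- .as_char_seqs(sequences)
  if (is.null(threshold)) threshold <- pwm$threshold
  L <- pwm$length
  out <- list()
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    fw <- .scan_one_strand(.encode_seq(s), pwm$matrix)
    rv <- .scan_one_strand(.encode_seq(.revcomp(s)), pwm$matrix)
    n <- nchar(s)
    if (length(fw)) {
      hit <- which(fw >= threshold)
      if (length(hit))
        out[[length(out) + 1]] <- data.frame(
          seqname = nm, start = hit - 1, end = hit - 1 + L,
          strand = "+", score = fw[hit], stringsAsFactors = FALSE)
      hit <- which(rv >= threshold)
      if (length(hit))
        out[[length(out) + 1]] <- data.frame(
          seqname = nm, start = n - (hit - 1) - L, end = n - (hit - 1),
          strand = "-", score = rv[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seqname = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$seqname, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_char_seqs <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  as.list(sequences)
}

#' Best PWM score of a sequence (both strands, no threshold)
#'
#' @param sequence a single sequence.
#' @param pwm a [pwm()].
#' @return maximum log-odds score over positions and strands, or `NA` when
#'   the sequence is shorter than the motif.
#' @export
best_motif_score <- function(sequence, pwm) {
  s <- .as_char_seqs(sequence)[[1]]
  if (nchar(s) < pwm$length) return(NA_real_)
  max(.scan_one_strand(.encode_seq(s), pwm$matrix),
      .scan_one_strand(.encode_seq(.revcomp(s)), pwm$matrix))
}

#' Hypergeometric motif enrichment in target vs background peaks
#'
#' Universe = target plus background peaks; per motif, `k` targets carrying
#' at least one hit are tested against hypergeometric(N, K, n); BH across
#' motifs.
#'
#' @param target_peaks,background_peaks interval tables (disjoint sets).
#' @param hit_map named list (per motif) of hit intervals, or a data.frame
#'   of hits with a `motif` column and `chrom`/`start`/`end`.
#' @return data.frame per motif: `motif`, `frac_target`, `frac_background`,
#'   `k`, `K`, `p`, `q`.
#' @export
motif_enrichment <- function(target_peaks, background_peaks, hit_map) {
  if (nrow(target_peaks) == 0) stop("empty target set")
  if (is.data.frame(hit_map))
    hit_map <- split(hit_map, hit_map$motif)
  n <- nrow(target_peaks); N <- n + nrow(background_peaks)
  rows <- lapply(names(hit_map), function(mn) {
    hits <- hit_map[[mn]]
    kt <- sum(overlap_intervals(target_peaks, hits, "count") > 0)
    kb <- sum(overlap_intervals(background_peaks, hits, "count") > 0)
    K <- kt + kb
    data.frame(motif = mn, frac_target = kt / n,
               frac_background = kb / max(1, N - n),
               k = kt, K = K,
               p = hypergeom_test(N, K, n, kt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' CTCF motif orientation at loop anchors
#'
#' One representative hit per anchor: the highest-scoring overlapping hit
#' (ties: larger |score|, then leftmost start). Loop categories follow the
#' extrusion convention: left `+` / right `-` is convergent, same strands
#' tandem, left `-` / right `+` divergent; loops with a hit on one anchor
#' only are `single`, otherwise `none`.
#'
#' @param loops [features2d()] table of loops.
#' @param ctcf_hits hit table from [scan_pwm()] with genomic coordinates
#'   (`chrom` or `seqname` naming the chromosome), or BED6-style intervals.
#' @param window_bp optional widening of each anchor before overlap
#'   (default 0).
#' @return list with `categories` (per loop) and `fractions`.
#' @export
ctcf_orientation <- function(loops, ctcf_hits, window_bp = 0) {
  if (!"chrom" %in% names(ctcf_hits)) {
    ctcf_hits$chrom <- ctcf_hits$seqname
  }
  best_strand <- function(chrom, lo, hi) {
    h <- ctcf_hits[ctcf_hits$chrom == chrom & ctcf_hits$end > lo &
                     ctcf_hits$start < hi, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h <- h[order(-h$score, -abs(h$score), h$start), , drop = FALSE]
    h$strand[1]
  }
  cats <- vapply(seq_len(nrow(loops)), function(k) {
    sl <- best_strand(loops$chrom[k], loops$start1[k] - window_bp / 2,
                      loops$end1[k] + window_bp / 2)
    sr <- best_strand(loops$chrom[k], loops$start2[k] - window_bp / 2,
                      loops$end2[k] + window_bp / 2)
    if (is.na(sl) && is.na(sr)) return("none")
    if (is.na(sl) || is.na(sr)) return("single")
    if (sl == "+" && sr == "-") return("convergent")
    if (sl == "-" && sr == "+") return("divergent")
    "tandem"
  }, character(1))
  lv <- c("convergent", "tandem", "divergent", "single", "none")
  fr <- table(factor(cats, levels = lv)) / max(1, length(cats))
  list(categories = stats::setNames(cats, loops$name), fractions = fr)
}

#' Motif-class co-association network
#'
#' A peak is positive for a class when at least one member motif hits it.
#' Node size = percent of peaks positive for the class; edge weight =
#' percent of peaks positive for both classes. The co-occurrence matrix is
#' symmetric with node percentages on the diagonal, and every edge is
#' bounded by its nodes.
#'
#' @param peaks interval table.
#' @param class_hits named list (per class) of hit interval tables.
#' @return list with `nodes` (percent), `edges` (data.frame), `matrix`.
#' @export
coassociation_network <- function(peaks, class_hits) {
  if (nrow(peaks) == 0) stop("zero peaks")
  flags <- vapply(class_hits, function(h)
    overlap_intervals(peaks, h, "count") > 0, logical(nrow(peaks)))
  flags <- matrix(flags, nrow = nrow(peaks),
                  dimnames = list(NULL, names(class_hits)))
  nodes <- 100 * colMeans(flags)
  cmat <- 100 * crossprod(flags) / nrow(peaks)
  classes <- names(class_hits)
  ed <- expand.grid(from = classes, to = classes, stringsAsFactors = FALSE)
  ed <- ed[match(ed$from, classes) < match(ed$to, classes), , drop = FALSE]
  ed$weight <- cmat[cbind(ed$from, ed$to)]
  rownames(ed) <- NULL
  list(nodes = nodes, edges = ed, matrix = cmat)
}
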
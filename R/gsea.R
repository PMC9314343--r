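#' Deterministically ranked statistics
#'
#' Orders features by decreasing signed statistic; ties break by feature id
#' (lexicographic), so barcodes and running sums are reproducible.
#'
#' @param ids unique feature identifiers.
#' @param stat signed per-feature statistic (e.g. logFC or moderated t).
#' @return object of class `ranked_stat` (data.frame `id`, `stat`, ordered).
#' @export
ranked_stat <- function(ids, stat) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("feature ids must be unique")
  if (length(ids) != length(stat)) stop("ids and stat lengths differ")
  ord <- order(-stat, ids)
  structure(data.frame(id = ids[ord], stat = as.numeric(stat)[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_stat", "data.frame"))
}

## Weighted Kolmogorov-Smirnov running sum; returns the signed maximum
## deviation and the running values. weight_p = 0 uses equal hit steps.
.gsea_es <- function(stat, inset, weight_p = 1) {
  n <- length(stat)
  nh <- sum(inset)
  if (nh == 0 || nh == n)
    return(list(es = 0, running = rep(0, n)))  # no contrast to measure
  w <- abs(stat)^weight_p
  hit <- ifelse(inset, w, 0)
  denom_hit <- sum(hit)
  if (denom_hit == 0) hit_step <- ifelse(inset, 1 / nh, 0)
  else hit_step <- hit / denom_hit
  miss_step <- ifelse(inset, 0, 1 / (n - nh))
  run <- cumsum(hit_step - miss_step)
  i <- which.max(abs(run))
  list(es = run[i], running = run)
}

#' Ranked set enrichment (permutation ES/NES)
#'
#' GSEA-style running-sum enrichment of feature sets within a ranked list:
#' hits increment by `|stat|^weight_p` (normalised over the set), misses
#' decrement by `1/(n - set size)`; ES is the signed maximum deviation.
#' The null distribution comes from `nperm` random same-size sets drawn
#' under the given seed; NES divides ES by the mean |null ES| of matching
#' sign, and the permutation p-value uses +1 smoothing. BH correction is
#' applied across sets.
#'
#' @param ranked a [ranked_stat()].
#' @param sets named list of id vectors (subsets of `ranked$id`).
#' @param weight_p hit-weight exponent (default 1; 0 = classic KS).
#' @param nperm number of permutations (default 1000, >= 100).
#' @param seed integer seed for the permutation null.
#' @return data.frame with one row per set: `set`, `size`, `ES`, `NES`,
#'   `p`, `q`, `direction`; attributes `barcodes` (rank positions of set
#'   members) and `leading_edge` carry plotting/leading-edge data.
#' @export
ranked_set_enrichment <- function(ranked, sets, weight_p = 1, nperm = 1000,
                                  seed = 1) {
  stopifnot(inherits(ranked, "ranked_stat"))
  if (nperm < 100) stop("nperm must be >= 100")
  n <- nrow(ranked)
  keep <- vapply(sets, function(s) {
    s <- intersect(s, ranked$id)
    length(s) >= 2 && length(s) < n
  }, logical(1))
  if (any(!keep))
    warning("skipping set(s) with fewer than 2 matching features: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  barcodes <- list(); leading <- list()
  rows <- lapply(names(sets), function(nm) {
    ids <- intersect(sets[[nm]], ranked$id)
    inset <- ranked$id %in% ids
    obs <- .gsea_es(ranked$stat, inset, weight_p)
    k <- sum(inset)
    null_es <- with_seed(seed + utf8_seed(nm), {
      vapply(seq_len(nperm), function(b) {
        ins <- rep(FALSE, n)
        ins[sample.int(n, k)] <- TRUE
        .gsea_es(ranked$stat, ins, weight_p)$es
      }, numeric(1))
    })
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(sign(null_es) == sign(obs$es) &
                    abs(null_es) >= abs(obs$es))) / (1 + length(null_es))
    pos <- which(inset)
    barcodes[[nm]] <<- pos
    peak <- which.max(abs(obs$running))
    leading[[nm]] <<- if (obs$es >= 0) ranked$id[intersect(pos, seq_len(peak))]
                      else ranked$id[intersect(pos, peak:n)]
    data.frame(set = nm, size = k, ES = obs$es, NES = nes, p = p,
               direction = if (obs$es >= 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set = character(), size = integer(),
                                      ES = numeric(), NES = numeric(),
                                      p = numeric(), q = numeric(),
                                      direction = character()))
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "barcodes") <- barcodes
  attr(out, "leading_edge") <- leading
  out
}

#' Competitive rank test of a feature set within a ranked list
#'
#' Wilcoxon rank-sum comparison of the set's statistics against the
#' complement; a declared stand-in for rotation tests, calibrated only
#' under exchangeability across features.
#'
#' @param ranked a [ranked_stat()].
#' @param set vector of feature ids, `2 <= |set| < n`.
#' @return list with `direction` (`"up"`/`"down"`), two-sided `p`, `U`.
#' @export
competitive_rank_test <- function(ranked, set) {
  stopifnot(inherits(ranked, "ranked_stat"))
  inset <- ranked$id %in% set
  k <- sum(inset)
  if (k < 2 || k >= nrow(ranked)) stop("need 2 <= |set| < n matching features")
  mw <- mann_whitney_u(ranked$stat[inset], ranked$stat[!inset])
  dir <- if (stats::median(ranked$stat[inset]) >=
               stats::median(ranked$stat[!inset])) "up" else "down"
  list(direction = dir, p = mw$p, U = mw$U)
}

## run code under a temporary RNG state; restores the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

## small deterministic offset from a string, to decorrelate per-set nulls
utf8_seed <- function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 10000L
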
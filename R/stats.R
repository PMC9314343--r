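#' Median-of-ratios normalisation factors
#'
#' Per-feature reference = geometric mean across samples over features
#' nonzero in every sample; per-sample factor = median of counts/reference,
#' rescaled to geometric mean 1. Falls back to total-count factors (with a
#' warning) when no feature is nonzero in all samples. Factors are
#' invariant to adding all-zero features.
#'
#' @param table a [count_table()] or counts matrix.
#' @return named numeric factors with geometric mean 1.
#' @export
normalize_counts <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no feature nonzero in all samples; using total-count factors")
    f <- colSums(counts)
  } else {
    lg <- log(counts[ok, , drop = FALSE])
    ref <- exp(rowMeans(lg))
    f <- apply(counts[ok, , drop = FALSE] / ref, 2, stats::median)
  }
  f / exp(mean(log(f)))
}

## Threshold-aware Welch test on a matrix of log2 values (features x samples).
## TREAT-style composite p against H0: |logFC| <= tau, evaluated at the
## null boundary: p = P(T >= (|d|-tau)/s) + P(T <= -(|d|+tau)/s), which
## reduces exactly to the two-sided Welch test at tau = 0 (when
## moderate = FALSE). With moderate = TRUE the per-feature pooled variance
## is shrunk toward a common value with an empirical-Bayes prior whose
## weight d0 is estimated by matching the spread of log variances to the
## scaled-F model (the moderation every count-based engine in this field
## applies); the t reference gains d0 degrees of freedom.
welch_treat <- function(logmat, design, tau = 0, moderate = FALSE) {
  design <- as.factor(design)
  lev <- levels(design)
  if (length(lev) != 2) stop("design must have exactly two levels")
  ia <- which(design == lev[1]); ib <- which(design == lev[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 replicates per condition")
  a <- logmat[, ia, drop = FALSE]; b <- logmat[, ib, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  na <- length(ia); nb <- length(ib)
  d <- mb - ma
  if (moderate) {
    dfres <- na + nb - 2
    s2 <- ((na - 1) * va + (nb - 1) * vb) / dfres
    sq <- .squeeze_var(s2, dfres)
    se2 <- sq$var * (1 / na + 1 / nb)
    df <- rep(dfres + sq$d0, length(d))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  se <- sqrt(se2)
  p <- rep(NA_real_, length(d))
  okv <- se > 0 & is.finite(se)
  tr <- (abs(d[okv]) - tau) / se[okv]
  tl <- (abs(d[okv]) + tau) / se[okv]
  p[okv] <- stats::pt(tr, df[okv], lower.tail = FALSE) +
    stats::pt(tl, df[okv], lower.tail = FALSE)
  p <- pmin(p, 1)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(logFC = d, p = p, q = q, zero_variance = !okv,
             row.names = NULL)
}

## Empirical-Bayes variance squeezing: fit s2 ~ s0^2 * F(df, d0) by
## matching mean/variance of log(s2); returns the posterior variances and
## the prior degrees of freedom d0.
.squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3) return(list(var = s2, d0 = 0))
  z <- log(s2[ok])
  ev <- stats::var(z)
  excess <- ev - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-6) {
    d0 <- Inf
  } else {
    d0 <- 2 * .inv_trigamma(excess)
  }
  if (is.infinite(d0)) {
    ls0 <- mean(z) - digamma(df / 2) + log(df / 2)
    return(list(var = rep(exp(ls0), length(s2)), d0 = 1e6))
  }
  ls0 <- mean(z) - digamma(df / 2) + log(df / 2) +
    digamma(d0 / 2) - log(d0 / 2)
  s0 <- exp(ls0)
  post <- (d0 * s0 + df * s2) / (d0 + df)
  post[!ok] <- s0 * d0 / d0
  list(var = post, d0 = d0)
}

## inverse of trigamma by Newton iteration (Smyth 2004)
.inv_trigamma <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Threshold-aware differential test for count tables
#'
#' Counts are converted to log2 counts-per-million with a prior count of
#' 0.5 using the supplied (or median-of-ratios) size factors, then each
#' feature is tested for `|logFC| > log2(fc_threshold)` with a Welch test
#' against the shifted (TREAT-style) null; `fc_threshold = 1` reduces
#' exactly to the ordinary two-sided Welch test. Optionally features are
#' pre-filtered to CPM > `cpm_min` in at least `min_samples` samples.
#'
#' @param table a [count_table()] (with `conditions`) or counts matrix.
#' @param design per-sample condition labels (two levels); defaults to the
#'   table's conditions.
#' @param fc_threshold fold-change the effect must exceed (>= 1).
#' @param sf optional external size factors (e.g. from [size_factors()]).
#' @param cpm_min,min_samples optional expression filter (disabled when
#'   `cpm_min` is `NULL`).
#' @param moderate shrink per-feature variances toward a common prior
#'   (default TRUE; set FALSE for the pure Welch test, which
#'   `fc_threshold = 1` then reduces to exactly).
#' @return data.frame with `name`, `logFC`, `p`, `q`, `kept`.
#' @export
differential_test <- function(table, design = NULL, fc_threshold = 1,
                              sf = NULL, cpm_min = NULL, min_samples = 2,
                              moderate = TRUE) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (is.null(design) && inherits(table, "count_table")) design <- table$conditions
  if (is.null(design)) stop("design labels required")
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (is.null(sf)) sf <- normalize_counts(counts)
  ## sf is a relative depth factor (median-of-ratios or external); dividing
  ## by it equalises depth, then counts are put on a common CPM scale.
  mean_lib <- mean(colSums(counts))
  cpm <- (sweep(counts, 2, sf, "/") + 0.5) / mean_lib * 1e6
  kept <- rep(TRUE, nrow(counts))
  if (!is.null(cpm_min))
    kept <- rowSums(cpm > cpm_min) >= min_samples
  res <- welch_treat(log2(cpm[kept, , drop = FALSE]), design,
                     tau = log2(fc_threshold), moderate = moderate)
  out <- data.frame(name = rownames(counts)[kept], res,
                    stringsAsFactors = FALSE)
  out$kept <- TRUE
  if (any(!kept)) {
    skipped <- data.frame(name = rownames(counts)[!kept], logFC = NA_real_,
                          p = NA_real_, q = NA_real_, zero_variance = FALSE,
                          kept = FALSE, stringsAsFactors = FALSE)
    out <- rbind(out, skipped)
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return q-values (monotone over the sorted p-values, capped at 1).
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Mann-Whitney U test (exact for small samples, tie-aware)
#'
#' For `n + m <= max_exact` the permutation distribution of U is enumerated
#' over all group assignments of the observed (mid-)ranks, so ties are
#' handled exactly; the two-sided p-value is
#' `P(|U - nm/2| >= |u - nm/2|)`. Larger samples use the tie-corrected
#' normal approximation.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param max_exact size limit for enumeration in auto mode (default 20).
#' @return list with `U` (for `x`) and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                           max_exact = 20) {
  mode <- match.arg(mode)
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("empty sample")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "exact" || (mode == "auto" && n + m <= max_exact)) {
    combs <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    dev <- abs(u_all - n * m / 2)
    p <- mean(dev >= abs(u_obs - n * m / 2) - 1e-9)
    return(list(U = u_obs, p = p, method = "exact"))
  }
  ## tie-corrected normal approximation with continuity correction
  nt <- table(r)
  tie_term <- sum(nt^3 - nt) / ((n + m) * (n + m - 1))
  sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
  mu <- n * m / 2
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  if (sigma2 == 0) return(list(U = u_obs, p = 1, method = "normal_approx"))
  list(U = u_obs, p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal_approx")
}

#' Fisher's exact test for a 2x2 table
#'
#' The odds ratio is the sample `(a d)/(b c)` with a Haldane 0.5 correction
#' applied to every cell when any cell is zero (flagged). The two-sided
#' p-value sums hypergeometric probabilities of all tables (at fixed
#' margins) no more probable than the observed one.
#'
#' @param a,b,c,d non-negative integer cell counts, layout
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio`, `p`, `haldane` flag, `table`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  haldane <- any(cells == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  dens <- stats::dhyper(support, m1, m2, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p), haldane = haldane,
       table = matrix(cells, 2, byrow = TRUE))
}

#' Hypergeometric enrichment test (upper tail)
#'
#' `P(X >= k)` drawing `n` from a universe of `N` with `K` successes.
#'
#' @param N universe size; `K` successes in universe; `n` draws;
#'   `k` observed successes.
#' @return upper-tail p-value.
#' @export
hypergeom_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0)) stop("negative input")
  if (K > N || n > N || k > min(K, n)) stop("inconsistent hypergeometric input")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
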
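#' Noise model for simulated samples
#'
#' @param depth expected Hi-C contacts per replicate. The default (5e6)
#'   scales the study's per-sample sequencing (hundreds of millions of
#'   contacts on a 3-Gb genome) down to the 40-Mb toy genome.
#' @param donor_sd standard deviation (log scale) of the shared per-donor
#'   multiplier applied across all features of a donor's samples.
#' @param dispersion negative-binomial dispersion for expression counts.
#' @param rna_depth expected library size scale for expression counts.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(depth = 5e6, donor_sd = 0.1, dispersion = 0.1,
                        rna_depth = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (donor_sd < 0 || dispersion < 0) stop("sd and dispersion must be >= 0")
  structure(list(depth = depth, donor_sd = donor_sd,
                 dispersion = dispersion, rna_depth = rna_depth),
            class = "noise_model")
}

#' Planted ground truth for a synthetic differentiation/knockdown design
#'
#' Generates and records everything the recovery tests need: TAD
#' boundaries tiling each chromosome into domains, focal loops with
#' per-condition enrichments (a knockdown condition attenuates a fraction
#' of loops toward background), A/B compartment blocks, anchor-resident
#' CTCF/RAD21/H3K27ac/ATAC peaks with CTCF motif placements (convergent
#' for a configurable fraction of loops), genes with planted fold changes
#' tied to attenuated loop domains, and coarse condition-specific
#' interchromosomal blocks.
#'
#' Defaults state the emulated world: 2 chromosomes x 20 Mb at 10-kb bins,
#' 25 internal TAD boundaries, 50 loops spanning 100-500 kb, contact decay
#' exponent 1, compartment modulation 1.3, TAD enrichment 3, loop
#' enrichment 5.
#'
#' @param layout a [genome_layout()].
#' @param resolution bin size (bp).
#' @param n_boundaries total internal TAD boundaries planted.
#' @param min_tad_bins minimum domain size in bins.
#' @param n_loops number of loops.
#' @param loop_dist_bins range (bins) of anchor separations.
#' @param f_tad,f_loop planted enrichment factors (>= 1); `f_loop` may be
#'   a range `c(lo, hi)` to draw per-loop enrichments uniformly.
#' @param alpha contact decay exponent: background ~ (1+d)^(-alpha).
#' @param comp_c compartment modulation (x c same sign, / c opposite).
#' @param comp_block_bins range of compartment block sizes (bins).
#' @param conditions condition names; the second is the knockdown-like one.
#' @param kd_fraction fraction of loops attenuated in the second condition.
#' @param kd_attenuation fraction of the excess enrichment (f - 1) removed
#'   in attenuated loops; 1 erases the loop. The default 0.625 halves the
#'   obs/exp score of an f = 5 loop (5 -> 2.5).
#' @param convergent_fraction fraction of loops with convergent CTCF
#'   motifs at their anchors.
#' @param peak_prob probability a loop anchor carries CTCF/RAD21 peaks.
#' @param peak_width peak width (bp).
#' @param n_enhancers non-anchor H3K27ac/ATAC enhancer sites.
#' @param n_genes,de_fraction,de_log2fc,housekeeping_fraction,mu_range
#'   expression layer: gene count, fraction differential, planted |log2FC|,
#'   fraction flagged housekeeping (always log2FC 0), baseline mean range.
#' @param n_interchrom_blocks condition-specific interchromosomal blocks
#'   (2.5-Mb scale).
#' @param seed integer seed; the truth is a pure function of its arguments.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(layout = genome_layout(c("chrS1", "chrS2"), c(2e7, 2e7)),
                      resolution = 1e4,
                      n_boundaries = 25, min_tad_bins = 30,
                      n_loops = 50, loop_dist_bins = c(10, 50),
                      f_tad = 3, f_loop = 5, alpha = 1,
                      comp_c = 1.3, comp_block_bins = c(50, 200),
                      conditions = c("control", "kd"),
                      kd_fraction = 0.4, kd_attenuation = 0.625,
                      convergent_fraction = 0.9, peak_prob = 1,
                      peak_width = 300, n_enhancers = 40,
                      n_genes = 200, de_fraction = 0.2, de_log2fc = 2,
                      housekeeping_fraction = 0.3, mu_range = c(50, 500),
                      n_interchrom_blocks = 3, seed = 1) {
  stopifnot(f_tad >= 1, f_loop >= 1, length(conditions) >= 1)
  with_seed(seed, {
    chroms <- layout$chrom_names
    nb <- vapply(chroms, function(ch) n_bins(layout, ch, resolution),
                 integer(1))
    ## --- boundaries & TADs -------------------------------------------------
    alloc <- diff(round(seq(0, n_boundaries, length.out = length(chroms) + 1)))
    boundaries <- list()
    tads <- list()
    for (ci in seq_along(chroms)) {
      k <- alloc[ci]; n <- nb[ci]
      slack <- n - (k + 1) * min_tad_bins
      if (slack < 0) stop("chromosome too small for requested boundaries")
      extra <- sort(sample.int(slack + 1, k, replace = TRUE) - 1)
      pos <- min_tad_bins * seq_len(k) + extra  # 0-based first bin of next TAD
      boundaries[[chroms[ci]]] <- pos
      cuts <- c(0, pos, n)
      tads[[chroms[ci]]] <- data.frame(
        chrom = chroms[ci],
        from = utils::head(cuts, -1), to = utils::tail(cuts, -1) - 1)
    }
    tad_df <- do.call(rbind, tads)
    rownames(tad_df) <- NULL
    tad_df$name <- paste0("ttad_", seq_len(nrow(tad_df)))
    for (cn in conditions) tad_df[[paste0("f_", cn)]] <- f_tad
    ## --- loops -------------------------------------------------------------
    loop_rows <- list()
    placed <- list()
    li <- 0
    tries <- 0
    while (li < n_loops) {
      tries <- tries + 1
      if (tries > 200 * n_loops)
        stop("could not place ", n_loops, " loops with 6-bin anchor ",
             "separation; use a larger layout or fewer loops")
      ci <- sample(seq_along(chroms), 1)
      n <- nb[ci]
      d <- sample(loop_dist_bins[1]:loop_dist_bins[2], 1)
      i <- sample.int(n - d - 10, 1) + 5  # keep off the edges
      j <- i + d
      ## keep anchors of different loops at least 6 bins apart so loop
      ## pixels (3x3 + donut) and anchor-resident peaks/motifs never collide
      used <- placed[[chroms[ci]]] %||% numeric(0)
      if (length(used) && (min(abs(used - i)) < 6 || min(abs(used - j)) < 6))
        next
      placed[[chroms[ci]]] <- c(used, i, j)
      li <- li + 1
      loop_rows[[li]] <- data.frame(chrom = chroms[ci], bin1 = i - 1,
                                    bin2 = j - 1)
    }
    loops <- do.call(rbind, loop_rows)
    loops <- loops[order(loops$chrom, loops$bin1, loops$bin2), , drop = FALSE]
    rownames(loops) <- NULL
    loops$name <- paste0("tloop_", seq_len(nrow(loops)))
    atten <- rep(FALSE, nrow(loops))
    if (length(conditions) >= 2 && kd_fraction > 0)
      atten[sample.int(nrow(loops), round(kd_fraction * nrow(loops)))] <- TRUE
    loops$attenuated <- atten
    ## f_loop may be a scalar (all loops equal) or a range c(lo, hi)
    fbase <- if (length(f_loop) == 2)
      stats::runif(nrow(loops), f_loop[1], f_loop[2]) else rep(f_loop, nrow(loops))
    for (ki in seq_along(conditions)) {
      f <- fbase
      if (ki >= 2) f[atten] <- 1 + (fbase[atten] - 1) * (1 - kd_attenuation)
      loops[[paste0("f_", conditions[ki])]] <- f
    }
    loops$convergent <- seq_len(nrow(loops)) %in%
      sample.int(nrow(loops), round(convergent_fraction * nrow(loops)))
    ## --- compartments ------------------------------------------------------
    compartments <- lapply(stats::setNames(seq_along(chroms), chroms),
                           function(ci) {
      n <- nb[ci]
      sgn <- sample(c(1, -1), 1)
      v <- integer(0)
      while (length(v) < n) {
        len <- sample(comp_block_bins[1]:comp_block_bins[2], 1)
        v <- c(v, rep(sgn, len))
        sgn <- -sgn
      }
      v[seq_len(n)]
    })
    ## --- peaks & motifs ----------------------------------------------------
    ctcf_consensus <- "TGGCCACCAGGGGGCGCTAC"  # 20-bp core consensus
    anchors <- rbind(
      data.frame(chrom = loops$chrom, bin = loops$bin1, side = "L",
                 loop = loops$name, f = loops[[paste0("f_", conditions[1])]],
                 convergent = loops$convergent),
      data.frame(chrom = loops$chrom, bin = loops$bin2, side = "R",
                 loop = loops$name, f = loops[[paste0("f_", conditions[1])]],
                 convergent = loops$convergent))
    anchors$pos <- (anchors$bin + 0.5) * resolution  # anchor bin centre
    anchors$has_peak <- stats::runif(nrow(anchors)) < peak_prob
    anchors$strand <- ifelse(anchors$convergent,
                             ifelse(anchors$side == "L", "+", "-"),
                             sample(c("+", "-"), nrow(anchors), replace = TRUE))
    enh <- data.frame(
      chrom = sample(chroms, n_enhancers, replace = TRUE, prob = nb / sum(nb)))
    enh$pos <- vapply(enh$chrom, function(ch)
      stats::runif(1, 5e4, chrom_length(layout, ch) - 5e4), numeric(1))
    ## --- genes -------------------------------------------------------------
    loop_dom <- data.frame(chrom = loops$chrom,
                           start = (loops$bin1 + 1) * resolution,
                           end = loops$bin2 * resolution,
                           name = loops$name, attenuated = loops$attenuated)
    genes <- data.frame(gene = paste0("g", seq_len(n_genes)))
    genes$chrom <- sample(chroms, n_genes, replace = TRUE, prob = nb / sum(nb))
    genes$tss <- round(vapply(genes$chrom, function(ch)
      stats::runif(1, 1e4, chrom_length(layout, ch) - 1e4), numeric(1)))
    genes$mu <- round(stats::runif(n_genes, mu_range[1], mu_range[2]))
    genes$housekeeping <- stats::runif(n_genes) < housekeeping_fraction
    genes$log2fc <- 0
    genes$domain <- "unlinked"
    n_de <- round(de_fraction * n_genes)
    de_idx <- sample(which(!genes$housekeeping), n_de)
    ## half the DE genes sit in attenuated loop domains and go down with
    ## them; the rest are unlinked and go up
    att_dom <- loop_dom[loop_dom$attenuated, , drop = FALSE]
    half <- floor(n_de / 2)
    if (nrow(att_dom) && half > 0) {
      inside <- de_idx[seq_len(half)]
      pick <- att_dom[sample.int(nrow(att_dom), half, replace = TRUE), ]
      genes$chrom[inside] <- pick$chrom
      genes$tss[inside] <- round(stats::runif(half, pick$start, pick$end))
      genes$log2fc[inside] <- -de_log2fc
      genes$domain[inside] <- pick$name
      de_idx <- de_idx[-seq_len(half)]
    }
    genes$log2fc[de_idx] <- de_log2fc
    ## --- interchromosomal blocks ------------------------------------------
    ic_res <- 2.5e6
    ic_bins <- do.call(rbind, lapply(chroms, function(ch)
      data.frame(chrom = ch, idx = seq_len(n_bins(layout, ch, ic_res)))))
    ic <- NULL
    if (length(chroms) >= 2 && n_interchrom_blocks > 0) {
      pairs <- which(outer(ic_bins$chrom, ic_bins$chrom, "!=") &
                       upper.tri(diag(nrow(ic_bins))), arr.ind = TRUE)
      sel <- pairs[sample.int(nrow(pairs),
                              min(n_interchrom_blocks * length(conditions),
                                  nrow(pairs))), , drop = FALSE]
      cond_of <- rep(conditions, length.out = nrow(sel))
      ic <- data.frame(bin_a = sel[, 1], bin_b = sel[, 2],
                       condition = cond_of, enrichment = 4)
    }
    structure(list(layout = layout, resolution = resolution,
                   conditions = conditions, alpha = alpha,
                   comp_c = comp_c, f_tad = f_tad, f_loop = f_loop,
                   boundaries = boundaries, tads = tad_df, loops = loops,
                   compartments = compartments,
                   anchors = anchors, enhancers = enh,
                   ctcf_consensus = ctcf_consensus,
                   genes = genes, interchrom = ic, seed = seed),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$layout$chrom_names), "chromosome(s) @",
      x$resolution, "bp bins;",
      sum(lengths(x$boundaries)), "boundaries,", nrow(x$loops), "loops,",
      nrow(x$genes), "genes; conditions:",
      paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

## expected intensity surface for one chromosome (unnormalised)
.lambda_chrom <- function(truth, chrom, condition) {
  res <- truth$resolution
  n <- n_bins(truth$layout, chrom, res)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (1 + d)^(-truth$alpha)
  comp <- truth$compartments[[chrom]]
  lam <- lam * ifelse(outer(comp, comp) > 0, truth$comp_c, 1 / truth$comp_c)
  fcol <- paste0("f_", condition)
  td <- truth$tads[truth$tads$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(td))) {
    idx <- (td$from[k] + 1):(td$to[k] + 1)
    lam[idx, idx] <- lam[idx, idx] * td[[fcol]][k]
  }
  lp <- truth$loops[truth$loops$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(lp))) {
    i <- lp$bin1[k] + 1; j <- lp$bin2[k] + 1
    ri <- max(1, i - 1):min(n, i + 1)
    rj <- max(1, j - 1):min(n, j + 1)
    lam[ri, rj] <- lam[ri, rj] * lp[[fcol]][k]
    lam[rj, ri] <- lam[rj, ri] * lp[[fcol]][k]
  }
  lam
}

#' Simulate a Hi-C contact map for one condition
#'
#' Expected intensity per pixel is the product of a power-law distance
#' decay `(1 + d)^(-alpha)`, compartment modulation (x c when both bins
#' share a compartment sign, / c otherwise), the TAD enrichment for pixels
#' inside a domain and the loop enrichment over each loop's 3x3 pixel
#' neighbourhood. Exactly `depth` contacts are drawn multinomially across
#' the upper triangles (diagonal included) of all chromosomes; the same
#' seed gives bitwise-identical output.
#'
#' @param truth a [sim_truth()].
#' @param condition condition name in `truth$conditions`.
#' @param depth total contact count (>= 1).
#' @param seed integer seed.
#' @return named list of [contact_matrix()] objects, one per chromosome.
#' @export
simulate_contact_map <- function(truth, condition, depth, seed) {
  if (!condition %in% truth$conditions)
    stop("unknown condition: ", condition)
  if (depth < 1) stop("depth must be >= 1")
  chroms <- truth$layout$chrom_names
  lams <- lapply(chroms, function(ch) .lambda_chrom(truth, ch, condition))
  ut <- lapply(lams, function(l) upper.tri(l, diag = TRUE))
  vec <- unlist(lapply(seq_along(lams), function(k) lams[[k]][ut[[k]]]))
  counts <- with_seed(seed,
    as.numeric(stats::rmultinom(1, size = depth, prob = vec)))
  out <- list()
  offset <- 0
  for (k in seq_along(chroms)) {
    n <- nrow(lams[[k]])
    m <- matrix(0, n, n)
    npx <- sum(ut[[k]])
    m[ut[[k]]] <- counts[offset + seq_len(npx)]
    offset <- offset + npx
    m <- m + t(m) - diag(diag(m))
    out[[chroms[k]]] <- contact_matrix(chroms[k], truth$resolution, m)
  }
  out
}

#' Simulate replicate contact maps for every condition
#'
#' Replicates emulate paired donors: donor `r` contributes one sample per
#' condition, with a shared log-normal donor multiplier on sequencing
#' depth. Returns all samples plus per-sample metadata.
#'
#' @param truth a [sim_truth()].
#' @param replicates replicates (donors) per condition; a warning is
#'   issued below 2 because differential stages need at least 2.
#' @param noise a [noise_model()].
#' @param seed integer seed; per-sample seeds are derived from it.
#' @return list with `samples` (named list of per-chromosome contact-map
#'   lists) and `metadata` (sample, condition, donor, depth, seed).
#' @export
simulate_condition_set <- function(truth, replicates = 3,
                                   noise = noise_model(), seed = 1) {
  if (replicates < 2)
    warning("fewer than 2 replicates: differential stages need >= 2")
  donor_mult <- with_seed(seed * 1000L %% .Machine$integer.max,
                          exp(stats::rnorm(replicates, 0, noise$donor_sd)))
  samples <- list()
  meta <- list()
  k <- 0
  for (ci in seq_along(truth$conditions)) {
    cn <- truth$conditions[ci]
    for (r in seq_len(replicates)) {
      k <- k + 1
      depth <- max(1, round(noise$depth * donor_mult[r]))
      sseed <- (seed * 7919L + ci * 101L + r) %% .Machine$integer.max
      nm <- paste0(cn, "_d", r)
      samples[[nm]] <- simulate_contact_map(truth, cn, depth, sseed)
      meta[[k]] <- data.frame(sample = nm, condition = cn, donor = r,
                              depth = depth, seed = sseed,
                              stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, metadata = do.call(rbind, meta))
}

#' Simulate peaks, motif placements and coverage tracks
#'
#' CTCF and RAD21 peaks sit at loop anchors with log-normal signal noise
#' around a mean proportional to the loop enrichment; H3K27ac and ATAC
#' peaks sit at a subset of anchors and at non-anchor enhancer sites; the
#' input track is flat background noise. CTCF motif strands follow the
#' planted convergent/random orientation.
#'
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @param signal_sd log-normal signal noise sd (default 0.2).
#' @param peak_width peak width in bp (default 300).
#' @param track_bin bedGraph bin width (default 200).
#' @return list with `peaks` (per class), `motifs` (CTCF placements with
#'   strand), `tracks` (bedGraph data frames per class).
#' @export
simulate_peaks_and_tracks <- function(truth, seed = 1, signal_sd = 0.2,
                                      peak_width = 300, track_bin = 200) {
  if (nrow(truth$loops) == 0) stop("truth has no loops")
  with_seed(seed * 31L %% .Machine$integer.max, {
    an <- truth$anchors
    an$signal <- 10 * an$f * exp(stats::rnorm(nrow(an), 0, signal_sd))
    mk <- function(df, width = peak_width) {
      intervals(df$chrom, pmax(0, df$pos - width / 2), df$pos + width / 2,
                name = paste0(df$loop %||% "site", "_", seq_len(nrow(df))),
                score = df$signal)
    }
    anp <- an[an$has_peak, , drop = FALSE]
    ctcf <- mk(anp)
    rad21 <- anp
    rad21$signal <- rad21$signal * exp(stats::rnorm(nrow(rad21), 0, signal_sd))
    rad21 <- mk(rad21)
    ## H3K27ac/ATAC: half the anchors plus the enhancer sites
    sel <- an[stats::runif(nrow(an)) < 0.5, , drop = FALSE]
    enh <- truth$enhancers
    enh$loop <- "enh"; enh$f <- 1.5
    enh$signal <- 10 * enh$f * exp(stats::rnorm(nrow(enh), 0, signal_sd))
    acsrc <- rbind(sel[, c("chrom", "pos", "loop", "signal")],
                   enh[, c("chrom", "pos", "loop", "signal")])
    h3k27ac <- mk(acsrc, width = 1000)
    atac <- acsrc
    atac$signal <- atac$signal * exp(stats::rnorm(nrow(atac), 0, signal_sd))
    atac <- mk(atac, width = 500)
    motifs <- data.frame(chrom = an$chrom,
                         start = round(an$pos - 10), end = round(an$pos + 10),
                         strand = an$strand, loop = an$loop, side = an$side,
                         stringsAsFactors = FALSE)
    tracks <- lapply(list(ctcf = ctcf, rad21 = rad21, h3k27ac = h3k27ac,
                          atac = atac), function(pk) {
      data.frame(chrom = pk$chrom,
                 start = floor(pk$start / track_bin) * track_bin,
                 end = ceiling(pk$end / track_bin) * track_bin,
                 value = pk$score)
    })
    flat <- do.call(rbind, lapply(truth$layout$chrom_names, function(ch) {
      n <- ceiling(chrom_length(truth$layout, ch) / 1e5)
      data.frame(chrom = ch, start = (seq_len(n) - 1) * 1e5,
                 end = pmin(seq_len(n) * 1e5, chrom_length(truth$layout, ch)),
                 value = exp(stats::rnorm(n, 0, signal_sd)))
    }))
    tracks$input <- flat
    list(peaks = list(ctcf = ctcf, rad21 = rad21, h3k27ac = h3k27ac,
                      atac = atac),
         motifs = motifs, tracks = tracks)
  })
}

#' Simulate replicate expression counts with planted fold changes
#'
#' Counts are negative binomial with mean
#' `lib_s x mu_g x 2^(log2FC)` (fold change applied in the second
#' condition only) and dispersion from the noise model; the per-donor
#' multiplier is shared with the Hi-C layer's design. Housekeeping genes
#' always have log2FC 0.
#'
#' @param truth a [sim_truth()].
#' @param replicates donors per condition.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return a [count_table()] with condition labels.
#' @export
simulate_expression <- function(truth, replicates = 3, noise = noise_model(),
                                seed = 1) {
  if (nrow(truth$genes) == 0) stop("truth has no genes")
  g <- truth$genes
  with_seed(seed * 17L %% .Machine$integer.max, {
    donor_mult <- exp(stats::rnorm(replicates, 0, noise$donor_sd))
    conds <- rep(truth$conditions[seq_len(min(2, length(truth$conditions)))],
                 each = replicates)
    cnt <- matrix(0L, nrow(g), length(conds))
    for (s in seq_along(conds)) {
      fc <- if (conds[s] == truth$conditions[1]) 0 else g$log2fc
      mu <- noise$rna_depth * donor_mult[(s - 1) %% replicates + 1] *
        g$mu * 2^fc
      cnt[, s] <- if (noise$dispersion > 0)
        stats::rnbinom(nrow(g), mu = mu, size = 1 / noise$dispersion)
      else stats::rpois(nrow(g), mu)
    }
    rownames(cnt) <- g$gene
    colnames(cnt) <- paste0(conds, "_d", rep(seq_len(replicates),
                                             times = length(conds) / replicates))
    count_table(cnt, conditions = conds)
  })
}

#' Simulate genome sequence with planted CTCF motifs
#'
#' I.i.d. background bases with the truth's motif consensus written at the
#' recorded positions and strands. Intended for compact layouts; sequence
#' length equals the layout.
#'
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @return named character vector of chromosome sequences.
#' @export
simulate_sequences <- function(truth, seed = 1) {
  mot <- truth$motifs %||% data.frame(
    chrom = truth$anchors$chrom,
    start = round(truth$anchors$pos - nchar(truth$ctcf_consensus) / 2),
    strand = truth$anchors$strand)
  mot$end <- mot$start + nchar(truth$ctcf_consensus)
  ord <- order(mot$chrom, mot$start)
  mot <- mot[ord, ]
  for (ch in unique(mot$chrom)) {
    mm <- mot[mot$chrom == ch, ]
    if (nrow(mm) > 1 && any(mm$start[-1] < mm$end[-nrow(mm)]))
      stop("overlapping motif placements on ", ch)
  }
  with_seed(seed * 13L %% .Machine$integer.max, {
    seqs <- vapply(truth$layout$chrom_names, function(ch) {
      len <- chrom_length(truth$layout, ch)
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      mm <- mot[mot$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(mm))) {
        ins <- truth$ctcf_consensus
        if (mm$strand[k] == "-") ins <- .revcomp(ins)
        s[(mm$start[k] + 1):mm$end[k]] <- strsplit(ins, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    seqs
  })
}

#' Simulate a coarse whole-genome map with interchromosomal blocks
#'
#' Uniform interchromosomal background plus the truth's condition-specific
#' enriched blocks; intrachromosomal cells follow the distance decay.
#' Counts are multinomial with total `depth`.
#'
#' @param truth a [sim_truth()].
#' @param condition condition name.
#' @param depth total contacts.
#' @param seed integer seed.
#' @return a [genome_matrix()] at 2.5-Mb bins.
#' @export
simulate_interchrom_map <- function(truth, condition, depth, seed) {
  if (!condition %in% truth$conditions) stop("unknown condition: ", condition)
  res <- 2.5e6
  gm0 <- genome_matrix(truth$layout, res,
                       diag(0, sum(vapply(truth$layout$chrom_names, function(ch)
                         n_bins(truth$layout, ch, res), integer(1)))))
  bins <- gm0$bins
  nbin <- nrow(bins)
  lam <- matrix(0.2, nbin, nbin)
  same <- outer(bins$chrom, bins$chrom, "==")
  d <- abs(outer(seq_len(nbin), seq_len(nbin), "-"))
  lam[same] <- ((1 + d)^(-truth$alpha))[same] * 5
  ic <- truth$interchrom
  if (!is.null(ic)) {
    icc <- ic[ic$condition == condition, , drop = FALSE]
    for (k in seq_len(nrow(icc))) {
      lam[icc$bin_a[k], icc$bin_b[k]] <- lam[icc$bin_a[k], icc$bin_b[k]] *
        icc$enrichment[k]
      lam[icc$bin_b[k], icc$bin_a[k]] <- lam[icc$bin_a[k], icc$bin_b[k]]
    }
  }
  ut <- upper.tri(lam, diag = TRUE)
  counts <- with_seed(seed,
    as.numeric(stats::rmultinom(1, depth, lam[ut])))
  m <- matrix(0, nbin, nbin)
  m[ut] <- counts
  m <- m + t(m) - diag(diag(m))
  genome_matrix(truth$layout, res, m)
}

#' Write / read the machine-readable truth file
#'
#' @param truth a [sim_truth()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  obj <- truth
  obj$layout <- list(chrom_names = truth$layout$chrom_names,
                     chrom_lengths = as.numeric(truth$layout$chrom_lengths))
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$layout <- genome_layout(obj$layout$chrom_names, obj$layout$chrom_lengths)
  obj$boundaries <- lapply(obj$boundaries, as.numeric)
  obj$compartments <- lapply(obj$compartments, as.numeric)
  structure(obj, class = "sim_truth")
}
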
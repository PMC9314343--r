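small_truth <- function() fixture("truth_small", sim_truth(
  layout = genome_layout(c("chrT1", "chrT2"), c(1.2e6, 1.2e6)),
  n_boundaries = 4, min_tad_bins = 15, n_loops = 6,
  loop_dist_bins = c(6, 15), n_genes = 30, n_enhancers = 5,
  convergent_fraction = 1, seed = 2))

test_that("generators are pure functions of parameters and seed", {
  tr <- small_truth()
  m1 <- simulate_contact_map(tr, "control", 5e4, seed = 7)
  m2 <- simulate_contact_map(tr, "control", 5e4, seed = 7)
  expect_identical(m1, m2)
  m3 <- simulate_contact_map(tr, "control", 5e4, seed = 8)
  expect_false(identical(m1, m3))
  ## multinomial total is exact across chromosomes
  expect_equal(sum(vapply(m1, function(m) m$total, numeric(1))), 5e4)
  expect_error(simulate_contact_map(tr, "nope", 1e4, 1), "unknown condition")
  e1 <- simulate_expression(tr, 3, noise_model(rna_depth = 1), seed = 3)
  e2 <- simulate_expression(tr, 3, noise_model(rna_depth = 1), seed = 3)
  expect_identical(e1$counts, e2$counts)
})

test_that("planted loop pixels carry the stated enrichment on average", {
  truth <- default_truth()
  depth <- 1e6
  maps <- fixture("map_d1e6_s1",
                  simulate_contact_map(truth, "control", depth, seed = 1))
  ## analytic expectation: intensity surface without the loop factor,
  ## normalised by the full surface's mass
  z <- 0
  lam_wo <- list()
  for (ch in truth$layout$chrom_names) {
    lam <- chromarch:::.lambda_chrom(truth, ch, "control")
    z <- z + sum(lam[upper.tri(lam, diag = TRUE)])
    tr0 <- truth
    tr0$loops$f_control <- 1
    lam_wo[[ch]] <- chromarch:::.lambda_chrom(tr0, ch, "control")
  }
  ratios <- c()
  for (ch in truth$layout$chrom_names) {
    lp <- truth$loops[truth$loops$chrom == ch, ]
    m <- maps[[ch]]$counts
    for (k in seq_len(nrow(lp))) {
      i <- lp$bin1[k] + 1; j <- lp$bin2[k] + 1
      obs <- sum(m[(i - 1):(i + 1), (j - 1):(j + 1)])
      exp_bg <- depth * sum(lam_wo[[ch]][(i - 1):(i + 1), (j - 1):(j + 1)]) / z
      ratios <- c(ratios, obs / exp_bg)
    }
  }
  ## mean over loops ~ f_loop = 5 within 3 sigma of the Poisson error
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 5), 3 * se + 0.15)
})

test_that("knockdown attenuation removes loop signal in the limit", {
  tr <- sim_truth(layout = genome_layout("chrK", 5e6), n_boundaries = 2,
                  min_tad_bins = 20, n_loops = 5, loop_dist_bins = c(6, 15),
                  n_genes = 10, kd_fraction = 1, kd_attenuation = 1,
                  n_interchrom_blocks = 0, seed = 4)
  lam_kd <- chromarch:::.lambda_chrom(tr, "chrK", "kd")
  tr0 <- tr
  tr0$loops$f_kd <- 1
  expect_equal(lam_kd, chromarch:::.lambda_chrom(tr0, "chrK", "kd"))
  ## fraction = 0: conditions identical in expectation
  tr2 <- sim_truth(layout = genome_layout("chrK", 5e6), n_boundaries = 2,
                   min_tad_bins = 20, n_loops = 5, loop_dist_bins = c(6, 15),
                   n_genes = 10, kd_fraction = 0, n_interchrom_blocks = 0,
                   seed = 4)
  expect_equal(chromarch:::.lambda_chrom(tr2, "chrK", "kd"),
               chromarch:::.lambda_chrom(tr2, "chrK", "control"))
})

test_that("condition sets carry paired donors and warn on single replicates", {
  tr <- small_truth()
  sim <- fixture("small_set",
                 simulate_condition_set(tr, replicates = 2,
                                        noise = noise_model(depth = 5e4),
                                        seed = 3))
  expect_equal(nrow(sim$metadata), 4)
  ## donor depth shared across conditions (paired design)
  md <- sim$metadata
  expect_equal(md$depth[md$condition == "control"],
               md$depth[md$condition == "kd"])
  expect_warning(simulate_condition_set(tr, replicates = 1,
                                        noise = noise_model(depth = 1e4),
                                        seed = 1),
                 ">= 2")
})

test_that("peaks sit on anchors with enrichment-linked signal and planted orientation", {
  tr <- small_truth()  # convergent_fraction = 1, peak_prob = 1
  pk <- simulate_peaks_and_tracks(tr, seed = 2)
  anchors <- feature_anchors(features2d(
    tr$loops$chrom, tr$loops$bin1 * tr$resolution,
    (tr$loops$bin1 + 1) * tr$resolution,
    tr$loops$bin2 * tr$resolution, (tr$loops$bin2 + 1) * tr$resolution,
    name = tr$loops$name))
  expect_true(all(overlap_intervals(anchors, pk$peaks$ctcf, "count") > 0))
  ## all loops convergent by construction
  loops <- features2d(tr$loops$chrom, tr$loops$bin1 * 1e4,
                      (tr$loops$bin1 + 1) * 1e4, tr$loops$bin2 * 1e4,
                      (tr$loops$bin2 + 1) * 1e4, name = tr$loops$name)
  hits <- pk$motifs
  hits$score <- 1
  oc <- ctcf_orientation(loops, hits, window_bp = 1e4)
  expect_equal(unname(oc$fractions["convergent"]), 1, ignore_attr = TRUE)
  ## signal tracks loop enrichment (Spearman over variable enrichments)
  trv <- sim_truth(f_loop = c(2, 8), seed = 3)
  pkv <- simulate_peaks_and_tracks(trv, seed = 3, signal_sd = 0.2)
  rho <- cor(trv$anchors$f, pkv$peaks$ctcf$score, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("sequences contain the planted motifs and nothing else above threshold", {
  tr <- small_truth()
  seqs <- fixture("seqs_small", simulate_sequences(tr, seed = 2))
  expect_equal(unname(nchar(seqs)), rep(1.2e6, 2))
  pw <- match_pwm(tr$ctcf_consensus, "CTCF")
  hits <- scan_pwm(seqs, pw, threshold = nchar(tr$ctcf_consensus) * 0.9)
  pk <- simulate_peaks_and_tracks(tr, seed = 2)
  planted <- pk$motifs
  got <- merge(planted, hits, by.x = c("chrom", "start"),
               by.y = c("seqname", "start"))
  expect_equal(nrow(got), nrow(planted))      # every placement found
  expect_true(all(got$strand.x == got$strand.y))  # strands recorded right
  ## a 20-mer exact-match threshold has essentially no background hits
  expect_lte(nrow(hits) - nrow(planted), 1)
  ## overlapping placements are rejected
  bad <- tr
  bad$anchors <- rbind(bad$anchors[1, ], bad$anchors[1, ])
  expect_error(simulate_sequences(bad, seed = 1), "overlapping")
})

test_that("expression counts follow the planted design", {
  tr <- small_truth()
  noise0 <- noise_model(donor_sd = 0, dispersion = 1e-4, rna_depth = 50)
  expr <- simulate_expression(tr, replicates = 3, noise = noise0, seed = 5)
  g <- tr$genes
  expect_equal(dim(expr$counts), c(nrow(g), 6))
  ## near-zero dispersion and noise: per-gene mean ratio approaches 2^log2FC
  mc <- rowMeans(expr$counts[, 1:3])
  mk <- rowMeans(expr$counts[, 4:6])
  de <- g$log2fc != 0
  expect_equal(log2(mk[de] / mc[de]), g$log2fc[de], tolerance = 0.15,
               ignore_attr = TRUE)
  expect_equal(mean(log2(mk[!de] / mc[!de])), 0, tolerance = 0.05)
  ## housekeeping genes are never differential
  expect_true(all(g$log2fc[g$housekeeping] == 0))
  ## differential genes map to a recorded domain or "unlinked"
  expect_true(all(g$domain[de] %in% c(tr$loops$name, "unlinked")))
})

test_that("truth files round-trip through JSON", {
  tr <- small_truth()
  f <- tempfile(fileext = ".json")
  write_truth(tr, f)
  back <- read_truth(f)
  expect_equal(back$boundaries, lapply(tr$boundaries, as.numeric))
  expect_equal(back$loops$bin1, tr$loops$bin1)
  expect_equal(back$loops$f_kd, tr$loops$f_kd)
  expect_equal(back$genes$log2fc, tr$genes$log2fc)
  expect_equal(back$layout$chrom_lengths, tr$layout$chrom_lengths)
})
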
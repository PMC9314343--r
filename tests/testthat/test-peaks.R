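test_that("anchor annotation flags classes and counts combinations", {
  loop <- features2d("chr1", 1.00e6, 1.01e6, 2.00e6, 2.01e6, name = "L1")
  ctcf <- intervals("chr1", 1.002e6, 1.003e6)       # inside left window only
  ann <- annotate_anchors(loop, list(ctcf = ctcf), window_bp = 15000)
  expect_true(ann$feature_flags$ctcf)
  expect_equal(unname(ann$combination_counts[c("ctcf", "none")]),
               c(1, 1), ignore_attr = TRUE)
  ## empty peak set: all flags false
  ann0 <- annotate_anchors(loop, list(x = empty_intervals()))
  expect_false(any(ann0$anchor_flags$x))
  ## counts match a per-bp oracle on a toy layout
  set.seed(61)
  loops <- features2d("chr1", s <- sort(runif(6, 0, 5e4)), s + 500,
                      s + 3e4, s + 3.05e4)
  pks <- random_intervals(15, chroms = "chr1", max_len = 9e4)
  ann2 <- annotate_anchors(loops, list(p = pks), window_bp = 2000)
  anchors <- feature_anchors(loops)
  mid <- (anchors$start + anchors$end) / 2
  wide <- intervals(anchors$chrom, pmax(0, mid - 1000), mid + 1000)
  expect_equal(unname(ann2$anchor_flags$p), bp_overlap_oracle(wide, pks))
})

test_that("coverage profiles centre, aggregate, flip and conserve signal", {
  ## 9 bins of 100 bp; the centre (450) falls inside bin 5
  regions <- intervals("chr1", c(1000, 5000, 9000), c(1900, 5900, 9900),
                       strand = c("+", "+", "-"))
  ## unit impulse at each region centre
  impulse <- data.frame(chrom = "chr1",
                        start = c(1450, 5450, 9450) - 5,
                        end = c(1450, 5450, 9450) + 5, value = 1)
  prof <- coverage_profile(impulse, regions, binsize = 100)
  expect_equal(which.max(prof), 5)  # central bin of 9
  expect_equal(sum(prof > 0), 1)
  ## aggregate equals the column mean of the per-region matrix
  mat <- coverage_profile(impulse, regions, binsize = 100,
                          mode = "per_region_matrix")
  expect_equal(prof, colMeans(mat), ignore_attr = TRUE)
  ## total signal conserved: 10 bp x value 1 per region
  expect_equal(sum(mat), 30)
  ## minus-strand region mirrors the plus-strand profile
  asym <- data.frame(chrom = "chr1", start = c(1000, 9000),
                     end = c(1200, 9200), value = 2)
  two <- intervals("chr1", c(1000, 9000), c(2000, 10000),
                   strand = c("+", "-"))
  m2 <- coverage_profile(asym, two, binsize = 100, mode = "per_region_matrix")
  expect_equal(m2[1, ], rev(m2[2, ]), ignore_attr = TRUE)
  expect_error(coverage_profile(asym, intervals("chr1", 0, 150), binsize = 100),
               "divide")
})

test_that("super-enhancer stitching respects the strict gap and TSS exclusion", {
  tss <- intervals("chr1", 1e6, 1e6 + 1)
  ## gaps of 11,999 bp stitch; 12,000 bp do not
  pk <- intervals("chr1", c(0, 12999, 26000), c(1000, 14000, 27000))
  ## gap1 = 12999-1000 = 11999 (stitch); gap2 = 26000-14000 = 12000 (cut)
  expect_error(call_superenhancers(pk, c(1, 1, 1), c(0, 0, 0), tss),
               "fewer than 3")
  pk6 <- rbind(pk, intervals("chr1", c(50000, 80000, 110000),
                             c(51000, 81000, 111000)))
  se <- call_superenhancers(pk6, rep(1, 6), rep(0, 6), tss)
  expect_equal(nrow(se$enhancers), 5)  # first two stitched, rest separate
  expect_true(any(se$enhancers$start == 0 & se$enhancers$end == 14000))
  ## stitching is idempotent: stitched enhancers never merge further
  en <- se$enhancers
  se2 <- call_superenhancers(
    intervals(en$chrom, en$start, en$end), en$y, rep(0, nrow(en)), tss)
  expect_equal(nrow(se2$enhancers), nrow(en))
  ## peaks with centres within 2 kb of a TSS are dropped
  pk7 <- rbind(pk6, intervals("chr1", 999000, 1001000))  # centre at the TSS
  se3 <- call_superenhancers(pk7, rep(1, 7), rep(0, 7), tss)
  expect_equal(nrow(se3$enhancers), 5)
  ## input correction floors at zero
  seF <- call_superenhancers(pk6, rep(1, 6), rep(5, 6), tss)
  expect_true(all(seF$enhancers$y == 0))
})

test_that("the tangent cutoff reproduces the analytic cubic solution", {
  n <- 1000
  y <- ((seq_len(n) - 1) / (n - 1))^3
  pk <- intervals(rep("chr1", n), seq(0, by = 2e4, length.out = n),
                  seq(0, by = 2e4, length.out = n) + 1000)
  tss <- intervals("chr2", 1, 2)
  se <- call_superenhancers(pk, y, rep(0, n), tss)
  ## tangent slope 1 at x = 3^(-1/2): n * (1 - 0.57735) = 422.6
  expect_lte(abs(se$n_super - 423), 1)
  expect_false(se$degenerate)
  ## cutoff invariant to affine rescaling of the raw signal
  se_scaled <- call_superenhancers(pk, 7 + 100 * y, rep(0, n), tss)
  expect_equal(se_scaled$cutoff_rank, se$cutoff_rank)
  ## a straight line has slope 1 everywhere: degenerate, no SE
  lin <- call_superenhancers(pk, (seq_len(n) - 1) / (n - 1), rep(0, n), tss)
  expect_true(lin$degenerate)
  expect_equal(lin$n_super, 0)
})

test_that("top-peak scale factors equalise samples and are idempotent", {
  set.seed(62)
  a <- rgamma(200, 2, 0.1)
  m <- cbind(a = a, b = 2 * a)
  f <- scale_tracks_top_peaks(m, top_n = 10)
  expect_equal(unname(f), c(1, 0.5))
  expect_equal(unname(scale_tracks_top_peaks(cbind(a, a), 10)), c(1, 1))
  ## applying the factors then recomputing gives all ones
  m2 <- sweep(m, 2, f, "*")
  expect_equal(unname(scale_tracks_top_peaks(m2, 10)), c(1, 1))
  expect_error(scale_tracks_top_peaks(m, 1000), "exceeds")
})

test_that("FRIP counts reads in peaks like the brute-force oracle", {
  peaks <- intervals("chr1", c(100, 1000), c(200, 1100))
  reads <- intervals("chr1", seq(0, 900, 100), seq(0, 900, 100) + 50)
  ## reads starting at 100 and... overlap check via oracle
  expect_equal(frip(reads, peaks), mean(bp_overlap_oracle(reads, peaks)))
  ## 4 of 10 reads in peaks
  r2 <- intervals("chr1", c(110, 120, 1010, 1020, 5000, 5100, 5200, 5300,
                            5400, 5500),
                  c(160, 170, 1060, 1070, 5050, 5150, 5250, 5350, 5450, 5550))
  expect_equal(frip(r2, peaks), 0.4)
  ## peaks covering everything: FRIP 1
  expect_equal(frip(r2, intervals("chr1", 0, 1e6)), 1)
  expect_error(frip(empty_intervals(), peaks), "zero reads")
})

test_that("anchor overlap enrichment builds the right table and exact p", {
  set.seed(63)
  universe <- intervals("chr1", s <- seq(0, by = 1e4, length.out = 30),
                        s + 2000)
  in_a <- rbinom(30, 1, 0.5) == 1
  in_b <- in_a  # perfectly associated
  test <- anchor_overlap_test(universe[in_a, ], universe[in_b, ], universe)
  expect_gt(test$odds_ratio, 1)
  expect_lt(test$p, 1e-4)
  ## p agrees with the hypergeometric enumeration oracle for n <= 30
  tab <- test$table
  oracle <- fisher.test(tab)$p.value
  expect_equal(test$p, oracle, tolerance = 1e-9)
  expect_error(anchor_overlap_test(universe, universe, empty_intervals()),
               "empty universe")
  ## degenerate case flagged when a margin is empty
  dg <- anchor_overlap_test(universe, universe, universe)
  expect_true(dg$degenerate)
})
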
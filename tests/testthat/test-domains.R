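test_that("insulation matches the closed-form two-block fixture", {
  cm <- two_block_matrix(nb = 10, within = 8, cross = 2)
  ins <- insulation_track(cm, 3)
  raw <- attr(ins, "raw")
  expect_equal(raw[10], 2)   # boundary bin: all window pairs cross
  expect_equal(raw[6], 8)    # interior bin
  expect_equal(ins$values[10] - ins$values[6], -2, tolerance = 1e-9)
  ## edge bins are missing
  expect_true(all(is.na(ins$values[c(1:3, 18:20)])))
  ## uniform matrix: normalised score 0 on interior bins
  um <- contact_matrix("u", 1e4, matrix(4, 20, 20))
  iu <- insulation_track(um, 3)
  expect_equal(iu$values[4:17], rep(0, 14))
  expect_error(insulation_track(um, 10), "half the chromosome")
  ## invariant under depth scaling
  expect_equal(insulation_track(normalize_depth(cm, 10 * cm$total), 3)$values,
               ins$values)
})

test_that("directionality index matches its defining formula", {
  ## bin 5 with upstream sum 10 and downstream sum 30: DI = +10
  m <- matrix(0, 9, 9)
  m[5, 1:4] <- 2.5; m[5, 6:9] <- 7.5
  m <- m + t(m)
  di <- directionality_track(contact_matrix("c", 1e4, m), 4)
  expect_equal(di$values[5], 10)
  ## mirrored configuration: DI = -10
  m2 <- matrix(0, 9, 9)
  m2[5, 1:4] <- 7.5; m2[5, 6:9] <- 2.5
  m2 <- m2 + t(m2)
  expect_equal(directionality_track(contact_matrix("c", 1e4, m2), 4)$values[5],
               -10)
  ## distance-symmetric matrix: interior DI exactly 0
  dm <- decay_matrix(n = 30)
  di3 <- directionality_track(dm, 5)
  expect_equal(di3$values[6:25], rep(0, 20))
})

test_that("TAD calling returns nothing on structureless matrices and respects symmetry", {
  um <- contact_matrix("u", 1e4, matrix(5, 80, 80))
  res <- call_tads(um, window_w = 5)
  expect_equal(nrow(res$tads), 0)
  expect_equal(nrow(res$boundaries), 0)
  ## strong two-domain fixture: exactly one boundary at the block edge
  cm <- two_block_matrix(nb = 40, within = 8, cross = 2)
  res2 <- call_tads(cm, window_w = 5, min_size = 5, ins_delta = 1)
  expect_equal(nrow(res2$boundaries), 1)
  expect_lte(abs(res2$boundaries$score - 40), 1)
  expect_equal(nrow(res2$tads), 2)
  expect_true(all(res2$tads$score > 0))
})

test_that("loop calling ignores expectation-equal matrices and finds a planted focus", {
  dm <- decay_matrix(n = 300, scale = 50)
  expect_equal(nrow(call_loops(dm, min_dist = 5e4)), 0)
  ## single sharply elevated pixel over a flat background
  n <- 200
  m <- matrix(10, n, n)
  m[60, 100] <- 200; m[100, 60] <- 200
  cm <- contact_matrix("c", 1e4, m)
  found <- call_loops(cm, min_dist = 1e5)
  expect_equal(nrow(found), 1)
  expect_equal(floor((found$start1 + found$end1) / 2 / 1e4), 59)  # bin 60, 0-based 59
  expect_equal(floor((found$start2 + found$end2) / 2 / 1e4), 99)
})

test_that("2D merging unions nearby anchors transitively and order-independently", {
  a <- features2d("chr1", 1.000e6, 1.010e6, 2.000e6, 2.010e6, name = "a")
  b <- features2d("chr1", 1.005e6, 1.015e6, 2.005e6, 2.015e6, name = "b")
  mg <- merge_2d(list(a, b), tolerance_bp = 15000)
  expect_equal(nrow(mg), 1)
  expect_equal(mg$start1, 1.000e6)
  expect_equal(mg$end2, 2.015e6)
  expect_equal(mg$members, "a,b")
  ## disjoint sets concatenate
  c2 <- features2d("chr1", 5e6, 5.01e6, 6e6, 6.01e6, name = "c")
  expect_equal(nrow(merge_2d(list(a, c2), 15000)), 2)
  ## order independence on a random fixture
  set.seed(51)
  sets <- lapply(1:3, function(i)
    features2d("chr1", s <- sort(runif(8, 0, 1e7)), s + 1e4,
               s2 <- s + runif(8, 2e5, 1e6), s2 + 1e4,
               name = paste0("s", i, "_", 1:8)))
  m1 <- merge_2d(sets, 5e4)
  m2 <- merge_2d(rev(sets), 5e4)
  key <- function(x) x[order(x$start1, x$start2),
                       c("start1", "end1", "start2", "end2", "members")]
  expect_equal(key(m1), key(m2), ignore_attr = TRUE)
  expect_error(merge_2d(list(a, features2d("chr1", 1, 10, 20, 30,
                                           kind = "tad")), 1e4), "mixed kind")
})

test_that("feature scoring matches analytic expectations and the depth-ratio identity", {
  ## scoring the expectation matrix gives loop scores of exactly 1
  dm <- decay_matrix(n = 80, scale = 40)
  feats <- features2d("chrD", c(1e5, 3e5), c(1.1e5, 3.1e5),
                      c(5e5, 7e5), c(5.1e5, 7.1e5))
  st <- score_features(list(s1 = dm), feats, anchor_window = 15000)
  expect_equal(unname(st$raw[, 1]), c(1, 1), tolerance = 1e-12)

  ## ideal intensity matrix with a planted 5x loop window scores ~5 (the
  ## loop's own mass slightly inflates E(d), hence the loose tolerance)
  n <- 400
  d <- abs(outer(1:n, 1:n, "-"))
  lam <- 40 * (1 + d)^(-1)
  lam[20:22, 50:52] <- lam[20:22, 50:52] * 5
  lam[50:52, 20:22] <- t(lam[20:22, 50:52])
  cm <- contact_matrix("c", 1e4, lam)
  lf <- features2d("c", 20.0e4, 21.0e4, 50.0e4, 51.0e4)  # centred on bin 21/51
  st5 <- score_features(list(s1 = cm), lf, anchor_window = 15000)
  expect_equal(unname(st5$raw[1, 1]), 5, tolerance = 0.04)

  ## raw and normalised scores differ by exactly depth/target per sample
  set.seed(52)
  m <- matrix(rpois(80 * 80, 6), 80, 80); m <- m + t(m)
  s1 <- contact_matrix("c", 1e4, m)
  s2 <- normalize_depth(s1, 3 * s1$total)  # a 3x deeper sample
  target <- 2 * s1$total
  st2 <- score_features(list(a = s1, b = s2), feats2 <- features2d(
    "c", c(1e5, 2e5), c(1.1e5, 2.1e5), c(4e5, 6e5), c(4.1e5, 6.1e5)),
    anchor_window = 15000, normalize_total = target)
  expect_equal(st2$raw[, "a"] / st2$norm[, "a"], rep(s1$total / target, 2),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(st2$raw[, "b"] / st2$norm[, "b"], rep(s2$total / target, 2),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("size factors follow the printed ratio formula", {
  sf <- size_factors(list(raw_totals = c(a = 2e8, b = 4e8),
                          norm_totals = c(a = 5e8, b = 5e8)))
  expect_equal(unname(sf), c(0.4, 0.8))
  ## equal-depth samples get equal factors
  sf2 <- size_factors(list(raw_totals = c(3e8, 3e8),
                           norm_totals = c(5e8, 5e8)))
  expect_equal(sf2[1], sf2[2])
  expect_error(size_factors(list(raw_totals = 1, norm_totals = 0)), "zero")
  expect_error(size_factors(list(raw_totals = 1)), "normalised")
})

test_that("differential domain p-values are uniform under the null and vanish at huge thresholds", {
  set.seed(53)
  nfeat <- 1000
  raw <- matrix(exp(rnorm(nfeat * 6, log(20), 0.3)), nfeat, 6,
                dimnames = list(paste0("f", 1:nfeat), paste0("s", 1:6)))
  tab <- structure(list(
    features = features2d("c", s <- seq_len(nfeat) * 1e4, s + 1e3,
                          s + 5e5, s + 5.01e5, name = rownames(raw)),
    raw = raw, norm = raw,
    raw_totals = colSums(raw), norm_totals = colSums(raw)),
    class = "domain_score_table")
  design <- rep(c("x", "y"), each = 3)
  res <- differential_domains(tab, design, sf = rep(1, 6))
  ks <- ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.035); expect_lt(frac, 0.065)
  ## threshold far above any effect: no calls
  res2 <- differential_domains(tab, design, fc_threshold = 1e6, sf = rep(1, 6))
  expect_equal(sum(res2$q < 0.05, na.rm = TRUE), 0)
})

test_that("loop size comparison uses the exact Mann-Whitney machinery", {
  a <- features2d("c", s <- seq(1e5, 8e5, 1e5), s + 1e4, s + 2e5, s + 2.1e5)
  expect_equal(loop_size_comparison(a, a)$p, 1)
  b <- features2d("c", s, s + 1e4, s + 2e6, s + 2.001e6)  # 10x the span
  cmp <- loop_size_comparison(b, a)
  expect_lt(cmp$p, 0.001)  # exact enumeration, n = 8 per group
  expect_equal(unname(cmp$quartiles_b),
               unname(quantile(a$start2 - a$start1, c(.25, .5, .75))))
  expect_error(loop_size_comparison(a[0, ], a), "empty")
})
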
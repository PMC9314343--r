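test_that("BED and BEDPE lines parse to the documented data model", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tp1\t5\t+", "chr2\t50\t80"), bed)
  iv <- read_regions(bed)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(0, 50))
  expect_equal(iv$end, c(100, 80))
  expect_equal(iv$name[1], "p1")
  expect_equal(iv$score[1], 5)
  expect_equal(iv$strand, c("+", "."))

  pe <- tempfile(fileext = ".bedpe")
  writeLines("chr1 1000 1010 chr1 5000 5010", pe)
  f2 <- read_regions(pe, "BEDPE")
  expect_equal(f2$start1, 1000)
  expect_equal(f2$end1, 1010)
  expect_equal(f2$start2, 5000)
  expect_equal(f2$kind, "loop")
})

test_that("malformed region files fail with the offending line", {
  bad <- tempfile()
  writeLines(c("chr1\t0\t100", "chr1\t200\t100"), bad)
  expect_error(read_regions(bad, "BED"), "line 2")
  writeLines("chr1\t10", bad)
  expect_error(read_regions(bad, "BED"), "line 1")
})

test_that("region writers and readers round-trip randomized fixtures", {
  set.seed(11)
  iv <- random_intervals(100)
  f <- tempfile(fileext = ".bed")
  write_regions(iv, f)
  back <- read_regions(f)
  expect_equal(back[c("chrom", "start", "end", "name", "score", "strand")],
               iv[c("chrom", "start", "end", "name", "score", "strand")])

  loops <- features2d("chr1", c(1000, 8000), c(1500, 8500),
                      c(20000, 30000), c(20500, 30500),
                      name = c("a", "b"))
  f2 <- tempfile(fileext = ".bedpe")
  write_regions(loops, f2)
  back2 <- read_regions(f2)
  expect_equal(back2[c("chrom", "start1", "end1", "start2", "end2", "name")],
               loops[c("chrom", "start1", "end1", "start2", "end2", "name")])

  bg <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 250),
                   value = c(1.5, -2))
  f3 <- tempfile(fileext = ".bedgraph")
  write_bedgraph(bg, f3)
  expect_equal(read_bedgraph(f3), bg)

  seqs <- c(s1 = "ACGTACGT", s2 = "GGGTTTCC")
  f4 <- tempfile(fileext = ".fa")
  write_fasta(seqs, f4)
  expect_equal(read_fasta(f4), seqs)
})

test_that("contact matrices obey symmetry, the diagonal-once total policy, and round-trip", {
  lay <- genome_layout("chrZ", 3e4)
  tri <- tempfile()
  writeLines("0\t1\t5", tri)
  cm <- read_contact_matrix(tri, lay, "chrZ", 1e4, "triplet")
  expect_equal(cm$counts[1, 2], 5)
  expect_equal(cm$counts[2, 1], 5)

  dense <- tempfile()
  writeLines(c("4\t1", "1\t2"), dense)
  lay2 <- genome_layout("chrZ", 2e4)
  cm2 <- read_contact_matrix(dense, lay2, "chrZ", 1e4, "dense")
  expect_equal(cm2$total, 4 + 1 + 2)  # diagonal counted once

  ## asymmetry and negatives rejected
  writeLines(c("4\t1", "2\t2"), dense)
  expect_error(read_contact_matrix(dense, lay2, "chrZ", 1e4, "dense"),
               "asymmetric")
  writeLines("0\t1\t-3", tri)
  expect_error(read_contact_matrix(tri, lay, "chrZ", 1e4, "triplet"),
               "negative")

  ## triplet/dense round trip identity on a random matrix
  set.seed(7)
  n <- 6
  m <- matrix(rpois(n * n, 4), n, n)
  m <- m + t(m)
  cm3 <- contact_matrix("chrZ", 1e4, m)
  lay3 <- genome_layout("chrZ", n * 1e4)
  ft <- tempfile(); fd <- tempfile()
  write_contact_matrix(cm3, ft, "triplet")
  write_contact_matrix(cm3, fd, "dense")
  expect_equal(read_contact_matrix(ft, lay3, "chrZ", 1e4, "triplet")$counts,
               cm3$counts)
  expect_equal(read_contact_matrix(fd, lay3, "chrZ", 1e4, "dense")$counts,
               cm3$counts)
})

test_that("interval overlap follows half-open semantics and matches a per-bp oracle", {
  a <- intervals("chr1", 0, 100)
  b <- intervals("chr1", 50, 150)
  expect_equal(nrow(overlap_intervals(a, b, "any")), 1)
  ## zero-length touch is no overlap
  expect_equal(nrow(overlap_intervals(a, intervals("chr1", 100, 200), "any")), 0)
  ## subtract splits around the removed span
  sub <- overlap_intervals(intervals("chr1", 0, 100),
                           intervals("chr1", 40, 60), "subtract")
  expect_equal(sub$start, c(0, 60))
  expect_equal(sub$end, c(40, 100))

  set.seed(21)
  q <- random_intervals(60, max_len = 1e4)
  s <- random_intervals(40, max_len = 1e4)
  expect_equal(overlap_intervals(q, s, "count") > 0, bp_overlap_oracle(q, s))

  ## subtract agrees with a per-bp mask oracle
  subr <- overlap_intervals(q, s, "subtract")
  for (ch in unique(q$chrom)) {
    mask_cov <- rep(FALSE, 1e4)
    for (j in which(s$chrom == ch)) mask_cov[(s$start[j] + 1):s$end[j]] <- TRUE
    want <- rep(FALSE, 1e4)
    for (i in which(q$chrom == ch))
      want[(q$start[i] + 1):q$end[i]] <- want[(q$start[i] + 1):q$end[i]] | !mask_cov[(q$start[i] + 1):q$end[i]]
    got <- rep(FALSE, 1e4)
    for (i in which(subr$chrom == ch)) got[(subr$start[i] + 1):subr$end[i]] <- TRUE
    expect_equal(got, want)
  }
})

test_that("count tables validate and round-trip TSV", {
  expect_error(count_table(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  ct <- count_table(matrix(1:6, 2, dimnames = list(c("g1", "g2"), NULL)),
                    conditions = c("a", "a", "b"))
  f <- tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  back <- read_count_table(f, conditions = ct$conditions)
  expect_equal(back$counts, ct$counts)
})
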
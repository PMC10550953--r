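test_that("bridge breakage yields reciprocal terminal daughters", {
  gm <- one_chrom_genome()
  k <- diploid_karyotype(gm)
  d <- apply_bfb_break(k, "chr1", "A", 60e6, gm)
  d1 <- simplify_karyotype(d$daughter1)
  d2 <- simplify_karyotype(d$daughter2)
  expect_equal(d1$cnA, c(1L, 0L))
  expect_equal(d2$cnA, c(1L, 2L))
  expect_equal(d1$start, c(0, 0) + c(0, 60e6))
  expect_equal(d1$cnB, c(1L, 1L))

  expect_error(apply_bfb_break(k, "chr1", "A", 0, gm), "inside")
  expect_error(apply_bfb_break(k, "chr1", "A", 150e6, gm), "inside")
  lost <- apply_terminal(k, "chr1", "A", 40e6, -1L, gm)
  expect_error(apply_bfb_break(lost, "chr1", "A", 80e6, gm), "copy number 0")
})

test_that("daughter pairs conserve copy number bin-wise over random breaks", {
  gm <- one_chrom_genome()
  set.seed(21)
  k <- diploid_karyotype(gm)
  # start from a non-trivial parent
  k <- apply_internal_segment(k, "chr1", "B", 30e6, 80e6, 1L, gm)
  for (i in 1:100) {
    bp <- runif(1, 1e6, 149e6)
    d <- apply_bfb_break(k, "chr1", "A", bp, gm)
    pb <- karyotype_bins(k, gm, 1e6)
    b1 <- karyotype_bins(d$daughter1, gm, 1e6)
    b2 <- karyotype_bins(d$daughter2, gm, 1e6)
    expect_identical(b1$total + b2$total, 2L * pb$total)
    validate_karyotype(d$daughter1, gm)
    validate_karyotype(d$daughter2, gm)
  }
})

test_that("internal segments classify as paracentric or pericentric", {
  gm <- one_chrom_genome()  # centromere at 59.5-60.5 Mb
  k <- diploid_karyotype(gm)
  para <- apply_internal_segment(k, "chr1", "A", 30e6, 50e6, -1L, gm)
  expect_equal(attr(para, "arm_class"), "paracentric")
  expect_equal(sort(unique(para$cnA)), c(0L, 1L))
  peri <- apply_internal_segment(k, "chr1", "A", 40e6, 90e6, 1L, gm)
  expect_equal(attr(peri, "arm_class"), "pericentric")
  expect_error(apply_internal_segment(k, "chr1", "A", 0, 50e6, -1L, gm),
               "terminal")
  zeroed <- apply_internal_segment(k, "chr1", "A", 30e6, 50e6, -1L, gm)
  expect_error(apply_internal_segment(zeroed, "chr1", "A", 35e6, 45e6,
                                      -1L, gm), "negative")
})

test_that("chromothripsis retention follows the configured probability", {
  gm <- one_chrom_genome()
  k <- diploid_karyotype(gm)
  same <- apply_chromothripsis(k, "chr1", "A", c(30e6, 90e6), 10, 1, seed = 5)
  expect_equal(simplify_karyotype(same)$cnA, 1L)
  gone <- apply_chromothripsis(k, "chr1", "A", c(30e6, 90e6), 10, 0, seed = 5)
  sg <- simplify_karyotype(gone)
  expect_equal(sg$cnA, c(1L, 0L, 1L))
  # per-seed audit: lost fragments in the karyotype match the draw
  set.seed(33)
  ks <- apply_chromothripsis(k, "chr1", "A", c(30e6, 90e6), 12, 0.5)
  fr <- attr(ks, "fragments")
  for (i in seq_len(nrow(fr))) {
    mid <- (fr$start[i] + fr$end[i]) / 2
    cn <- karyotype_bins(ks, gm, 1e6)  # coarse check at fragment midpoints
    expect_equal(unname(ks$cnA[ks$start <= mid & ks$end > mid][1]),
                 if (fr$retained[i]) 1L else 0L)
  }
  # binomial expectation over seeds
  set.seed(8)
  retained <- replicate(50, sum(attr(apply_chromothripsis(
    k, "chr1", "A", c(30e6, 90e6), 10, 0.5), "fragments")$retained))
  expect_lt(abs(mean(retained) - 5), 3 * sqrt(10 * 0.25 / 50))
})

test_that("BFB amplification doubles per round and breaks the terminus", {
  gm <- one_chrom_genome()
  k <- diploid_karyotype(gm)
  amp <- apply_bfb_amplification(k, "chr1", "A", c(140e6, 143e6), 3, gm)
  expect_equal(max(amp$cnA), 8L)
  expect_equal(min(amp$cnA[amp$start >= 143e6]), 0L)  # broken flank lost
  expect_identical(apply_bfb_amplification(k, "chr1", "A",
                                           c(140e6, 143e6), 0, gm), k)
  k2 <- k; k2$cnA <- 2L
  amp2 <- apply_bfb_amplification(k2, "chr1", "A", c(140e6, 143e6), 2, gm)
  expect_equal(max(amp2$cnA), 8L)
})

test_that("WGD, missegregation and UPD behave as defined", {
  gm <- one_chrom_genome()
  k <- diploid_karyotype(gm)
  k21 <- apply_missegregation(k, "chr1", "A", 1L)  # (2,1)
  w <- apply_wgd(k21)
  expect_equal(unique(w$cnA), 4L)
  expect_equal(unique(w$cnB), 2L)
  u <- apply_upd(k, "chr1", c(0, 150e6), "A")
  expect_equal(unique(u$cnA), 2L)
  expect_equal(unique(u$cnB), 0L)
  expect_equal(karyotype_ploidy(u), karyotype_ploidy(k))  # copy-neutral
  lost <- apply_missegregation(k, "chr1", "B", -1L)
  expect_error(apply_missegregation(lost, "chr1", "B", -1L), "negative")
  expect_error(apply_upd(lost, "chr1", c(0, 150e6), "B"), "copy number 0")
})

test_that("every operator preserves the tiling invariant", {
  gm <- small_genome()
  k <- diploid_karyotype(gm)
  set.seed(4)
  ops <- list(
    function(k) apply_terminal(k, "chr1", "A", 3e7, 1L, gm),
    function(k) apply_internal_segment(k, "chr2", "B", 5e6, 1.2e7, 1L, gm),
    function(k) apply_chromothripsis(k, "chr1", "B", c(1e7, 3e7), 8, 0.5),
    function(k) apply_upd(k, "chr2", c(2e7, 4e7), "A"),
    function(k) apply_wgd(k),
    function(k) apply_focal(k, "chr1", "A", c(4e7, 4.2e7), -1L)
  )
  for (op in ops) {
    k <- op(k)
    expect_true(validate_karyotype(k, gm))
  }
})
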
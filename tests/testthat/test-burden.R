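mk_ev <- function(sample, chrom, homolog, category) {
  data.frame(sample = sample, chrom = chrom, homolog = homolog,
             category = category, start = 0, end = 1e6,
             breakpoints = "1", copy_change = -1,
             footprint = NA_character_, complexity = "simple",
             stringsAsFactors = FALSE)
}

test_that("burden counts altered homologs once with category precedence", {
  hg <- simulate_genome(setNames(rep(50e6, 22), paste0("chr", 1:22)),
                        het_density = 0, seed = 1)
  # every autosome, both homologs altered -> the 44 maximum
  full <- do.call(rbind, lapply(paste0("chr", 1:22), function(cn)
    rbind(mk_ev("S1", cn, "A", "terminal_loss"),
          mk_ev("S1", cn, "B", "focal_del"))))
  b <- compute_burden(full, hg)
  expect_equal(b$total, 44)
  expect_equal(b$segmental + b$local + b$upd + b$arm, 44)
  # no events
  b0 <- compute_burden(full[0, ], hg)
  expect_equal(b0$total, 0)
  # UPD + later segmental loss on the same homolog counts once, segmental
  both <- rbind(mk_ev("S1", "chr1", "A", "UPD"),
                mk_ev("S1", "chr1", "A", "terminal_loss"))
  b2 <- compute_burden(both, hg)
  expect_equal(b2$total, 1)
  expect_equal(b2$segmental, 1)
  expect_equal(b2$upd, 0)
})

test_that("allelic distribution splits mono/bi-allelic and genome scope", {
  ev <- rbind(
    # chr1: same loss seen in two samples, one homolog -> mono, multi-genome
    within(mk_ev("S1", "chr1", "A", "terminal_loss"), breakpoints <- "5e6"),
    within(mk_ev("S2", "chr1", "A", "terminal_loss"), breakpoints <- "9e6"),
    # chr2: a single event
    mk_ev("S1", "chr2", "A", "paracentric_loss"),
    # chr3: both homologs in one sample -> bi-allelic, single-genome
    within(mk_ev("S1", "chr3", "A", "terminal_loss"), breakpoints <- "2e6"),
    within(mk_ev("S1", "chr3", "B", "terminal_loss"), breakpoints <- "8e6"))
  ad <- allelic_distribution(ev)
  expect_equal(ad$pattern[ad$chrom == "chr1"], "mono-allelic")
  expect_equal(ad$scope[ad$chrom == "chr1"], "multi-genome")
  expect_equal(ad$pattern[ad$chrom == "chr2"], "single")
  expect_equal(ad$pattern[ad$chrom == "chr3"], "bi-allelic")
  expect_equal(ad$scope[ad$chrom == "chr3"], "single-genome")
})

test_that("genome state fractions respect the WGD-adjusted threshold", {
  # clean diploid
  dip <- data.frame(chrom = "chr1", start = 0, end = 1e8,
                    rawA = 1, rawB = 1, cnA = 1L, cnB = 1L)
  expect_true(all(genome_fraction_states(dip) == 0))
  # one homolog arm lost over 10% of the genome
  seg <- data.frame(chrom = c("chr1", "chr1"), start = c(0, 2e7),
                    end = c(2e7, 1e8),
                    rawA = c(0.02, 1), rawB = c(1, 1),
                    cnA = c(0L, 1L), cnB = c(1L, 1L))
  fr <- genome_fraction_states(seg)
  expect_equal(unname(fr["deletion"]), 0.10, tolerance = 0.01)
  # (2,2) WGD genome: no duplication under the >= 3 threshold
  wgd <- data.frame(chrom = "chr1", start = 0, end = 1e8,
                    rawA = 2, rawB = 2, cnA = 2L, cnB = 2L)
  expect_equal(unname(genome_fraction_states(wgd, wgd = TRUE)["duplication"]),
               0)
  expect_equal(unname(genome_fraction_states(wgd, wgd = FALSE)["duplication"]),
               1)
  # subclonal states partition with the integer states
  sub <- data.frame(chrom = "chr1", start = 0, end = 1e8,
                    rawA = 0.5, rawB = 1.6, cnA = 1L, cnB = 2L)
  fs <- genome_fraction_states(sub)
  expect_equal(unname(fs["subclonal_loss"]), 0.5)
  expect_equal(unname(fs["subclonal_gain"]), 0.5)
  expect_lte(sum(fs), 1)
})

test_that("group comparisons report rank-sum tests with effect sizes", {
  set.seed(91)
  v <- c(rnorm(10, 10), rnorm(10, 10))
  g <- rep(c("a", "b"), each = 10)
  res <- compare_groups(v, g)
  expect_gt(res$tests$p, 0.05)
  shifted <- compare_groups(c(rnorm(20, 10), rnorm(20, 20)),
                            rep(c("a", "b"), each = 20))
  expect_lt(shifted$tests$p, 0.01)
  expect_gt(abs(shifted$tests$effect), 0.5)
  tiny <- compare_groups(c(1, 5, 6, 7), c("a", "b", "b", "b"))
  expect_true(is.na(tiny$tests$p))
  expect_match(tiny$tests$note, "too small")
  fish <- compare_groups(v, g, counts = matrix(c(20, 5, 6, 18), 2))
  expect_lt(fish$fisher$p, 0.01)
})

test_that("rank-sum power and type-I error are calibrated", {
  set.seed(92)
  # power: shift of 10 at n = 20/20
  rej <- mean(replicate(200, {
    wilcox.test(rpois(20, 12), rpois(20, 22), exact = FALSE)$p.value < 0.01
  }))
  expect_gte(rej, 0.95)
  # type-I error at nominal 0.05 stays below 0.06
  fp <- mean(replicate(1000, {
    wilcox.test(rnorm(10), rnorm(10))$p.value < 0.05
  }))
  expect_lte(fp, 0.06)
})
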
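test_that("het-site selection applies the four cohort filters", {
  # six sites built to violate each rule once; two survive
  het <- rbind(c(TRUE, TRUE, FALSE, FALSE),   # good
               c(FALSE, FALSE, FALSE, FALSE), # no het call
               c(TRUE, TRUE, FALSE, FALSE),   # only 1 sample alt>2
               c(TRUE, TRUE, FALSE, FALSE),   # only 1 sample ref>2
               c(TRUE, TRUE, TRUE, TRUE),     # het in 100% of cohort
               c(TRUE, FALSE, TRUE, FALSE))   # good
  alt <- rbind(c(10, 12, 0, 0),
               c(10, 12, 0, 0),
               c(10, 2, 1, 0),
               c(10, 12, 30, 30),
               c(10, 12, 9, 11),
               c(8, 0, 9, 0))
  ref <- rbind(c(9, 11, 30, 28),
               c(9, 11, 30, 28),
               c(9, 11, 30, 28),
               c(9, 2, 0, 1),
               c(10, 9, 11, 12),
               c(7, 25, 8, 30))
  g <- list(het = het, alt = alt, ref = ref)
  expect_equal(select_het_sites(g), c(1L, 6L))
  # all-homozygous matrix: nothing survives
  g0 <- list(het = het & FALSE, alt = alt, ref = ref)
  expect_length(select_het_sites(g0), 0)
  # fully heterozygous site removed by the Hardy-Weinberg bound
  expect_false(5L %in% select_het_sites(g))
  expect_length(select_het_sites(list(het = het[0, ], alt = alt[0, ],
                                      ref = ref[0, ])), 0)
})

test_that("the Hardy-Weinberg heterozygote bound is one half", {
  expect_equal(hardy_weinberg_max_het(), 0.5, tolerance = 1e-6)
})

test_that("windowed imbalance reflects allelic copy state", {
  df <- data.frame(chrom = "chr1", pos = seq(1e4, 2e6, by = 1e4))
  n <- nrow(df)
  # balanced first Mb, (2,0)-like second Mb, zero-depth tail window
  bal <- df$pos < 1e6
  df$depthA <- ifelse(bal, 10L, 20L)
  df$depthB <- ifelse(bal, 10L, 0L)
  df$depthA[df$pos > 1.95e6] <- 0L
  df$depthB[df$pos > 1.95e6] <- 0L
  wi <- window_allelic_imbalance(allelic_from_df(df), 5e4, min_total = 50)
  expect_true(all(abs(wi$stat[wi$start < 1e6]) < 0.01))
  mid <- wi$start >= 1e6 & wi$end <= 1.95e6
  expect_true(all(wi$stat[mid] == 1))
  expect_false(any(wi$informative[wi$start >= 1.95e6]))
})

test_that("a single switch error is located within one het-site spacing", {
  set.seed(10)
  pos <- sort(runif(4000, 0, 2e7))
  switch_at <- 1.2e7
  truth_flip <- pos > switch_at
  mk <- function() {
    a <- rpois(length(pos), 18) + 2L  # (2,0): all depth on hap A
    b <- integer(length(pos))
    dA <- ifelse(truth_flip, b, a)
    dB <- ifelse(truth_flip, a, b)
    cbind(dA, dB)
  }
  s1 <- mk(); s2 <- mk(); s3 <- mk()
  al <- list(sites = data.frame(chrom = "chr1", pos = pos),
             depthA = cbind(S1 = s1[, 1], S2 = s2[, 1], S3 = s3[, 1]),
             depthB = cbind(S1 = s1[, 2], S2 = s2[, 2], S3 = s3[, 2]))
  cs <- correct_switch_errors(al)
  fl <- cs$flip$chr1
  # flipped set equals the switched tail, up to one het site at the boundary
  expect_lt(sum(fl != truth_flip), 2)
  # depths are permuted within site, never altered
  tot0 <- al$depthA + al$depthB
  tot1 <- cs$allelic$depthA + cs$allelic$depthB
  expect_identical(unname(tot0), unname(tot1))
  # corrected signs are concordant within the region
  d <- cs$allelic$depthA[, 1] - cs$allelic$depthB[, 1]
  expect_true(all(d >= 0))
  # idempotence: a second pass flips nothing
  cs2 <- correct_switch_errors(cs$allelic)
  expect_equal(sum(unlist(cs2$flip)), 0)
})

test_that("balanced genomes are left untouched", {
  set.seed(12)
  pos <- sort(runif(2000, 0, 1e7))
  a <- matrix(rpois(3 * length(pos), 10), ncol = 3,
              dimnames = list(NULL, c("S1", "S2", "S3")))
  b <- matrix(rpois(3 * length(pos), 10), ncol = 3,
              dimnames = list(NULL, c("S1", "S2", "S3")))
  al <- list(sites = data.frame(chrom = "chr1", pos = pos),
             depthA = a, depthB = b)
  cs <- correct_switch_errors(al)
  expect_equal(sum(unlist(cs$flip)), 0)
  expect_identical(cs$allelic$depthA, a)
})

test_that("switch errors inside imbalanced regions are strongly reduced", {
  gm <- small_genome(seed = 31)
  k <- apply_upd(diploid_karyotype(gm), "chr1", c(0, 6e7), "A")  # (2,0)
  cfg <- render_config(n_panel = 0)
  set.seed(77)
  bias <- make_bias_profile(gm, cfg)
  ori <- haplocna:::draw_switch_orientation(gm, cfg$switch_rate)
  dA <- NULL; dB <- NULL; sites <- NULL
  for (s in 1:3) {
    r <- render_bulk(list(k), 0.7, gm, cfg, bias, ori)
    if (is.null(sites)) sites <- r$allelic[, c("chrom", "pos")]
    dA <- cbind(dA, r$allelic$depthA)
    dB <- cbind(dB, r$allelic$depthB)
  }
  colnames(dA) <- colnames(dB) <- paste0("S", 1:3)
  cs <- correct_switch_errors(list(sites = sites, depthA = dA, depthB = dB))
  sel <- sites$chrom == "chr1"
  input_sw <- count_switch_points(ori$chr1)
  rel <- ori$chr1 * ifelse(cs$flip$chr1, -1L, 1L)
  resid_sw <- count_switch_points(rel)
  expect_gt(input_sw, 50)  # the chromosome really carries switch errors
  expect_lt(resid_sw, input_sw / 5)
})

test_that("two-pass correction selects exactly the aneuploid cells", {
  gm <- simulate_genome(c(chr1 = 4e7, chr2 = 3e7), het_density = 1 / 3000,
                        seed = 41)
  k_dip <- diploid_karyotype(gm)
  k_aneu <- apply_missegregation(k_dip, "chr1", "B", -1L)  # (1,0) chr1
  set.seed(55)
  n_aneu <- 8; n_dip <- 16
  dA <- NULL; dB <- NULL; sites <- NULL
  for (i in seq_len(n_aneu + n_dip)) {
    k <- if (i <= n_aneu) k_aneu else k_dip
    r <- render_single_cell(k, gm, depth = 60, site_depth = 1.2)
    if (is.null(sites)) sites <- r$allelic[, c("chrom", "pos")]
    dA <- cbind(dA, r$allelic$depthA)
    dB <- cbind(dB, r$allelic$depthB)
  }
  cells <- paste0("cell", seq_len(n_aneu + n_dip))
  colnames(dA) <- colnames(dB) <- cells
  res <- two_pass_correct_cells(list(sites = sites, depthA = dA,
                                     depthB = dB))
  expect_equal(res$pass, 2L)
  expect_setequal(res$aneuploid_cells, cells[seq_len(n_aneu)])
  # all-diploid collection takes the warning path
  dip <- list(sites = sites,
              depthA = dA[, (n_aneu + 1):(n_aneu + n_dip)],
              depthB = dB[, (n_aneu + 1):(n_aneu + n_dip)])
  expect_warning(r2 <- two_pass_correct_cells(dip), "no aneuploid")
  expect_equal(r2$pass, 1L)
})
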
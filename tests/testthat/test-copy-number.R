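make_flat_obs <- function(seed = 1, n_bins = 2000, n_panel = 4) {
  set.seed(seed)
  gc <- pmin(0.65, pmax(0.3, 0.45 + 0.05 * sin(seq_len(n_bins) / 50) +
                          rnorm(n_bins, 0, 0.01)))
  bias <- exp(0.4 * (gc - 0.45) - 3 * (gc - 0.45)^2 +
                0.1 * sin(seq_len(n_bins) / 200))
  counts <- rpois(n_bins, 1000 * bias)
  panel <- sapply(seq_len(n_panel), function(i) rpois(n_bins, 1000 * bias))
  list(counts = counts, panel = panel, gc = gc, bias = bias)
}

test_that("panel normalization flattens shared bias to within 2%", {
  o <- make_flat_obs()
  norm <- normalize_bulk(o$counts, o$panel, o$gc)
  expect_lt(sd(norm, na.rm = TRUE), 0.05)
  expect_lt(abs(mean(norm, na.rm = TRUE) - 1), 0.02)
  # the shared (GC + recurrent) bias itself is removed, not just averaged
  expect_lt(abs(stats::cor(norm, o$bias)), 0.25)
})

test_that("normalization is scale invariant and masks dead panel bins", {
  o <- make_flat_obs(seed = 2)
  n1 <- normalize_bulk(o$counts, o$panel, o$gc)
  n2 <- normalize_bulk(o$counts * 7L, o$panel, o$gc)
  expect_equal(unname(n1), unname(n2), tolerance = 1e-8)
  panel0 <- o$panel; panel0[5, ] <- 0L
  n3 <- normalize_bulk(o$counts, panel0, o$gc)
  expect_true(attr(n3, "masked")[5])
  expect_true(is.na(n3[5]))
  expect_error(normalize_bulk(o$counts, o$panel[, 1:2], o$gc), ">= 3")
})

test_that("eigensample denoising removes panel-spanned bias only", {
  set.seed(3)
  n <- 1000; m <- 12
  u1 <- sin(seq_len(n) / 40); u2 <- cos(seq_len(n) / 90)
  panel <- exp(outer(u1, rnorm(m, 0, 0.2)) + outer(u2, rnorm(m, 0, 0.2)))
  # k = 0 is the identity (up to recentering)
  x <- exp(0.3 * u1)
  same <- denoise_with_eigensamples(x, panel, k = 0)
  expect_equal(unname(same / mean(same)), unname(x / mean(x)),
               tolerance = 1e-8)
  # bias inside the panel span vanishes
  den <- denoise_with_eigensamples(x, panel, k = 2)
  expect_lt(sd(log(den)), 0.01)
  # true signal orthogonal to the panel span survives
  step <- exp(c(rep(0, n / 2), rep(0.5, n / 2)))
  den2 <- denoise_with_eigensamples(step, panel, k = 2)
  ratio <- mean(den2[(n / 2 + 1):n]) / mean(den2[1:(n / 2)])
  expect_lt(abs(ratio - exp(0.5)) / exp(0.5), 0.01)
  expect_error(denoise_with_eigensamples(x, panel, k = 20), "panel size")
})

test_that("haplotype coverage splits total by smoothed allelic fraction", {
  gm <- small_genome(seed = 13)
  k <- apply_upd(diploid_karyotype(gm), "chr1", c(0, 6e7), "A")
  cfg <- render_config(switch_rate = 0, n_panel = 3)
  set.seed(9)
  bias <- make_bias_profile(gm, cfg)
  r <- render_bulk(list(k), 1, gm, cfg, bias)
  norm <- r$counts / bias$bias / mean(r$counts / bias$bias)
  al <- list(sites = r$allelic[, c("chrom", "pos")],
             depthA = r$allelic$depthA, depthB = r$allelic$depthB)
  hap <- haplotype_coverage(norm, al, bias[, c("chrom", "start", "end")])
  expect_equal(hap$hapA + hap$hapB, hap$total)
  expect_lt(mean(hap$hapB[hap$chrom == "chr1"]), 0.02)       # (2,0) at purity 1
  expect_lt(abs(mean(hap$hapA[hap$chrom == "chr2"]) -
                  mean(hap$hapB[hap$chrom == "chr2"])), 0.05) # (1,1) split
  # purity 0.5 mixture: hap B fraction of total is (0.5*0+0.5)/2 = 0.25
  r5 <- render_bulk(list(k), 0.5, gm, cfg, bias)
  norm5 <- r5$counts / bias$bias / mean(r5$counts / bias$bias)
  al5 <- list(sites = r5$allelic[, c("chrom", "pos")],
              depthA = r5$allelic$depthA, depthB = r5$allelic$depthB)
  hap5 <- haplotype_coverage(norm5, al5, bias[, c("chrom", "start", "end")])
  sel <- hap5$chrom == "chr1"
  expect_lt(abs(mean(hap5$hapB[sel] / hap5$total[sel]) - 0.25), 0.03)
})

test_that("segmentation finds exact noiseless steps and nothing else", {
  hap <- data.frame(chrom = "chr1",
                    start = seq(0, 25e6 - 25e3, by = 25e3))
  hap$end <- hap$start + 25e3
  hap$hapA <- ifelse(hap$start >= 1e7, 2, 1) + rnorm(nrow(hap), 0, 1e-4)
  hap$hapB <- 1 + rnorm(nrow(hap), 0, 1e-4)
  seg <- segment_profile(hap)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$start[2], 1e7)
  flat <- hap; flat$hapA <- 1 + rnorm(nrow(hap), 0, 1e-4)
  expect_equal(nrow(segment_profile(flat)), 1)
})

test_that("segment boundaries are recovered within two bins under noise", {
  set.seed(23)
  hits <- 0
  for (r in 1:50) {
    n <- 800
    bp_bin <- sample(200:600, 1)
    hapA <- ifelse(seq_len(n) >= bp_bin, 1.5, 1) + rnorm(n, 0, 0.09)
    hapB <- 0.5 + rnorm(n, 0, 0.09)
    hap <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 25e3,
                      end = seq_len(n) * 25e3, hapA = hapA, hapB = hapB)
    seg <- segment_profile(hap)
    if (any(abs(seg$start / 25e3 + 1 - bp_bin) <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("purity and ploidy are exactly recoverable from clean segments", {
  # truth: purity 1, karyotype with states (1,1), (2,1), (2,0), ploidy 2.4
  w <- c(4e7, 3e7, 3e7)
  states <- rbind(c(1, 1), c(2, 1), c(2, 0))
  ploidy <- sum(w * rowSums(states)) / sum(w)
  for (p in c(1, 0.6)) {
    D <- p * ploidy + 2 * (1 - p)
    seg <- data.frame(chrom = "chr1", start = cumsum(c(0, w[-3])),
                      end = cumsum(w), n_bins = w / 25e3,
                      hapA = (p * states[, 1] + (1 - p)) / D,
                      hapB = (p * states[, 2] + (1 - p)) / D)
    seg$total <- seg$hapA + seg$hapB
    fit <- estimate_purity_ploidy(seg)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$purity - p), 0.011)
    expect_lt(abs(fit$ploidy - ploidy), 0.051)
    call <- call_integer_cn(seg, fit$purity, fit$ploidy)
    expect_equal(call$karyotype$cnA, states[, 1])
    expect_equal(call$karyotype$cnB, states[, 2])
    expect_false(any(call$diagnostics$subclonal))
  }
})

test_that("SCNA-free samples are reported indeterminate", {
  seg <- data.frame(chrom = "chr1", start = 0, end = 1e8, n_bins = 4000,
                    hapA = 0.5, hapB = 0.5, total = 1)
  fit <- estimate_purity_ploidy(seg)
  expect_equal(fit$status, "indeterminate")
  expect_true(is.na(fit$purity))
})

test_that("subclonal mixtures are flagged and calls never go negative", {
  # a 50/50 subclonal segment sits halfway between integer states
  seg <- data.frame(chrom = "chr1",
                    start = c(0, 4e7, 8e7), end = c(4e7, 8e7, 1.2e8),
                    n_bins = rep(1600, 3),
                    hapA = c(1, 1.5, 2) / 2.5, hapB = c(1, 1, 0.02) / 2.5)
  seg$total <- seg$hapA + seg$hapB
  call <- call_integer_cn(seg, purity = 1, ploidy = 2.5 - 2 + 2 * 0.5 + 1)
  expect_true(all(call$karyotype$cnA >= 0 & call$karyotype$cnB >= 0))
  call2 <- call_integer_cn(seg, purity = 1, ploidy = 2.52)
  residA <- abs(call2$diagnostics$rawA - round(call2$diagnostics$rawA))
  residB <- abs(call2$diagnostics$rawB - round(call2$diagnostics$rawB))
  expect_equal(call2$diagnostics$subclonal,
               residA > 0.3 | residB > 0.3)
})
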
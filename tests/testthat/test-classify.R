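test_that("definitional single events classify to their category", {
  gm <- default_genome()
  k0 <- diploid_karyotype(gm)

  term <- apply_terminal(k0, "chr1", "A", 70e6, -1L, gm)
  ev <- classify_chromosome(term, "chr1", gm)
  expect_equal(ev$category, "terminal_loss")
  expect_equal(ev$breakpoints, "7e+07")
  expect_equal(ev$homolog, "A")

  upd <- apply_upd(k0, "chr1", c(60.5e6, 150e6), "A")
  ev <- classify_chromosome(upd, "chr1", gm)
  expect_equal(ev$category, c("UPD"))
  expect_equal(ev$copy_change, 0)

  # 12 alternating (1 <-> 0) segments inside 30 Mb
  ct <- k0
  for (s in seq(30e6, 30e6 + 11 * 2.5e6, by = 5e6))
    ct <- apply_focal(ct, "chr1", "A", c(s, s + 2.5e6), -1L)
  ct <- simplify_karyotype(ct)
  ev <- classify_chromosome(ct, "chr1", gm)
  expect_true("chromothripsis" %in% ev$category)

  amp <- apply_bfb_amplification(k0, "chr1", "A", c(140e6, 143e6), 3, gm)
  ev <- classify_chromosome(amp, "chr1", gm)
  expect_true("amplification" %in% ev$category)
  expect_equal(sum(ev$category == "amplification"), 1)
})

test_that("amplification calls are exactly the segments at CN >= 8", {
  gm <- default_genome()
  k <- diploid_karyotype(gm)
  k <- apply_focal(k, "chr1", "A", c(20e6, 22e6), 6L)  # CN 7: no call
  ev <- classify_chromosome(k, "chr1", gm)
  expect_false("amplification" %in% ev$category)
  k8 <- apply_focal(k, "chr1", "A", c(21e6, 21.5e6), 1L)  # CN 8 inside
  ev8 <- classify_chromosome(simplify_karyotype(k8), "chr1", gm)
  amp <- ev8[ev8$category == "amplification", ]
  expect_equal(nrow(amp), 1)
  expect_equal(c(amp$start, amp$end), c(21e6, 21.5e6))
})

test_that("the classifier recovers generating categories on random draws", {
  gm <- default_genome()
  cats <- c("terminal_gain", "terminal_loss", "paracentric_gain",
            "paracentric_loss", "pericentric_gain", "pericentric_loss",
            "UPD", "arm_gain", "arm_loss", "whole_chrom_gain",
            "whole_chrom_loss", "focal_del", "focal_dup",
            "amplification", "chromothripsis")
  set.seed(61)
  for (rep in 1:3) for (cat in cats) {
    sim <- simulate_single_event(gm, cat)
    ev <- classify_chromosome(sim$karyotype, sim$chrom, gm)
    expect_true(cat %in% ev$category,
                info = paste("category", cat, "replicate", rep))
  }
})

test_that("chromothripsis footprints follow the adjacency rules", {
  gm <- default_genome()
  k0 <- diploid_karyotype(gm)
  # oscillation abutting a terminal-loss boundary: direct-bridge
  k <- apply_terminal(k0, "chr1", "A", 100e6, -1L, gm)
  for (s in seq(72.2e6, 72.2e6 + 4 * 6e6, by = 6e6))
    k <- apply_focal(k, "chr1", "A", c(s, s + 3e6), -1L)
  k <- simplify_karyotype(k)
  ev <- classify_chromosome(k, "chr1", gm)
  ct <- ev[ev$category == "chromothripsis", ][1, ]
  fp <- classify_chromothripsis_footprint(ct, ev, gm)
  expect_equal(fp, "direct-bridge")
  # telomere-reaching oscillation: downstream-micronucleus
  k2 <- k0
  for (s in seq(0.5e6, 0.5e6 + 4 * 11.2e6, by = 11.2e6))
    k2 <- apply_focal(k2, "chr1", "B", c(s, s + 5.6e6), -1L)
  ev2 <- classify_chromosome(simplify_karyotype(k2), "chr1", gm)
  ct2 <- ev2[ev2$category == "chromothripsis", ][1, ]
  expect_equal(classify_chromothripsis_footprint(ct2, ev2, gm),
               "downstream-micronucleus")
  # isolated interior oscillation: regional
  k3 <- k0
  for (s in seq(65e6, 65e6 + 9 * 3e6, by = 6e6))
    k3 <- apply_focal(k3, "chr1", "B", c(s, s + 3e6), -1L)
  ev3 <- classify_chromosome(simplify_karyotype(k3), "chr1", gm)
  ct3 <- ev3[ev3$category == "chromothripsis", ][1, ]
  expect_equal(classify_chromothripsis_footprint(ct3, ev3, gm), "regional")
})

test_that("WGD inference tolerates extensive post-WGD losses", {
  gm <- small_genome()
  dip <- diploid_karyotype(gm)
  expect_false(infer_wgd_bulk(dip))
  expect_true(infer_wgd_bulk(apply_wgd(dip)))
  tri <- apply_missegregation(dip, "chr2", "A", 1L)
  expect_false(infer_wgd_bulk(tri))
  # WGD followed by losses over ~30% of the genome: still called
  set.seed(71)
  k <- apply_wgd(dip)
  k <- apply_terminal(k, "chr1", "A", 4e7, -1L, gm)   # 20 Mb to (1,.)
  k <- apply_missegregation(k, "chr2", "B", -1L)
  k <- kar_edit(k, "chr2", "B", 0, 4e7, -1L) # chr2 B to 0: 40+20=60Mb of 100
  expect_true(infer_wgd_bulk(k))
})

test_that("rearrangement filtering applies both distance rules", {
  cands <- data.frame(
    chrom1 = "chr1", pos1 = c(10e6, 20e6, 30e6),
    chrom2 = "chr1", pos2 = c(10.05e6, 30.02e6, 30.5e6),
    support = c(5, 8, 3))
  cps <- data.frame(chrom = "chr1", pos = c(20e6, 30e6))
  kept <- filter_rearrangements(cands, cps)
  # pair 1: intra-pair distance 50 kb < 100 kb -> dropped
  # pair 2: both ends within 100 kb of changepoints -> kept
  # pair 3: second end 500 kb from any changepoint -> dropped
  expect_equal(kept$pos1, 20e6)
})
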
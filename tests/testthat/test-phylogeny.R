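mk_event <- function(chrom = "chr1", homolog = "A", category = "terminal_loss",
                     bps, copy_change = -1, sample = "S1") {
  data.frame(sample = sample, chrom = chrom, homolog = homolog,
             category = category, start = min(bps), end = max(bps),
             breakpoints = paste(sort(bps), collapse = ","),
             copy_change = copy_change, footprint = NA_character_,
             complexity = "segmental", stringsAsFactors = FALSE)
}

test_that("breakpoint matching follows the 0.1 Mb direction-aware rule", {
  a <- mk_event(bps = 60.00e6, copy_change = -1)
  b <- mk_event(bps = 60.05e6, copy_change = -1, sample = "S2")
  g <- mk_event(bps = 60.05e6, copy_change = +1, sample = "S2")
  far <- mk_event(bps = 60.2e6, copy_change = -1, sample = "S2")
  expect_equal(match_breakpoints(a, b)$relation, "identical")
  expect_equal(match_breakpoints(a, g)$relation, "complementary")
  expect_equal(match_breakpoints(a, far)$relation, "distinct")
  # symmetric
  expect_equal(match_breakpoints(b, a)$relation, "identical")
  other_hom <- mk_event(bps = 60.0e6, homolog = "B", sample = "S2")
  expect_equal(match_breakpoints(a, other_hom)$relation, "distinct")
})

test_that("event relations distinguish shared, branching and unrelated", {
  a <- mk_event(category = "paracentric_loss", bps = c(30e6, 50e6))
  b <- mk_event(category = "paracentric_loss", bps = c(30.04e6, 50.06e6),
                sample = "S2")
  expect_equal(classify_event_relation(a, b), "shared")
  expect_equal(classify_event_relation(b, a), "shared")
  half <- mk_event(category = "paracentric_loss", bps = c(30.02e6, 80e6),
                   sample = "S2")
  expect_equal(classify_event_relation(a, half), "branching")
  # complementary terminal retention/loss pair: reciprocal daughters
  loss <- mk_event(bps = 60e6, copy_change = -1)
  gain <- mk_event(category = "terminal_gain", bps = 60.03e6,
                   copy_change = 1, sample = "S2")
  expect_equal(classify_event_relation(loss, gain), "branching")
  far <- mk_event(bps = 90e6, sample = "S2")
  expect_equal(classify_event_relation(loss, far), "unrelated")
})

test_that("perfect-phylogeny construction recovers nested clades", {
  inc <- rbind(S1 = c(1, 1, 0, 1),
               S2 = c(1, 1, 0, 0),
               S3 = c(1, 0, 1, 0),
               S4 = c(1, 0, 1, 0))
  colnames(inc) <- c("trunk", "c12", "c34", "p1")
  tr <- build_tree(inc, support = c(4, 3, 3, 1))
  expect_equal(nrow(tr$conflicts), 0)
  nwk <- sample_tree_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("S1", "S2", "S3", "S4", "germline"))
  # S1+S2 and S3+S4 are clades
  clades <- lapply(tr$clades, sort)
  expect_true(list(c("S1", "S2")) %in% clades)
  expect_true(list(c("S3", "S4")) %in% clades)
  # star topology when nothing is shared
  star <- build_tree(diag(3), support = rep(1, 3))
  expect_true(all(star$nodes$parent[-1] == 1L))
})

test_that("conflicting characters are dropped by support and logged", {
  inc <- rbind(S1 = c(1, 1, 0),
               S2 = c(1, 1, 1),
               S3 = c(0, 1, 1))
  colnames(inc) <- c("a", "b", "c")
  # {S1,S2} and {S2,S3} overlap without nesting: the weaker one is dropped
  tr <- build_tree(inc, support = c(5, 6, 2))
  expect_equal(tr$conflicts$character, "c")
  expect_true("a" %in% unlist(tr$branch_characters))
})

test_that("simulated patients are reconstructed exactly from breakpoints", {
  gm <- default_genome()
  set.seed(81)
  for (rep in 1:5) {
    n_leaves <- sample(4:6, 1)
    true_tr <- simulate_breakpoint_patient(gm, n_leaves = n_leaves,
                                           seed = 500 + rep)
    events <- do.call(rbind, lapply(tree_leaves(true_tr), function(s)
      classify_karyotype(tree_karyotype(true_tr, s), gm, sample = s)))
    inc <- event_incidence(events, samples = tree_leaves(true_tr))
    est <- build_tree(inc$incidence, inc$support, inc$chrom)
    t1 <- ape::read.tree(text = sample_tree_newick(est))
    t2 <- ape::read.tree(text = sample_tree_newick(true_tr))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("WGD timing follows the copy-difference and odd/even rules", {
  seg4 <- mk_event(category = "paracentric_gain", bps = c(30e6, 50e6),
                   copy_change = 2)
  expect_equal(time_scna_vs_wgd(seg4, wgd = TRUE), "pre-WGD")
  seg3 <- mk_event(category = "paracentric_gain", bps = c(30e6, 50e6),
                   copy_change = 1)
  expect_equal(time_scna_vs_wgd(seg3, wgd = TRUE), "post-WGD")
  expect_true(is.na(time_scna_vs_wgd(seg3, wgd = FALSE)))
  wc <- mk_event(category = "whole_chrom_loss", bps = 1, copy_change = -3)
  expect_equal(time_scna_vs_wgd(wc, wgd = TRUE, final_cn = 1), "post-WGD")
  expect_equal(time_scna_vs_wgd(wc, wgd = TRUE, final_cn = 3), "post-WGD")
  expect_equal(time_scna_vs_wgd(wc, wgd = TRUE, final_cn = 5), "post-WGD")
  expect_equal(time_scna_vs_wgd(wc, wgd = TRUE, final_cn = 4), "pre-WGD")
  expect_equal(time_scna_vs_wgd(wc, wgd = TRUE, final_cn = 6), "pre-WGD")
})

test_that("WGD placement finds maximal duplicated clades", {
  inc <- rbind(S1 = c(1, 1), S2 = c(1, 1), S3 = c(1, 0), S4 = c(1, 0))
  colnames(inc) <- c("trunk", "c12")
  tr <- build_tree(inc)
  all_wgd <- assign_wgd_to_branches(tr, c(S1 = TRUE, S2 = TRUE, S3 = TRUE,
                                          S4 = TRUE))
  # every sample duplicated: one placement on the truncal branch
  expect_equal(length(all_wgd$wgd_placements), 1)
  expect_setequal(all_wgd$wgd_placements[[1]], c("S1", "S2", "S3", "S4"))
  none <- assign_wgd_to_branches(tr, c(S1 = FALSE, S2 = FALSE, S3 = FALSE,
                                       S4 = FALSE))
  expect_equal(length(none$wgd_placements), 0)
  # two disjoint duplicated pairs: two independent events
  inc2 <- rbind(S1 = c(1, 0), S2 = c(1, 0), S3 = c(0, 1), S4 = c(0, 1))
  colnames(inc2) <- c("c12", "c34")
  tr2 <- build_tree(inc2)
  two <- assign_wgd_to_branches(tr2, c(S1 = TRUE, S2 = TRUE, S3 = TRUE,
                                       S4 = TRUE))
  expect_equal(length(two$wgd_placements), 2)
})

test_that("sSNV similarity is the normalized shared fraction", {
  sup <- cbind(A = c(5, 4, 3, 0, 0), B = c(0, 6, 9, 7, 2))
  res <- snv_similarity(sup, min_support = 3)
  expect_equal(res$similarity["A", "B"], 2 / 3)
  expect_equal(res$similarity["B", "A"], 2 / 3)
  expect_equal(res$similarity["A", "A"], 1)
  disj <- cbind(A = c(5, 0), B = c(0, 5))
  expect_equal(snv_similarity(disj)$similarity["A", "B"], 0)
  empty <- cbind(A = c(5, 4), B = c(0, 0))
  r2 <- snv_similarity(empty)
  expect_equal(r2$empty_samples, "B")
  expect_equal(r2$similarity["B", "A"], 0)
})
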
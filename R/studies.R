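#' Validation studies
#'
#' Each function runs one self-contained simulation study against the
#' package's own pipeline and returns the summary metric: classifier
#' oracle equivalence, purity/ploidy recovery, switch-error correction,
#' phylogeny recovery, WGD-timing accuracy, sloping detection
#' calibration, and event-operator conservation audits.  They are used
#' by the test suite and the reproduction script.
#'
#' @name validation_studies
NULL

coarse_group <- function(category) {
  sub("_(gain|loss|del|dup)$", "", category)
}

#' @describeIn validation_studies classifier accuracy on noiseless
#'   single-event chromosomes.  Draws `n` karyotypes round-robin over
#'   the category repertoire, classifies each, and scores recovery of
#'   the generating category (coarse groups: gain/loss variants of a
#'   mechanism count as one group; an amplification instance also
#'   creates its broken-terminus loss, so it scores on the
#'   amplification call).
#' @param n number of instances.
#' @param seed integer seed.
#' @param genome a `genome_model` (default: the 4-chromosome test
#'   genome, no het sites needed).
#' @return list with `accuracy` and the `confusion` table.
#' @export
study_classifier_accuracy <- function(n = 500, seed = 1,
                                      genome = simulate_genome(
                                        het_density = 0, seed = seed)) {
  set.seed(seed)
  cats <- c("terminal_gain", "terminal_loss", "paracentric_gain",
            "paracentric_loss", "pericentric_gain", "pericentric_loss",
            "UPD", "arm_gain", "arm_loss", "whole_chrom_gain",
            "whole_chrom_loss", "focal_del", "focal_dup", "amplification")
  truth <- character(n); pred <- character(n)
  for (i in seq_len(n)) {
    cat_i <- cats[(i - 1) %% length(cats) + 1]
    sim <- simulate_single_event(genome, cat_i)
    ev <- classify_chromosome(sim$karyotype, sim$chrom, genome)
    truth[i] <- coarse_group(cat_i)
    pred[i] <- if ("amplification" %in% ev$category) "amplification"
      else if (nrow(ev) == 1) coarse_group(ev$category)
      else "other"
  }
  list(accuracy = mean(pred == truth),
       confusion = table(truth = truth, predicted = pred))
}

#' @describeIn validation_studies purity/ploidy recovery on simulated
#'   20x bulk samples with purity 0.3-0.9.  Clones are redrawn until
#'   they are identifiable from coverage ratios alone: at least 10 Mb
#'   of odd-copy-number states in segments of 5 Mb or more (breaks the
#'   genome-halving alias) and at least 5 Mb of LOH (one homolog at
#'   zero copies, breaking the one-copy-shift alias).  Clones without
#'   these anchors are genuinely ratio-degenerate and are excluded,
#'   mirroring the exclusion of SCNA-poor samples from purity/ploidy
#'   estimation in practice.
#' @param n_samples replicates.
#' @param cfg a `render_config` (default 20x).
#' @return list with `results` (per-replicate truth and estimates) and
#'   `recovery_rate` (fraction within +-0.05 purity and +-0.1 ploidy).
#' @export
study_purity_ploidy <- function(n_samples = 20, seed = 1,
                                cfg = render_config()) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_samples)) {
    p_true <- stats::runif(1, 0.3, 0.9)
    repeat {
      sub_seed <- sample.int(2^30, 1)
      gm <- simulate_genome(seed = sub_seed)
      tr <- simulate_clone_tree(gm, n_leaves = 2, tp53_node = 2L,
                                events_per_branch = 3, seed = sub_seed + 1)
      k <- tree_karyotype(tr, "S1")
      w <- k$end - k$start
      big <- w >= 5e6
      imb <- sum(w[big & k$cnA != k$cnB]) >= 1e7
      odd <- sum(w[big & (k$cnA %% 2 == 1 | k$cnB %% 2 == 1)]) >= 1e7
      loh <- sum(w[big & (k$cnA == 0 | k$cnB == 0)]) >= 5e6
      if (imb && odd && loh && karyotype_ploidy(k) <= 5.5) break
    }
    obs <- render_patient(tr, samples = "S1", purities = p_true, cfg = cfg)
    cs <- correct_switch_errors(obs$allelic)
    cl <- call_sample_cn(obs, "S1", cs$allelic)
    rows[[r]] <- data.frame(
      p_true = p_true, p_est = cl$fit$purity,
      ploidy_true = karyotype_ploidy(k), ploidy_est = cl$fit$ploidy,
      status = cl$fit$status)
  }
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p_est) &
    abs(res$p_est - res$p_true) <= 0.05 &
    abs(res$ploidy_est - res$ploidy_true) <= 0.1
  list(results = res, recovery_rate = mean(ok))
}

#' @describeIn validation_studies switch-error correction across
#'   simulated patients.  Each patient carries chromosome-scale allelic
#'   imbalance shared by three samples; the pooled residual switch rate
#'   inside imbalanced regions is compared with the simulated input
#'   rate (about one switch per 250 kb).
#' @param n_patients patients to simulate.
#' @return list with `input_switches`, `residual_switches`,
#'   `fold_reduction` (pooled), `input_rate_bp`, `residual_rate_bp`.
#' @export
study_switch_correction <- function(n_patients = 20, seed = 1) {
  set.seed(seed)
  input_sw <- 0; resid_sw <- 0; bp_total <- 0
  for (r in seq_len(n_patients)) {
    gm <- simulate_genome(c(chr1 = 6e7, chr2 = 4e7),
                          seed = sample.int(2^30, 1))
    k <- apply_upd(diploid_karyotype(gm), "chr1", c(0, 6e7), "A")
    k <- apply_terminal(k, "chr2", "B", 1e7, -1L, gm)
    cfg <- render_config(n_panel = 0)
    bias <- make_bias_profile(gm, cfg)
    ori <- draw_switch_orientation(gm, cfg$switch_rate)
    dA <- NULL; dB <- NULL; sites <- NULL
    for (s in 1:3) {
      rb <- render_bulk(list(k), stats::runif(1, 0.6, 0.8), gm, cfg,
                        bias, ori)
      if (is.null(sites)) sites <- rb$allelic[, c("chrom", "pos")]
      dA <- cbind(dA, rb$allelic$depthA)
      dB <- cbind(dB, rb$allelic$depthB)
    }
    colnames(dA) <- colnames(dB) <- paste0("S", 1:3)
    cs <- correct_switch_errors(list(sites = sites, depthA = dA,
                                     depthB = dB))
    # truth-imbalanced regions: all of chr1 (UPD), chr2 distal of 10 Mb
    for (cn in c("chr1", "chr2")) {
      sel <- sites$chrom == cn
      keep <- if (cn == "chr1") rep(TRUE, sum(sel))
              else sites$pos[sel] >= 1e7
      o <- ori[[cn]][keep]
      f <- cs$flip[[cn]][keep]
      input_sw <- input_sw + sum(diff(o) != 0)
      resid_sw <- resid_sw + sum(diff(o * ifelse(f, -1L, 1L)) != 0)
      pos <- sites$pos[sel][keep]
      bp_total <- bp_total + max(pos) - min(pos)
    }
  }
  list(input_switches = input_sw, residual_switches = resid_sw,
       fold_reduction = input_sw / max(resid_sw, 1),
       input_rate_bp = input_sw / bp_total,
       residual_rate_bp = resid_sw / bp_total)
}

#' @describeIn validation_studies phylogeny recovery from noiseless
#'   breakpoint markers: random patients with 4-8 samples and three
#'   unique markers per branch; scored by Robinson-Foulds distance
#'   zero against the generating topology.
#' @param n_patients patients.
#' @return list with `exact_rate` and per-patient `rf` distances.
#' @export
study_tree_recovery <- function(n_patients = 20, seed = 1) {
  set.seed(seed)
  gm <- simulate_genome(het_density = 0, seed = seed)
  rf <- numeric(n_patients)
  for (r in seq_len(n_patients)) {
    tr <- simulate_breakpoint_patient(gm, n_leaves = sample(4:8, 1),
                                      seed = sample.int(2^30, 1))
    events <- do.call(rbind, lapply(tree_leaves(tr), function(s)
      classify_karyotype(tree_karyotype(tr, s), gm, sample = s)))
    inc <- event_incidence(events, samples = tree_leaves(tr))
    est <- build_tree(inc$incidence, inc$support, inc$chrom)
    t1 <- ape::read.tree(text = sample_tree_newick(est))
    t2 <- ape::read.tree(text = sample_tree_newick(tr))
    rf[r] <- ape::dist.topo(ape::unroot(t1), ape::unroot(t2))
  }
  list(exact_rate = mean(rf == 0), rf = rf)
}

#' @describeIn validation_studies WGD-timing label accuracy on
#'   noiseless duplication lineages, covering the copy-difference rule
#'   for segmental SCNAs and the final-copy-number-1 / odd-state rules
#'   for whole-chromosome events.
#' @param n_cases segmental cases (whole-chromosome cases are
#'   enumerated exhaustively).
#' @return list with `accuracy`, `n`.
#' @export
study_wgd_timing <- function(n_cases = 40, seed = 1) {
  set.seed(seed)
  gm <- simulate_genome(het_density = 0, seed = seed)
  correct <- 0L; total <- 0L
  for (r in seq_len(n_cases)) {
    chrom <- sample(gm$chroms, 1)
    L <- gm$lengths[[chrom]]
    hom <- sample(c("A", "B"), 1)
    pre <- stats::runif(1) < 0.5
    sign <- sample(c(-1L, 1L), 1)
    k <- diploid_karyotype(gm)
    cen <- gm$centromeres[gm$centromeres$chrom == chrom, ]
    repeat {
      bp <- stats::runif(1, 0.15 * L, 0.85 * L)
      if (bp < cen$start - 2e6 || bp > cen$end + 2e6) break
    }
    if (pre) {
      k <- apply_terminal(k, chrom, hom, bp, sign, gm)
      k <- apply_wgd(k)
    } else {
      k <- apply_wgd(k)
      k <- apply_terminal(k, chrom, hom, bp, sign, gm)
    }
    ev <- classify_chromosome(simplify_karyotype(k), chrom, gm)
    ev <- ev[ev$homolog == hom & grepl("terminal|arm", ev$category), ]
    if (nrow(ev) == 1) {
      lab <- time_scna_vs_wgd(ev[1, ], wgd = TRUE)
      total <- total + 1L
      if (identical(lab, if (pre) "pre-WGD" else "post-WGD"))
        correct <- correct + 1L
    }
  }
  # whole-chromosome states reached by explicit duplication histories
  wc <- data.frame(final_cn = c(1, 3, 5, 4, 6),
                   truth = c("post-WGD", "post-WGD", "post-WGD",
                             "pre-WGD", "pre-WGD"))
  for (i in seq_len(nrow(wc))) {
    ev <- data.frame(sample = "S", chrom = "chr1", homolog = "A",
                     category = "whole_chrom_gain", start = 0, end = 1,
                     breakpoints = "", copy_change = wc$final_cn[i] - 2,
                     footprint = NA, complexity = "simple")
    lab <- time_scna_vs_wgd(ev, wgd = TRUE, final_cn = wc$final_cn[i])
    total <- total + 1L
    if (identical(lab, wc$truth[i])) correct <- correct + 1L
  }
  list(accuracy = correct / total, n = total)
}

#' @describeIn validation_studies sloping-detector calibration:
#'   sensitivity on rendered progressive-erosion mixtures (population
#'   attenuation 0.5 copies over 10 Mb at purity 0.5, 20x) and false
#'   calls on rendered flat diploid genomes.
#' @param n_pos positive replicates.
#' @param n_null flat-genome replicates.
#' @return list with `sensitivity`, `false_calls`, `n_null`,
#'   `false_calls_per_100`.
#' @export
study_sloping <- function(n_pos = 30, n_null = 100, seed = 1) {
  set.seed(seed)
  gm <- simulate_genome(c(chr1 = 6e7, chr2 = 4e7), seed = seed)
  cfg <- render_config()
  hap_cn <- function(r, bias, purity, ploidy) {
    norm <- r$counts / bias$bias
    norm <- norm / mean(norm)
    al <- list(sites = r$allelic[, c("chrom", "pos")],
               depthA = r$allelic$depthA, depthB = r$allelic$depthB)
    hap <- haplotype_coverage(norm, al, bias[, c("chrom", "start", "end")])
    hap$cnA <- implied_allelic_cn(hap$hapA, purity, ploidy)
    hap$cnB <- implied_allelic_cn(hap$hapB, purity, ploidy)
    hap
  }
  base <- diploid_karyotype(gm)
  hits <- 0
  for (r in seq_len(n_pos)) {
    bias <- make_bias_profile(gm, cfg)
    bounds <- seq(46e6, 56e6, length.out = 10)
    rb <- render_sloping_population(base, "chr1", "A", bounds,
                                    rep(0.05, 10), gm, cfg, bias)
    calls <- detect_sloping(hap_cn(rb, bias, 0.5, 2), gm)
    hit <- calls[calls$chrom == "chr1" & calls$arm == "q" &
                   calls$homolog == "A" &
                   calls$direction == "telomeric", ]
    if (nrow(hit) >= 1) hits <- hits + 1
  }
  false_calls <- 0
  for (r in seq_len(n_null)) {
    bias <- make_bias_profile(gm, cfg)
    rb <- render_bulk(list(base), 0.5, gm, cfg, bias)
    false_calls <- false_calls + nrow(detect_sloping(
      hap_cn(rb, bias, 0.5, 2), gm))
  }
  list(sensitivity = hits / n_pos, false_calls = false_calls,
       n_null = n_null, false_calls_per_100 = 100 * false_calls / n_null)
}

#' @describeIn validation_studies conservation audit: bin-wise daughter
#'   sums after bridge breakage equal twice the parent, and UPD
#'   preserves total copy number, over random events.
#' @param n_events random events.
#' @return list with `violations`, `n_events`.
#' @export
study_conservation <- function(n_events = 1000, seed = 1) {
  set.seed(seed)
  gm <- simulate_genome(het_density = 0, seed = seed)
  viol <- 0L
  for (r in seq_len(n_events)) {
    chrom <- sample(gm$chroms, 1)
    L <- gm$lengths[[chrom]]
    k <- diploid_karyotype(gm)
    if (stats::runif(1) < 0.3)  # random non-trivial parent
      k <- apply_internal_segment(k, chrom, "B",
                                  0.2 * L, 0.6 * L, 1L, gm)
    if (stats::runif(1) < 0.5) {
      d <- apply_bfb_break(k, chrom, "A", stats::runif(1, 1e6, L - 1e6), gm)
      pb <- karyotype_bins(k, gm, 2e6)
      b1 <- karyotype_bins(d$daughter1, gm, 2e6)
      b2 <- karyotype_bins(d$daughter2, gm, 2e6)
      if (!all(b1$total + b2$total == 2L * pb$total)) viol <- viol + 1L
    } else {
      region <- sort(stats::runif(2, 0, L))
      if (diff(region) < 1e6) region <- c(region[1], region[1] + 1e6)
      u <- apply_upd(k, chrom, region, sample(c("A", "B"), 1))
      pb <- karyotype_bins(k, gm, 2e6)
      ub <- karyotype_bins(u, gm, 2e6)
      if (!all(ub$total == pb$total)) viol <- viol + 1L
    }
  }
  list(violations = viol, n_events = n_events)
}
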
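#' Select usable heterozygous sites from a cohort genotype matrix
#'
#' Applies the cohort-level filters that remove apparent heterozygous
#' sites caused by sequencing or alignment artifacts: a site is kept if
#' (1) at least one sample is called heterozygous, (2) at least two
#' samples show more than two alternate reads, (3) at least two samples
#' show more than two reference reads, and (4) the fraction of
#' heterozygous samples does not exceed `cohort_het_fraction_threshold`
#' — under Hardy-Weinberg equilibrium the heterozygote frequency of a
#' biallelic locus is at most 2p(1-p) <= 50%, so sites heterozygous in
#' more than half the cohort are artifacts.
#'
#' @param g list with components `het` (logical sites x samples matrix
#'   of heterozygous calls), `ref` and `alt` (integer depth matrices of
#'   the same shape), and optionally `sites` (data.frame with one row
#'   per site).
#' @param cohort_het_fraction_threshold maximum heterozygous-sample
#'   fraction (default 0.5).
#' @return integer vector of kept site indices (rows of the matrices).
#' @export
select_het_sites <- function(g, cohort_het_fraction_threshold = 0.5) {
  if (is.null(g$het) || nrow(g$het) == 0) return(integer(0))
  stopifnot(ncol(g$het) >= 1)
  het_n <- rowSums(g$het)
  keep <- het_n >= 1 &
    rowSums(g$alt > 2) >= 2 &
    rowSums(g$ref > 2) >= 2 &
    het_n / ncol(g$het) <= cohort_het_fraction_threshold
  which(keep)
}

#' Maximum heterozygote frequency under Hardy-Weinberg equilibrium
#'
#' For a biallelic locus with allele frequency p the heterozygote
#' frequency is 2p(1-p), maximized at p = 1/2.  This bound motivates
#' the cohort het-fraction filter in [select_het_sites()].
#'
#' @return numeric scalar (0.5).
#' @export
hardy_weinberg_max_het <- function() {
  p <- seq(0, 1, by = 1e-4)
  max(2 * p * (1 - p))
}

#' Windowed allelic-imbalance statistic
#'
#' For each fixed-width window and sample, computes the haplotype depth
#' imbalance (depthA - depthB) / (depthA + depthB) under the current
#' phase, with windows below the minimum informative total depth
#' flagged uninformative.
#'
#' @param allelic list with `sites` (chrom, pos) and `depthA`/`depthB`
#'   site x sample matrices (a single-sample pair of vectors is
#'   accepted).
#' @param window_bp window width (default 50000).
#' @param min_total minimum total allele count for an informative
#'   window (default 50).
#' @return data.frame chrom, start, end, sample, depthA, depthB, stat,
#'   informative.
#' @export
window_allelic_imbalance <- function(allelic, window_bp = 50000,
                                     min_total = 50) {
  sites <- allelic$sites
  dA <- as.matrix(allelic$depthA); dB <- as.matrix(allelic$depthB)
  samples <- colnames(dA)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(dA)))
  out <- list()
  for (cn in unique(sites$chrom)) {
    sel <- sites$chrom == cn
    w <- floor(sites$pos[sel] / window_bp)
    uw <- sort(unique(w))
    for (j in seq_along(samples)) {
      a <- tapply(dA[sel, j], w, sum)[as.character(uw)]
      b <- tapply(dB[sel, j], w, sum)[as.character(uw)]
      tot <- a + b
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = uw * window_bp, end = (uw + 1) * window_bp,
        sample = samples[j], depthA = as.integer(a), depthB = as.integer(b),
        stat = ifelse(tot > 0, (a - b) / tot, NA_real_),
        informative = tot >= min_total,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Correct statistical-phasing switch errors from cross-sample allelic
#' imbalance
#'
#' Within genomic regions where at least `min_samples_informative`
#' samples show consistent allelic imbalance, the per-site phased depth
#' differences are aggregated across samples (after aligning each
#' sample's imbalance direction), the aggregated sign sequence is
#' segmented with a penalized changepoint criterion, and each segment
#' is flipped or kept by majority vote so that the imbalance sign is
#' concordant along the region.  Regions with no informative sample are
#' left untouched.  Depths are never altered, only the site
#' orientations.
#'
#' @param allelic as in [window_allelic_imbalance()].
#' @param window_bp window for region detection (default 50000).
#' @param min_samples_informative minimum samples with imbalance for a
#'   region to be correctable; the default requires cross-sample
#'   consensus (2) but degrades gracefully to 1 for single-sample
#'   cohorts.
#' @param imbalance_threshold minimum |windowed statistic| that counts
#'   as imbalance (default 0.15).
#' @param min_total minimum informative window depth (default 50).
#' @param penalty_factor changepoint penalty multiplier (default 2).
#' @return list with `allelic` (corrected copy: flipped sites have
#'   depthA/depthB swapped in every sample), `flip` (per-chromosome
#'   logical vectors: TRUE where the site orientation was flipped),
#'   `flip_positions` (data.frame chrom, pos of flip-run boundaries)
#'   and `regions` (the imbalanced regions used).
#' @export
correct_switch_errors <- function(allelic, window_bp = 50000,
                                  min_samples_informative = NULL,
                                  imbalance_threshold = 0.15,
                                  min_total = 50,
                                  penalty_factor = 2) {
  sites <- allelic$sites
  dA <- as.matrix(allelic$depthA); dB <- as.matrix(allelic$depthB)
  if (is.null(min_samples_informative))
    min_samples_informative <- min(2L, ncol(dA))
  wi <- window_allelic_imbalance(allelic, window_bp, min_total)
  flip <- lapply(split(seq_len(nrow(sites)), sites$chrom),
                 function(ix) rep(FALSE, length(ix)))
  regions <- list()
  for (cn in unique(sites$chrom)) {
    sel_s <- which(sites$chrom == cn)
    w <- wi[wi$chrom == cn, ]
    # windows where enough samples show strong imbalance
    agg <- stats::aggregate(
      cbind(n_imb = w$informative & !is.na(w$stat) &
              abs(w$stat) >= imbalance_threshold) ~ start, data = w, FUN = sum)
    agg <- agg[order(agg$start), ]
    marked <- agg$n_imb >= min_samples_informative
    if (!any(marked)) next
    # merge marked windows into regions, bridging gaps of <= 2 windows
    runs <- rle(marked)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    keep_run <- runs$values
    for (r in which(!runs$values)) {
      if (r > 1 && r < length(runs$values) && runs$lengths[r] <= 2)
        keep_run[r] <- TRUE
    }
    merged <- rle(keep_run)$values  # not used; recompute region extents
    region_ix <- which(keep_run)
    # build contiguous blocks of runs marked keep
    blocks <- split(region_ix, cumsum(c(1, diff(region_ix) != 1)))
    for (blk in blocks) {
      if (!any(runs$values[blk])) next
      r_start <- agg$start[idx_start[min(blk)]]
      r_end <- agg$start[idx_end[max(blk)]] + window_bp
      in_reg <- sel_s[sites$pos[sel_s] >= r_start & sites$pos[sel_s] < r_end]
      if (length(in_reg) < 4) next
      # informative samples in this region
      wreg <- w[w$start >= r_start & w$end <= r_end & w$informative &
                  !is.na(w$stat), ]
      strength <- tapply(abs(wreg$stat), wreg$sample, mean)
      use <- names(strength)[!is.na(strength) &
                               strength >= imbalance_threshold / 2]
      if (length(use) == 0) next
      jj <- match(use, colnames(dA))
      if (anyNA(jj)) jj <- match(use, paste0("s", seq_len(ncol(dA))))
      diffs <- dA[in_reg, jj, drop = FALSE] - dB[in_reg, jj, drop = FALSE]
      ref <- jj[which.max(strength[use])]
      refd <- dA[in_reg, ref] - dB[in_reg, ref]
      sgn <- vapply(seq_along(jj), function(q) {
        s <- sum(diffs[, q] * refd)
        if (s >= 0) 1 else -1
      }, 0)
      z <- as.numeric(diffs %*% sgn)
      cps <- find_changepoints(z, penalty_factor = penalty_factor,
                               min_seg = 2)
      seg_id <- findInterval(seq_along(z), c(1, cps))
      seg_sign <- tapply(z, seg_id, sum)
      # flip segments whose sign disagrees with the dominant orientation
      seg_len <- tabulate(seg_id)
      dominant <- sum(sign(seg_sign) * seg_len)
      dom <- if (dominant != 0) sign(dominant) else 1
      to_flip <- names(seg_sign)[sign(seg_sign) == -dom & seg_sign != 0]
      fl <- seg_id %in% as.integer(to_flip)
      # per-site refinement at segment boundaries: sites with confident
      # aggregated evidence follow their own sign, weak sites keep the
      # segment vote
      conf <- abs(z) >= 10
      fl[conf] <- sign(z[conf]) == -dom
      local_ix <- match(in_reg, sel_s)
      flip[[cn]][local_ix] <- fl
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = cn, start = r_start, end = r_end,
        n_samples = length(use), stringsAsFactors = FALSE)
    }
  }
  # apply flips
  dA2 <- dA; dB2 <- dB
  flip_pos <- list()
  for (cn in unique(sites$chrom)) {
    sel_s <- which(sites$chrom == cn)
    fl <- flip[[cn]]
    if (any(fl)) {
      ix <- sel_s[fl]
      tmp <- dA2[ix, , drop = FALSE]
      dA2[ix, ] <- dB2[ix, , drop = FALSE]
      dB2[ix, ] <- tmp
      bound <- which(diff(c(FALSE, fl, FALSE)) != 0)
      pos <- sites$pos[sel_s]
      bp <- pos[pmin(bound, length(pos))]
      flip_pos[[cn]] <- data.frame(chrom = cn, pos = bp,
                                   stringsAsFactors = FALSE)
    }
  }
  list(allelic = list(sites = sites, depthA = dA2, depthB = dB2),
       flip = flip,
       flip_positions = if (length(flip_pos)) do.call(rbind, flip_pos)
                        else data.frame(chrom = character(0), pos = numeric(0)),
       regions = if (length(regions)) do.call(rbind, regions)
                 else data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), n_samples = integer(0)))
}

#' Two-pass haplotype correction for single-cell collections
#'
#' Pass 1 aggregates allelic-depth differences across all cells to find
#' recurrent imbalance and correct switch errors.  Cells that then show
#' large segmental imbalance (at least one run of >= `min_span` bp with
#' |windowed imbalance| > `aneuploid_threshold`) are classified
#' aneuploid, and only those are used for a second, cleaner pass.  If
#' no aneuploid cell is found the pass-1 result is returned with a
#' warning.
#'
#' @param cells allelic list (sites + depthA/depthB matrices, columns =
#'   cells).
#' @param window_bp imbalance window (default 50000).
#' @param min_samples_informative minimum cells with imbalance for
#'   correction (default 3).
#' @param min_total minimum window depth per cell; low-pass cells are
#'   sparse, so the default is 5.
#' @param aneuploid_threshold,min_span aneuploidy rule (default |stat| >
#'   0.25 over >= 10 Mb).
#' @return list as [correct_switch_errors()] plus `aneuploid_cells` and
#'   `pass`.
#' @export
two_pass_correct_cells <- function(cells, window_bp = 50000,
                                   min_samples_informative = 3,
                                   min_total = 5,
                                   aneuploid_threshold = 0.25,
                                   min_span = 1e7) {
  pass1 <- correct_switch_errors(cells, window_bp,
                                 min_samples_informative,
                                 imbalance_threshold = 0.15,
                                 min_total = min_total)
  wi <- window_allelic_imbalance(pass1$allelic, window_bp, min_total)
  cellnames <- colnames(as.matrix(cells$depthA))
  if (is.null(cellnames)) cellnames <- paste0("s", seq_len(ncol(as.matrix(cells$depthA))))
  aneu <- vapply(cellnames, function(s) {
    w <- wi[wi$sample == s & wi$informative & !is.na(wi$stat), ]
    if (nrow(w) == 0) return(FALSE)
    for (cn in unique(w$chrom)) {
      wc <- w[w$chrom == cn, ]
      wc <- wc[order(wc$start), ]
      r <- rle(abs(wc$stat) > aneuploid_threshold)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (q in which(r$values)) {
        span <- wc$end[ends[q]] - wc$start[starts[q]]
        if (span >= min_span) return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  if (!any(aneu)) {
    warning("no aneuploid cell found; returning pass-1 haplotype")
    return(c(pass1, list(aneuploid_cells = character(0), pass = 1L)))
  }
  sub <- list(sites = pass1$allelic$sites,
              depthA = pass1$allelic$depthA[, aneu, drop = FALSE],
              depthB = pass1$allelic$depthB[, aneu, drop = FALSE])
  pass2 <- correct_switch_errors(sub, window_bp,
                                 min_samples_informative =
                                   min(min_samples_informative, sum(aneu)),
                                 imbalance_threshold = 0.15,
                                 min_total = min_total)
  # apply pass-2 flips to all cells
  dA <- pass1$allelic$depthA; dB <- pass1$allelic$depthB
  sites <- pass1$allelic$sites
  for (cn in names(pass2$flip)) {
    fl <- pass2$flip[[cn]]
    ix <- which(sites$chrom == cn)[fl]
    if (length(ix)) {
      tmp <- dA[ix, , drop = FALSE]
      dA[ix, ] <- dB[ix, , drop = FALSE]
      dB[ix, ] <- tmp
    }
  }
  flip <- mapply(function(f1, f2) xor(f1, f2), pass1$flip, pass2$flip,
                 SIMPLIFY = FALSE)
  list(allelic = list(sites = sites, depthA = dA, depthB = dB),
       flip = flip,
       flip_positions = rbind(pass1$flip_positions, pass2$flip_positions),
       regions = rbind(pass1$regions, pass2$regions),
       aneuploid_cells = cellnames[aneu], pass = 2L)
}
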
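#' Four-step normalization of single-cell 10 kb read counts
#'
#' Implements the standard low-pass single-cell pipeline: (1) center
#' each cell's 10 kb counts by its genome-wide mean; (2) remove
#' recurrent coverage bias by fitting the cell's log-coverage — in a
#' region of constant copy number — to a cubic polynomial of the
#' log-median coverage across all cells, and subtracting the predicted
#' bias genome-wide; (3) remove GC-dependent variation with a smooth
#' fit; (4) average to 1 Mb resolution.
#'
#' The constant-copy-number region is the largest chromosome arm whose
#' median coverage is within 0.05 of the genome-wide median of
#' arm-level medians; if no arm qualifies (highly aneuploid genomes)
#' the arm with the lowest coverage standard deviation is used.
#'
#' @param counts bins x cells matrix of 10 kb read counts (>= 5 cells).
#' @param bins data.frame chrom, start, end (10 kb grid), optionally gc.
#' @param genome a `genome_model` (for arm definitions).
#' @param report_bin_width output resolution (default 1e6).
#' @return list with `norm` (10 kb normalized coverage matrix), `cn`
#'   (report-resolution coverage matrix), `report_bins`, and
#'   `fit_arm` (per cell, the arm used for the bias fit).
#' @export
single_cell_normalize <- function(counts, bins, genome,
                                  report_bin_width = 1e6) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 5) stop("need >= 5 cells for the median profile")
  cov <- sweep(counts, 2, colMeans(counts), "/")          # step 1
  med <- apply(cov, 1, stats::median)                     # recurrent profile
  arms <- genome_arms(genome)
  mid <- (bins$start + bins$end) / 2
  arm_of <- rep(NA_integer_, nrow(bins))
  for (i in seq_len(nrow(arms))) {
    sel <- bins$chrom == arms$chrom[i] & mid >= arms$start[i] &
      mid < arms$end[i]
    arm_of[sel] <- i
  }
  lmed <- log(pmax(med, 0.01))
  fit_arm <- character(ncol(cov))
  norm <- cov
  for (j in seq_len(ncol(cov))) {                          # step 2
    v <- cov[, j]
    arm_med <- tapply(v, arm_of, stats::median)
    genome_med <- stats::median(arm_med)
    dev <- abs(arm_med - genome_med)
    cand <- which(dev < 0.05)
    if (length(cand) > 0) {
      arm_len <- arms$end - arms$start
      use <- as.integer(names(arm_med))[cand][
        which.max(arm_len[as.integer(names(arm_med))[cand]])]
    } else {
      arm_sd <- tapply(v, arm_of, stats::sd)
      use <- as.integer(names(arm_sd))[which.min(arm_sd)]
    }
    fit_arm[j] <- paste0(arms$chrom[use], arms$arm[use])
    sel <- which(arm_of == use & v > 0)
    lv <- log(pmax(v, 0.01))
    pf <- stats::lm(lv[sel] ~ stats::poly(lmed[sel], 3, raw = TRUE))
    co <- stats::coef(pf); co[is.na(co)] <- 0
    bias <- co[1] + co[2] * lmed + co[3] * lmed^2 + co[4] * lmed^3
    norm[, j] <- exp(lv - bias)
  }
  if (!is.null(bins$gc)) {                                 # step 3
    for (j in seq_len(ncol(norm))) {
      v <- norm[, j]
      ok <- v > 0 & is.finite(bins$gc)
      sub <- if (sum(ok) > 5000) sample(which(ok), 5000) else which(ok)
      df <- data.frame(y = log(v[sub]), g = bins$gc[sub])
      lf <- stats::loess(y ~ g, data = df, span = 0.75, degree = 2)
      pred <- stats::predict(lf, newdata = data.frame(g = bins$gc))
      pred[is.na(pred)] <- 0
      norm[, j] <- v / exp(pred)
    }
  }
  norm <- sweep(norm, 2, colMeans(norm), "/")
  grp <- paste(bins$chrom, floor(bins$start / report_bin_width))  # step 4
  grp <- factor(grp, levels = unique(grp))
  cn <- apply(norm, 2, function(v) tapply(v, grp, mean))
  report_bins <- data.frame(
    chrom = tapply(bins$chrom, grp, function(x) x[1]),
    start = tapply(bins$start, grp, min),
    end = tapply(bins$end, grp, max), stringsAsFactors = FALSE)
  rownames(report_bins) <- NULL
  list(norm = norm, cn = cn, report_bins = report_bins, fit_arm = fit_arm)
}

#' Chromosomal integer copy number and WGD call for a single cell
#'
#' Normalizes arm-level allelic copy number by the genome median
#' arm-level allelic copy number of both homologs.  In a near-diploid
#' genome all states are then integers; a preponderance of
#' half-integer states indicates that the "median" chromosomes are
#' themselves duplicated, so the profile is doubled and the cell
#' flagged as whole-genome duplicated.  Independently, the cell is
#' called near-tetraploid when at least one arm has median allelic
#' copy number between 0.2 and 0.8 with allelic-coverage standard
#' deviation < 0.25 (a lost-then-rescaled homolog).  A uniformly
#' balanced duplicated genome, e.g. (2,2) everywhere, is
#' indistinguishable from (1,1) by coverage ratios and is not flagged.
#'
#' @param arm_alleles data.frame with columns chrom, arm, medA, medB
#'   (median allelic copy number per arm and homolog) and sdA, sdB
#'   (standard deviation of allelic coverage).
#' @param half_int_tol states count as half-integer when within 0.15 of
#'   k + 1/2 (default 0.15).
#' @return list with `states` (arm_alleles plus cnA, cnB integer
#'   calls), `wgd` (logical), `scale` (multiplier applied: 1 or 2).
#' @export
single_cell_chrom_cn <- function(arm_alleles, half_int_tol = 0.15) {
  vals <- c(arm_alleles$medA, arm_alleles$medB)
  m <- stats::median(vals[vals > 0.1])
  if (!is.finite(m) || m <= 0) m <- 1
  x <- cbind(A = arm_alleles$medA, B = arm_alleles$medB) / m
  dist_int <- abs(x - round(x))
  dist_half <- abs(x - (floor(x) + 0.5))
  nonzero <- x > 0.25
  is_half <- dist_half < half_int_tol & dist_int > half_int_tol & nonzero
  wgd_half <- any(is_half)
  tetra <- any(
    (pmin(arm_alleles$medA / m, arm_alleles$medB / m) >= 0.2 &
       pmin(arm_alleles$medA / m, arm_alleles$medB / m) <= 0.8 &
       pmin(arm_alleles$sdA, arm_alleles$sdB) < 0.25))
  scale <- if (wgd_half) 2 else 1
  states <- arm_alleles
  states$cnA <- pmax(0L, as.integer(round(arm_alleles$medA / m * scale)))
  states$cnB <- pmax(0L, as.integer(round(arm_alleles$medB / m * scale)))
  list(states = states, wgd = wgd_half || (tetra && scale == 1 &&
         any(abs(states$cnA + states$cnB - 4) <= 1)),
       tetraploid = tetra, scale = scale)
}

#' Arm-level allelic copy number summaries for a single cell
#'
#' Helper combining normalized coverage and corrected allelic
#' fractions into the per-arm medians and standard deviations consumed
#' by [single_cell_chrom_cn()].
#'
#' @param cn per-bin total copy-number estimate (report resolution).
#' @param report_bins bins matching `cn`.
#' @param allelic corrected allelic depths for the cell.
#' @param genome a `genome_model`.
#' @param window_bp allelic-fraction window (default 50000).
#' @return data.frame chrom, arm, medA, medB, sdA, sdB.
#' @export
cell_arm_alleles <- function(cn, report_bins, allelic, genome,
                             window_bp = 50000) {
  arms <- genome_arms(genome)
  wi <- window_allelic_imbalance(list(sites = allelic[, c("chrom", "pos")],
                                      depthA = matrix(allelic$depthA),
                                      depthB = matrix(allelic$depthB)),
                                 window_bp, min_total = 5)
  mid <- (report_bins$start + report_bins$end) / 2
  out <- arms
  out$medA <- NA_real_; out$medB <- NA_real_
  out$sdA <- NA_real_; out$sdB <- NA_real_
  for (i in seq_len(nrow(arms))) {
    sel_b <- report_bins$chrom == arms$chrom[i] & mid >= arms$start[i] &
      mid < arms$end[i]
    w <- wi[wi$chrom == arms$chrom[i] & wi$start >= arms$start[i] &
              wi$end <= arms$end[i] & wi$informative, ]
    fA <- if (nrow(w) > 0)
      sum(w$depthA) / sum(w$depthA + w$depthB) else 0.5
    tot <- cn[sel_b]
    a <- tot * fA; b <- tot * (1 - fA)
    out$medA[i] <- stats::median(a, na.rm = TRUE)
    out$medB[i] <- stats::median(b, na.rm = TRUE)
    out$sdA[i] <- stats::sd(a, na.rm = TRUE)
    out$sdB[i] <- stats::sd(b, na.rm = TRUE)
  }
  out
}
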
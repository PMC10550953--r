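#' Normalize binned coverage against a germline reference panel
#'
#' Converts raw bin counts to fractional coverage, removes GC-dependent
#' bias with a smooth (loess) fit of log-coverage against GC content,
#' divides out the panel median profile (recurrent FFPE bias), and
#' centers the result so the genome-wide length-weighted mean is 1.
#' Bins with zero panel coverage are masked (NA).
#'
#' @param counts integer vector or bins x samples matrix of raw counts.
#' @param panel bins x m matrix of germline reference counts (m >= 3).
#' @param gc per-bin GC fraction.
#' @return matrix (or vector) of normalized coverage, same shape as
#'   `counts`, with attribute "masked" (logical per bin).
#' @export
normalize_bulk <- function(counts, panel, gc) {
  if (ncol(as.matrix(panel)) < 3) stop("need >= 3 panel samples")
  x <- as.matrix(counts)
  p <- as.matrix(panel)
  xf <- sweep(x, 2, colMeans(x), "/")
  pf <- sweep(p, 2, colMeans(p), "/")
  ref <- apply(pf, 1, stats::median)
  masked <- !is.finite(ref) | ref <= 0
  ref[masked] <- NA
  # residual per-sample GC effect, fit robustly after panel division so
  # copy-number-altered segments act as outliers, not signal to absorb
  gc_correct <- function(v) {
    ok <- !is.na(v) & v > 0 & is.finite(gc)
    sub <- if (sum(ok) > 5000) sample(which(ok), 5000) else which(ok)
    df <- data.frame(y = log(v[sub]), g = gc[sub])
    fit <- stats::loess(y ~ g, data = df, span = 0.5, degree = 2,
                        family = "symmetric")
    pred <- stats::predict(fit, newdata = data.frame(g = gc))
    pred[is.na(pred)] <- 0
    out <- v / exp(pred)
    out / mean(out, na.rm = TRUE)
  }
  out <- apply(sweep(xf, 1, ref, "/"), 2, gc_correct)
  out <- sweep(out, 2, colMeans(out, na.rm = TRUE), "/")
  attr(out, "masked") <- masked
  if (is.null(dim(counts))) out <- structure(out[, 1], masked = masked)
  out
}

#' Remove panel-spanned variation with eigensamples
#'
#' Computes the top-`k` singular vectors of the (log-scale, centered)
#' reference-panel coverage and removes each sample's projection onto
#' them, the standard denoising step for shallow longitudinal cohorts.
#'
#' @param x normalized coverage, bins x samples (vector accepted).
#' @param panel normalized panel coverage, bins x m (m >= k).
#' @param k number of eigensamples (default 10; 0 is the identity).
#' @return denoised coverage, same shape, re-centered at mean 1.
#' @export
denoise_with_eigensamples <- function(x, panel, k = 10) {
  p <- as.matrix(panel)
  if (k > ncol(p)) stop("k exceeds panel size")
  xm <- as.matrix(x)
  lx <- log(pmax(xm, 1e-6))
  lx <- sweep(lx, 2, colMeans(lx))
  if (k > 0) {
    lp <- log(pmax(p, 1e-6))
    lp <- sweep(lp, 2, colMeans(lp))
    sv <- svd(lp, nu = k, nv = 0)
    U <- sv$u
    lx <- lx - U %*% crossprod(U, lx)
  }
  out <- exp(lx)
  out <- sweep(out, 2, colMeans(out), "/")
  if (is.null(dim(x))) out <- out[, 1]
  out
}

#' Haplotype-specific coverage from total coverage and corrected phase
#'
#' Splits normalized total coverage into homolog A and B components
#' using the smoothed per-bin haplotype-A depth fraction from the
#' (switch-corrected) allelic-depth table.  Bins without an informative
#' het site inherit the nearest informative fraction and are flagged.
#'
#' @param norm_cov per-bin normalized total coverage (vector, one
#'   sample).
#' @param allelic corrected allelic depths for that sample: list with
#'   `sites` (chrom, pos) and `depthA`/`depthB` vectors.
#' @param bins data.frame chrom, start, end matching `norm_cov`.
#' @param smooth_halfwidth half-width (in bins) of the running-mean
#'   smoothing of the allelic fraction (default 2).
#' @return data.frame bins plus total, hapA, hapB, frac, imputed.
#' @export
haplotype_coverage <- function(norm_cov, allelic, bins,
                               smooth_halfwidth = 2) {
  sites <- allelic$sites
  dA <- as.numeric(allelic$depthA); dB <- as.numeric(allelic$depthB)
  out <- bins
  out$total <- as.numeric(norm_cov)
  out$frac <- NA_real_; out$imputed <- FALSE
  for (cn in unique(bins$chrom)) {
    bi <- which(bins$chrom == cn)
    si <- which(sites$chrom == cn)
    if (length(si) == 0) { out$frac[bi] <- 0.5; out$imputed[bi] <- TRUE; next }
    w <- findInterval(sites$pos[si], bins$start[bi])
    sumA <- tapply(dA[si], w, sum)
    sumB <- tapply(dB[si], w, sum)
    a <- numeric(length(bi)); b <- numeric(length(bi))
    a[as.integer(names(sumA))] <- sumA
    b[as.integer(names(sumB))] <- sumB
    # rolling window sum over +/- smooth_halfwidth bins
    kern <- rep(1, 2 * smooth_halfwidth + 1)
    aa <- stats::filter(a, kern, sides = 2)
    bb <- stats::filter(b, kern, sides = 2)
    aa[is.na(aa)] <- a[is.na(aa)]; bb[is.na(bb)] <- b[is.na(bb)]
    tot <- aa + bb
    fr <- ifelse(tot > 0, aa / tot, NA)
    miss <- is.na(fr)
    if (all(miss)) { fr[] <- 0.5 } else if (any(miss)) {
      ok <- which(!miss)
      nearest <- ok[pmax(1, findInterval(which(miss), ok))]
      # nearest informative bin (either side)
      for (qi in seq_along(nearest)) {
        m <- which(miss)[qi]
        lo <- nearest[qi]
        hi <- ok[min(length(ok), findInterval(m, ok) + 1)]
        fr[m] <- fr[if (abs(m - lo) <= abs(hi - m)) lo else hi]
      }
    }
    out$frac[bi] <- fr
    out$imputed[bi] <- miss
  }
  out$hapA <- out$total * out$frac
  out$hapB <- out$total * (1 - out$frac)
  out
}

#' Segment a haplotype-specific coverage profile
#'
#' Joint penalized least-squares changepoint detection on the two
#' homolog coverage tracks; the changepoint penalty scales with
#' `penalty_factor` (default 1.8, a deliberately conservative setting
#' that avoids over-segmentation of noisy FFPE coverage).
#'
#' @param hap output of [haplotype_coverage()].
#' @param penalty_factor penalty multiplier (default 1.8).
#' @param min_seg minimum segment length in bins (default 2).
#' @return data.frame chrom, start, end, n_bins, hapA, hapB (segment
#'   means), total.
#' @export
segment_profile <- function(hap, penalty_factor = 1.8, min_seg = 2) {
  out <- list()
  for (cn in unique(hap$chrom)) {
    h <- hap[hap$chrom == cn, ]
    ok <- is.finite(h$hapA) & is.finite(h$hapB)
    h <- h[ok, ]
    if (nrow(h) < 2) next
    cps <- find_changepoints(cbind(h$hapA, h$hapB), penalty_factor,
                             min_seg)
    seg_id <- findInterval(seq_len(nrow(h)), c(1, cps))
    out[[cn]] <- data.frame(
      chrom = cn,
      start = tapply(h$start, seg_id, min),
      end = tapply(h$end, seg_id, max),
      n_bins = as.integer(table(seg_id)),
      hapA = tapply(h$hapA, seg_id, mean),
      hapB = tapply(h$hapB, seg_id, mean),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df$total <- df$hapA + df$hapB
  rownames(df) <- NULL
  df
}

# expected normalized allelic coverage for allelic CN c (internal):
# a = (p*c + (1-p)) / D with D = p*ploidy + 2*(1-p), so that the
# genome-wide mean total coverage is 1 (the centering convention of
# normalize_bulk) and the implied average total CN equals the ploidy.
implied_allelic_cn <- function(a, purity, ploidy) {
  D <- purity * ploidy + 2 * (1 - purity)
  (a * D - (1 - purity)) / purity
}

#' Grid-search estimation of sample purity and ploidy
#'
#' Searches purity in [0.05, 1] (step 0.01) x ploidy in [1.2, 6]
#' (step 0.05) for the solution whose implied allelic copy numbers are
#' closest to non-negative integers (length-weighted).  Candidate
#' solutions are ranked and the automatic pick is the candidate with
#' the fewest subclonal (non-integer) states, ties broken toward lower
#' ploidy — a deterministic stand-in for manual solution review.
#' Samples without allelic imbalance anywhere are reported
#' "indeterminate" rather than forced.
#'
#' @param segments output of [segment_profile()].
#' @param min_seg_len ignore segments shorter than this many bp in the
#'   fit (default 2e6).
#' @param subclonal_threshold residual (in copies) above which a
#'   segment state counts as subclonal (default 0.3).
#' @param imbalance_min minimum |hapA - hapB| coverage difference that
#'   counts as allelic imbalance (default 0.1).
#' @return list with `status` ("ok"/"indeterminate"), `purity`,
#'   `ploidy`, and `candidates` (data.frame purity, ploidy, objective,
#'   n_subclonal, ranked).
#' @export
estimate_purity_ploidy <- function(segments, min_seg_len = 2e6,
                                   subclonal_threshold = 0.3,
                                   imbalance_min = 0.1) {
  seg <- segments[segments$end - segments$start >= min_seg_len, ]
  if (nrow(seg) == 0 ||
      (max(abs(seg$hapA - seg$hapB)) < imbalance_min &&
       max(seg$total) - min(seg$total) < imbalance_min)) {
    return(list(status = "indeterminate", purity = NA_real_,
                ploidy = NA_real_, candidates = NULL))
  }
  w <- rep(seg$end - seg$start, 2)
  a <- c(seg$hapA, seg$hapB)
  purities <- seq(0.05, 1, by = 0.01)
  ploidies <- seq(1.2, 6, by = 0.05)
  grid <- expand.grid(purity = purities, ploidy = ploidies)
  obj <- numeric(nrow(grid)); nsub <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cc <- implied_allelic_cn(a, grid$purity[i], grid$ploidy[i])
    dist <- abs(cc - pmax(0, round(cc)))
    obj[i] <- sum(w * dist) / sum(w)
    nsub[i] <- sum(dist > subclonal_threshold)
  }
  grid$objective <- obj
  grid$n_subclonal <- nsub
  # candidate set: fits statistically indistinguishable from the best;
  # a wider window would let the lower-ploidy preference bias the pick
  cand <- grid[grid$objective <= min(grid$objective) + 0.005, ]
  cand <- cand[order(cand$n_subclonal, cand$ploidy, cand$objective), ]
  best <- cand[1, ]
  list(status = "ok", purity = best$purity, ploidy = best$ploidy,
       candidates = cand)
}

#' Call integer allelic copy number from segments
#'
#' Maps segment-level haplotype coverages to allelic copy numbers given
#' purity and ploidy, rounds to the nearest non-negative integer and
#' flags segments whose residual exceeds `subclonal_threshold` copies
#' as subclonal.
#'
#' @param segments output of [segment_profile()].
#' @param purity,ploidy sample estimates.
#' @param subclonal_threshold residual threshold in copies (default
#'   0.3).
#' @return list with `karyotype` (a `karyotype`: chrom, start, end,
#'   cnA, cnB) and `diagnostics` (segments plus raw cnA/cnB and
#'   subclonal flags).
#' @export
call_integer_cn <- function(segments, purity, ploidy,
                            subclonal_threshold = 0.3) {
  if (is.na(purity) || purity <= 0) stop("purity must be positive")
  rawA <- implied_allelic_cn(segments$hapA, purity, ploidy)
  rawB <- implied_allelic_cn(segments$hapB, purity, ploidy)
  cnA <- pmax(0L, as.integer(round(rawA)))
  cnB <- pmax(0L, as.integer(round(rawB)))
  diag <- segments
  diag$rawA <- rawA; diag$rawB <- rawB
  diag$cnA <- cnA; diag$cnB <- cnB
  diag$subclonal <- abs(rawA - cnA) > subclonal_threshold |
    abs(rawB - cnB) > subclonal_threshold
  k <- as_karyotype(data.frame(chrom = segments$chrom,
                               start = segments$start, end = segments$end,
                               cnA = cnA, cnB = cnB,
                               stringsAsFactors = FALSE))
  list(karyotype = simplify_karyotype(k), diagnostics = diag)
}

#' End-to-end allelic copy-number calling for one bulk sample
#'
#' Convenience wrapper: panel normalization, haplotype coverage,
#' segmentation, purity/ploidy grid search and integer calls.
#'
#' @param obs a `patient_obs` from [render_patient()].
#' @param sample sample name (column of `obs$counts`).
#' @param allelic_corrected corrected allelic list (defaults to the raw
#'   reported phase, i.e. no correction).
#' @param penalty_factor segmentation penalty (default 1.8).
#' @return list with `hap`, `segments`, `fit`, `call`.
#' @export
call_sample_cn <- function(obs, sample,
                           allelic_corrected = obs$allelic,
                           penalty_factor = 1.8) {
  norm <- normalize_bulk(obs$counts[, sample], obs$panel_counts,
                         obs$bins$gc)
  j <- match(sample, colnames(as.matrix(allelic_corrected$depthA)))
  al <- list(sites = allelic_corrected$sites,
             depthA = as.matrix(allelic_corrected$depthA)[, j],
             depthB = as.matrix(allelic_corrected$depthB)[, j])
  hap <- haplotype_coverage(norm, al, obs$bins)
  segs <- segment_profile(hap, penalty_factor)
  fit <- estimate_purity_ploidy(segs)
  call <- if (fit$status == "ok")
    call_integer_cn(segs, fit$purity, fit$ploidy) else NULL
  list(hap = hap, segments = segs, fit = fit, call = call)
}
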
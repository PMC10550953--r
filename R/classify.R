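#' Classification options for SCNA calling
#'
#' @param osc_threshold minimum number of alternating copy-number
#'   switches between two states that counts as chromothripsis
#'   (default 8).
#' @param arm_tol breakpoints within this distance of a centromere or
#'   telomere count as arm-level (default 1e6, absorbing segmentation
#'   jitter).
#' @param focal_max interior events shorter than this are focal
#'   (default 5e6).
#' @param amp_threshold allelic copy number at or above which a segment
#'   is an amplification (default 8, reachable from one copy by three
#'   duplication rounds).
#' @param max_osc_fragment maximum length of a single oscillation
#'   fragment (default 1e7); longer runs terminate the oscillating
#'   chain so that adjacent large SCNAs stay separate events.
#' @return list of class `classify_config`.
#' @export
classify_config <- function(osc_threshold = 8, arm_tol = 1e6,
                            focal_max = 5e6, amp_threshold = 8,
                            max_osc_fragment = 1e7) {
  structure(list(osc_threshold = osc_threshold, arm_tol = arm_tol,
                 focal_max = focal_max, amp_threshold = amp_threshold,
                 max_osc_fragment = max_osc_fragment),
            class = "classify_config")
}

# Length-weighted modal CN per homolog, ties -> lower CN (internal).
baseline_cn <- function(k, homolog) {
  col <- paste0("cn", homolog)
  w <- tapply(k$end - k$start, k[[col]], sum)
  vals <- as.integer(names(w))
  vals[order(-w, vals)][1]
}

# Per-homolog constant-CN runs on one chromosome (internal).
homolog_runs <- function(k, chrom, homolog) {
  s <- k[k$chrom == chrom, ]
  s <- s[order(s$start), ]
  cn <- s[[paste0("cn", homolog)]]
  r <- rle(cn)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  data.frame(start = s$start[starts], end = s$end[ends], cn = r$values)
}

complexity_tier <- function(category) {
  switch(category,
         chromothripsis = "complex",
         amplification = "amplified",
         terminal_gain = , terminal_loss = ,
         paracentric_gain = , paracentric_loss = ,
         pericentric_gain = , pericentric_loss = ,
         sloping = "segmental",
         "simple")
}

scna_event <- function(sample = NA_character_, chrom, homolog, category,
                       start, end, breakpoints, copy_change,
                       footprint = NA_character_) {
  data.frame(sample = sample, chrom = chrom, homolog = homolog,
             category = category, start = start, end = end,
             breakpoints = paste(sort(breakpoints), collapse = ","),
             copy_change = copy_change, footprint = footprint,
             complexity = complexity_tier(category),
             stringsAsFactors = FALSE)
}

#' Classify the SCNAs on one chromosome of a parental karyotype
#'
#' Decomposes the copy-number profile of each homolog relative to its
#' genome-wide baseline (length-weighted modal copy number, ties to the
#' lower state) into classified events.  Decision order: oscillating
#' runs of at least `osc_threshold` switches between two states are
#' chromothripsis; whole-chromosome and arm-level deviations (to within
#' `arm_tol` of centromere/telomere); copy-neutral one-homolog-zero
#' regions are UPD; telomere-reaching deviations with one interior
#' breakpoint are terminal; interior segments are focal (< `focal_max`),
#' paracentric (within one arm) or pericentric (spanning the
#' centromere); any segment at allelic copy number >= `amp_threshold`
#' is additionally an amplification.
#'
#' @param k an integer `karyotype`.
#' @param chrom chromosome to classify.
#' @param genome a `genome_model`.
#' @param config a [classify_config()].
#' @param sample optional sample label carried into the events.
#' @return data.frame of `ScnaEvent` rows (zero rows if the chromosome
#'   is at baseline).
#' @export
classify_chromosome <- function(k, chrom, genome,
                                config = classify_config(),
                                sample = NA_character_) {
  L <- genome$lengths[[chrom]]
  cen <- genome$centromeres[genome$centromeres$chrom == chrom, ]
  tol <- config$arm_tol
  events <- list()
  add <- function(e) events[[length(events) + 1L]] <<- e

  baseA <- baseline_cn(k, "A"); baseB <- baseline_cn(k, "B")
  base <- c(A = baseA, B = baseB)

  # --- UPD: copy-neutral, one homolog zero, the other compensating ---
  s <- k[k$chrom == chrom, ]; s <- s[order(s$start), ]
  upd_seg <- (s$cnA + s$cnB == baseA + baseB) &
    ((s$cnA == 0 & s$cnB > base["B"]) | (s$cnB == 0 & s$cnA > base["A"]))
  consumed_upd <- rep(FALSE, nrow(s))
  if (any(upd_seg)) {
    r <- rle(upd_seg)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (q in which(r$values)) {
      i0 <- starts[q]; i1 <- ends[q]
      hom <- if (s$cnA[i0] == 0) "B" else "A"  # donor homolog
      bps <- c(s$start[i0], s$end[i1])
      bps <- bps[bps > 0 & bps < L]
      add(scna_event(sample, chrom, hom, "UPD", s$start[i0], s$end[i1],
                     bps, 0))
      consumed_upd[i0:i1] <- TRUE
    }
  }
  upd_iv <- do.call(rbind, lapply(which(consumed_upd),
                                  function(i) c(s$start[i], s$end[i])))

  for (hom in c("A", "B")) {
    runs <- homolog_runs(k, chrom, hom)
    bl <- base[[hom]]
    # drop runs fully inside UPD regions (both homologs already consumed)
    in_upd <- rep(FALSE, nrow(runs))
    if (!is.null(upd_iv)) {
      for (i in seq_len(nrow(runs)))
        in_upd[i] <- any(runs$start[i] >= upd_iv[, 1] &
                           runs$end[i] <= upd_iv[, 2])
    }
    # --- chromothripsis: oscillation between two CN states ---
    consumed <- in_upd
    n <- nrow(runs)
    if (n >= 3) {
      eligible <- (runs$end - runs$start) <= config$max_osc_fragment
      i <- 1L
      while (i <= n - 1L) {
        if (!eligible[i] || !eligible[i + 1L]) { i <- i + 1L; next }
        v1 <- runs$cn[i]; v2 <- runs$cn[i + 1L]
        j <- i + 1L
        while (j < n && eligible[j + 1L] &&
               runs$cn[j + 1L] == runs$cn[j - 1L]) j <- j + 1L
        switches <- j - i
        if (switches >= config$osc_threshold) {
          # trim flanking baseline runs: the footprint spans the deviant part
          i2 <- if (runs$cn[i] == bl) i + 1L else i
          j2 <- if (runs$cn[j] == bl) j - 1L else j
          bps <- runs$start[(i + 1L):j]
          states <- sort(unique(c(v1, v2)))
          add(scna_event(sample, chrom, hom, "chromothripsis",
                         runs$start[i2], runs$end[j2], bps,
                         min(states) - bl))
          consumed[i:j] <- TRUE
        }
        i <- j
      }
    }
    # --- amplification: allelic CN >= threshold ---
    for (i in seq_len(n)) {
      if (runs$cn[i] >= config$amp_threshold) {
        bps <- c(runs$start[i], runs$end[i])
        bps <- bps[bps > 0 & bps < L]
        add(scna_event(sample, chrom, hom, "amplification",
                       runs$start[i], runs$end[i], bps,
                       runs$cn[i] - bl))
        consumed[i] <- TRUE
      }
    }
    # --- remaining deviant runs, one event per constant-CN run ---
    for (i in seq_len(n)) {
      if (consumed[i] || runs$cn[i] == bl) next
      r_start <- runs$start[i]; r_end <- runs$end[i]
      dc <- runs$cn[i] - bl
      dir <- if (dc > 0) "gain" else "loss"
      touches_p <- r_start <= 0
      touches_q <- r_end >= L
      near_p <- r_start <= tol
      near_q <- r_end >= L - tol
      near_cen_lo <- abs(r_start - cen$start) <= tol |
        abs(r_start - cen$end) <= tol
      near_cen_hi <- abs(r_end - cen$start) <= tol |
        abs(r_end - cen$end) <= tol
      bps <- c(r_start, r_end); bps <- bps[bps > 0 & bps < L]
      cat_name <- if (near_p && near_q) {
        paste0("whole_chrom_", dir)
      } else if ((near_p && near_cen_hi) || (near_cen_lo && near_q)) {
        paste0("arm_", dir)
      } else if (touches_p || touches_q) {
        paste0("terminal_", dir)
      } else if (r_end - r_start < config$focal_max) {
        if (dc > 0) "focal_dup" else "focal_del"
      } else if (r_start < cen$end && r_end > cen$start) {
        paste0("pericentric_", dir)
      } else {
        paste0("paracentric_", dir)
      }
      add(scna_event(sample, chrom, hom, cat_name, r_start, r_end,
                     bps, dc))
    }
  }
  if (length(events) == 0)
    return(scna_event(sample, chrom, "A", "none", 0, 0, numeric(0), 0)[0, ])
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Classify all chromosomes of a karyotype
#' @inheritParams classify_chromosome
#' @return combined event data.frame.
#' @export
classify_karyotype <- function(k, genome, config = classify_config(),
                               sample = NA_character_) {
  out <- lapply(genome$chroms, function(cn)
    classify_chromosome(k, cn, genome, config, sample))
  do.call(rbind, out)
}

#' Footprint label for a chromothripsis event
#'
#' Labels the oscillating region 'direct-bridge' when it abuts the
#' boundary of a large terminal or internal SCNA (within `tol`),
#' 'downstream-micronucleus' when it spans a whole arm or a
#' centromeric/telomeric segment, and 'regional' otherwise.  The two
#' mechanisms are not strictly distinguishable from copy number alone,
#' so the label is a best-effort annotation, not a hard claim.
#'
#' @param event one chromothripsis event row.
#' @param chrom_events all events on the same chromosome and homolog.
#' @param genome a `genome_model`.
#' @param tol boundary tolerance in bp (default 1e6).
#' @return character footprint label.
#' @export
classify_chromothripsis_footprint <- function(event, chrom_events, genome,
                                              tol = 1e6) {
  stopifnot(event$category == "chromothripsis")
  L <- genome$lengths[[event$chrom]]
  cen <- genome$centromeres[genome$centromeres$chrom == event$chrom, ]
  big <- chrom_events[chrom_events$category %in%
                        c("terminal_gain", "terminal_loss",
                          "paracentric_gain", "paracentric_loss",
                          "pericentric_gain", "pericentric_loss") &
                        !(chrom_events$start == event$start &
                            chrom_events$end == event$end), , drop = FALSE]
  if (nrow(big) > 0) {
    bnd <- c(big$start, big$end)
    if (any(abs(bnd - event$start) <= tol | abs(bnd - event$end) <= tol))
      return("direct-bridge")
  }
  spans_arm <- (event$start <= tol && abs(event$end - cen$start) <= tol) ||
    (abs(event$start - cen$end) <= tol && event$end >= L - tol) ||
    (event$start <= tol && event$end >= L - tol)
  spans_cen <- event$start < cen$end && event$end > cen$start
  touches_tel <- event$start <= tol || event$end >= L - tol
  if (spans_arm || spans_cen || touches_tel) return("downstream-micronucleus")
  "regional"
}

# best single-step (two-mean) SSE along an ordered signal (internal)
best_step_sse <- function(y) {
  n <- length(y)
  if (n < 4) return(sum((y - mean(y))^2))
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  t <- 2:(n - 2)
  sseL <- cs2[t] - cs[t]^2 / t
  sseR <- (cs2[n] - cs2[t]) - (cs[n] - cs[t])^2 / (n - t)
  min(sseL + sseR)
}

#' Detect sloping (gradually attenuating) copy number on an arm
#'
#' A sloping call on a homolog requires a robust monotone trend toward
#' a telomere or centromere with total attenuation of at least
#' `min_atten` copies over at least `min_span` bp, while the other
#' homolog stays flat (its attenuation below `flat_band`).  The trend
#' is assessed by Spearman rank correlation plus a robust linear fit,
#' and a clonal step is rejected by requiring the linear fit to beat
#' the best single-step (two-level) fit.
#'
#' @param hap_cn data.frame chrom, start, end, cnA, cnB with continuous
#'   (purity-corrected) allelic copy number per bin.
#' @param genome a `genome_model`.
#' @param min_span minimum span in bp (default 5e6).
#' @param min_atten minimum attenuation in copies (default 0.3).
#' @param flat_band maximum attenuation of the control homolog
#'   (default 0.2).
#' @param min_rho minimum |Spearman rho| (default 0.4).
#' @return data.frame of calls: chrom, arm, homolog, start, end,
#'   direction ("telomeric"/"centromeric"), attenuation, rho.
#' @export
detect_sloping <- function(hap_cn, genome, min_span = 5e6,
                           min_atten = 0.3, flat_band = 0.2,
                           min_rho = 0.4) {
  arms <- genome_arms(genome)
  calls <- list()
  for (i in seq_len(nrow(arms))) {
    sel <- hap_cn$chrom == arms$chrom[i] &
      hap_cn$start >= arms$start[i] & hap_cn$end <= arms$end[i]
    h <- hap_cn[sel, ]
    h <- h[order(h$start), ]
    arm_span <- if (nrow(h)) max(h$end) - min(h$start) else 0
    if (arm_span < min_span || nrow(h) < 20) next
    x <- (h$start + h$end) / 2
    n <- nrow(h)
    # candidate regions anchored at either arm end (erosion always runs
    # into a telomere or centromere); spans from min_span to the arm
    spans <- unique(pmin(arm_span, min_span * 2^(0:10)))
    spans <- spans[spans >= min_span]
    q_arm <- arms$arm[i] == "q"
    best <- NULL
    for (hom in c("A", "B")) {
      other <- if (hom == "A") "B" else "A"
      y <- h[[paste0("cn", hom)]]
      yo <- h[[paste0("cn", other)]]
      for (anchor in c("left", "right")) for (sp in spans) {
        idx <- if (anchor == "right") which(x >= max(h$end) - sp)
               else which(x <= min(h$start) + sp)
        if (length(idx) < 20) next
        xs <- x[idx]; ys <- y[idx]; yos <- yo[idx]
        span <- max(xs) - min(xs)
        fit <- tryCatch(MASS::rlm(ys ~ xs, maxit = 50),
                        error = function(e) stats::lm(ys ~ xs))
        slope <- stats::coef(fit)[2]
        # decline must run toward the anchor end
        if (anchor == "right" && slope >= 0) next
        if (anchor == "left" && slope <= 0) next
        att <- abs(slope) * span
        rho <- suppressWarnings(stats::cor(xs, ys, method = "spearman"))
        if (is.na(att) || att < min_atten || is.na(rho) ||
            abs(rho) < min_rho) next
        fito <- stats::lm(yos ~ xs)
        if (abs(stats::coef(fito)[2]) * span > flat_band) next
        res_lin <- sum(stats::resid(stats::lm(ys ~ xs))^2)
        if (res_lin > best_step_sse(ys)) next  # a step, not a slope
        toward_tel <- (q_arm && anchor == "right") ||
          (!q_arm && anchor == "left")
        cand <- data.frame(
          chrom = arms$chrom[i], arm = arms$arm[i], homolog = hom,
          start = min(h$start[idx]), end = max(h$end[idx]),
          direction = if (toward_tel) "telomeric" else "centromeric",
          attenuation = att, rho = rho, stringsAsFactors = FALSE)
        if (is.null(best) || abs(rho) > abs(best$rho) ||
            (best$homolog == hom && att > best$attenuation))
          best <- cand
      }
    }
    if (!is.null(best)) calls[[length(calls) + 1L]] <- best
  }
  if (length(calls) == 0)
    return(data.frame(chrom = character(0), arm = character(0),
                      homolog = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      attenuation = numeric(0), rho = numeric(0)))
  do.call(rbind, calls)
}

#' Infer whole-genome duplication from an integer karyotype
#'
#' A sample is called WGD when the length-weighted fraction of the
#' genome whose major homolog has two or more copies exceeds
#' `threshold`: even heavily rearranged post-WGD genomes retain most
#' homologous chromosomes at two or more copies.
#'
#' @param k an integer `karyotype`.
#' @param threshold genome fraction (default 0.5).
#' @return logical.
#' @export
infer_wgd_bulk <- function(k, threshold = 0.5) {
  w <- k$end - k$start
  frac <- sum(w[pmax(k$cnA, k$cnB) >= 2]) / sum(w)
  frac > threshold
}

#' Filter candidate rearrangements against copy-number changepoints
#'
#' FFPE libraries generate chimeric artifacts, so candidates whose two
#' breakpoints lie within `min_pair_dist` of each other are discarded,
#' and only candidates with BOTH breakpoints within `tol` of some
#' copy-number changepoint are kept.
#'
#' @param cands data.frame chrom1, pos1, chrom2, pos2 (plus anything
#'   else, carried through).
#' @param changepoints data.frame chrom, pos of copy-number
#'   changepoints.
#' @param min_pair_dist minimum intra-pair distance (default 1e5).
#' @param tol maximum breakpoint-to-changepoint distance (default 1e5).
#' @return the kept rows of `cands`.
#' @export
filter_rearrangements <- function(cands, changepoints,
                                  min_pair_dist = 1e5, tol = 1e5) {
  if (nrow(cands) == 0) return(cands)
  near_cp <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      cp <- changepoints$pos[changepoints$chrom == chrom[i]]
      length(cp) > 0 && min(abs(cp - pos[i])) <= tol
    }, TRUE)
  }
  keep <- !(cands$chrom1 == cands$chrom2 &
              abs(cands$pos1 - cands$pos2) < min_pair_dist) &
    near_cp(cands$chrom1, cands$pos1) &
    near_cp(cands$chrom2, cands$pos2)
  cands[keep, , drop = FALSE]
}
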
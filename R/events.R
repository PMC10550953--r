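#' Mechanistic copy-number event operators
#'
#' These functions apply single structural events to a parental
#' karyotype and are the generative repertoire of the clone-evolution
#' simulator: breakage-fusion-bridge (BFB) terminal breaks, paracentric
#' and pericentric segmental changes, chromothripsis, BFB focal
#' amplification, whole-genome duplication, whole-chromosome
#' missegregation, uniparental disomy (UPD) and focal events.  All
#' operators preserve the segment-tiling invariant and return a new
#' karyotype; they never mutate their input.
#'
#' @name scna_events
NULL

#' Break a dicentric bridge: reciprocal terminal loss and gain
#'
#' Breakage of a chromatid-type bridge distributes the distal segment
#' unevenly between the two daughter cells: one daughter loses one copy
#' of the region distal of the breakpoint and the other gains one, so
#' for every position the two daughters sum to twice the parent.
#'
#' @param k parent `karyotype`.
#' @param chrom chromosome name.
#' @param homolog "A" or "B".
#' @param breakpoint position in bp, strictly inside the chromosome.
#' @param genome a `genome_model` (for chromosome lengths).
#' @return list with `daughter1` (terminal loss) and `daughter2`
#'   (terminal gain).
#' @export
apply_bfb_break <- function(k, chrom, homolog, breakpoint, genome) {
  L <- genome$lengths[[chrom]]
  if (breakpoint <= 0 || breakpoint >= L)
    stop("breakpoint must be strictly inside the chromosome")
  if (min(kar_cn_at(k, chrom, homolog,
                    c(breakpoint, (breakpoint + L) / 2))) < 1)
    stop("homolog has copy number 0 distal of the breakpoint")
  d1 <- kar_edit(k, chrom, homolog, breakpoint, L, -1L)
  d2 <- kar_edit(k, chrom, homolog, breakpoint, L, +1L)
  list(daughter1 = d1, daughter2 = d2)
}

#' Internal segmental gain or loss (paracentric or pericentric)
#'
#' Chromosome-type bridge breakage (or a broken ring chromosome) leaves
#' a gain or loss of an internal segment; the event is paracentric if
#' the segment lies within one arm and pericentric if it spans the
#' centromere.  Segments touching a telomere are rejected: those are
#' terminal events.
#'
#' @param k parent `karyotype`.
#' @param chrom,homolog target homolog.
#' @param bp1,bp2 interior breakpoints, bp1 < bp2.
#' @param sign +1 (gain) or -1 (loss).
#' @param genome a `genome_model`.
#' @return a `karyotype`; attribute "arm_class" is "paracentric" or
#'   "pericentric".
#' @export
apply_internal_segment <- function(k, chrom, homolog, bp1, bp2, sign, genome) {
  L <- genome$lengths[[chrom]]
  if (!(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  if (!(bp1 < bp2)) stop("bp1 must be < bp2")
  if (bp1 <= 0 || bp2 >= L)
    stop("segment touching a telomere is a terminal event, not internal")
  out <- kar_edit(k, chrom, homolog, bp1, bp2, as.integer(sign))
  cen <- genome$centromeres
  ci <- cen[cen$chrom == chrom, ]
  spans_cen <- bp1 < ci$end && bp2 > ci$start
  attr(out, "arm_class") <- if (spans_cen) "pericentric" else "paracentric"
  out
}

#' Chromothripsis: shatter a region into fragments with random retention
#'
#' The region is partitioned into `n_fragments` intervals by uniform
#' stick-breaking; each fragment is independently retained (copy number
#' unchanged) with probability `retention_p` or lost (one copy removed).
#' On a uniform baseline this yields the oscillating two-state
#' copy-number profile characteristic of shattered bridge or
#' micronucleus chromatin.
#'
#' @param k parent `karyotype`.
#' @param chrom,homolog target homolog.
#' @param region numeric length-2 (start, end) in bp.
#' @param n_fragments number of fragments (>= 4).
#' @param retention_p per-fragment retention probability.
#' @param seed optional seed.
#' @return a `karyotype`; attribute "fragments" records the partition
#'   and retention outcome.
#' @export
apply_chromothripsis <- function(k, chrom, homolog, region, n_fragments,
                                 retention_p = 0.5, seed = NULL) {
  if (n_fragments < 4) stop("chromothripsis needs at least 4 fragments")
  if (!is.null(seed)) set.seed(seed)
  cuts <- sort(stats::runif(n_fragments - 1, region[1], region[2]))
  bounds <- c(region[1], cuts, region[2])
  retained <- stats::runif(n_fragments) < retention_p
  out <- k
  for (i in which(!retained)) {
    out <- kar_edit(out, chrom, homolog, bounds[i], bounds[i + 1], -1L)
  }
  attr(out, "fragments") <- data.frame(start = bounds[-length(bounds)],
                                       end = bounds[-1],
                                       retained = retained)
  out
}

#' BFB focal amplification by successive duplication rounds
#'
#' Successive duplications at a broken chromosome end double the focus
#' copy number each round; the flank distal of the focus (toward the
#' nearest telomere, i.e. the broken terminus) is lost.  Three rounds
#' starting from one copy reach copy number 8, the conventional
#' amplification threshold.
#'
#' @param k parent `karyotype`.
#' @param chrom,homolog target homolog.
#' @param focus numeric length-2 (start, end) of the amplified interval.
#' @param rounds number of duplication rounds (>= 0).
#' @param genome a `genome_model`.
#' @return a `karyotype`.
#' @export
apply_bfb_amplification <- function(k, chrom, homolog, focus, rounds, genome) {
  if (rounds < 0) stop("rounds must be >= 0")
  L <- genome$lengths[[chrom]]
  if (rounds == 0) return(k)
  col <- paste0("cn", homolog)
  out <- kar_split_at(k, chrom, focus)
  sel <- out$chrom == chrom & out$start >= focus[1] & out$end <= focus[2]
  if (min(out[[col]][sel]) < 1) stop("focus has copy number 0")
  out[[col]][sel] <- out[[col]][sel] * 2L^rounds
  # broken terminus: the telomere closer to the focus loses the flank
  q_side <- (focus[1] + focus[2]) / 2 > L / 2
  flank <- if (q_side) c(focus[2], L) else c(0, focus[1])
  if (flank[2] > flank[1]) {
    out <- kar_split_at(out, chrom, flank)
    sel2 <- out$chrom == chrom & out$start >= flank[1] & out$end <= flank[2]
    out[[col]][sel2] <- 0L
  }
  out
}

#' Whole-genome duplication
#' @param k a `karyotype`.
#' @return karyotype with every copy number doubled.
#' @export
apply_wgd <- function(k) {
  k$cnA <- k$cnA * 2L
  k$cnB <- k$cnB * 2L
  k
}

#' Whole-chromosome missegregation
#' @param k a `karyotype`.
#' @param chrom,homolog target homolog.
#' @param sign +1 (gain) or -1 (loss of one copy).
#' @return a `karyotype`.
#' @export
apply_missegregation <- function(k, chrom, homolog, sign) {
  col <- paste0("cn", homolog)
  sel <- k$chrom == chrom
  newcn <- k[[col]][sel] + as.integer(sign)
  if (any(newcn < 0)) stop("missegregation would produce negative copy number")
  k[[col]][sel] <- newcn
  k
}

#' Uniparental disomy (copy-neutral loss of heterozygosity)
#'
#' The recipient homolog is replaced by additional copies of the donor
#' over the region: total copy number is preserved exactly.
#'
#' @param k a `karyotype`.
#' @param chrom chromosome.
#' @param region numeric length-2 (start, end); use c(0, length) for
#'   whole-chromosome UPD.
#' @param donor_homolog "A" or "B": the homolog that replaces the other.
#' @return a `karyotype`.
#' @export
apply_upd <- function(k, chrom, region, donor_homolog = "A") {
  recip <- if (donor_homolog == "A") "B" else "A"
  dcol <- paste0("cn", donor_homolog); rcol <- paste0("cn", recip)
  out <- kar_split_at(k, chrom, region)
  sel <- out$chrom == chrom & out$start >= region[1] & out$end <= region[2]
  if (min(out[[dcol]][sel]) < 1) stop("donor homolog has copy number 0")
  out[[dcol]][sel] <- out[[dcol]][sel] + out[[rcol]][sel]
  out[[rcol]][sel] <- 0L
  out
}

#' Focal deletion or duplication
#' @param k a `karyotype`.
#' @param chrom,homolog target homolog.
#' @param region numeric length-2 (start, end), typically < 5 Mb.
#' @param sign +1 or -1.
#' @return a `karyotype`.
#' @export
apply_focal <- function(k, chrom, homolog, region, sign) {
  kar_edit(k, chrom, homolog, region[1], region[2], as.integer(sign))
}

#' Terminal gain or loss (single bridge-break daughter)
#' @param k a `karyotype`.
#' @param chrom,homolog target homolog.
#' @param breakpoint interior breakpoint in bp.
#' @param sign +1 or -1 applied distal of the breakpoint (toward the q
#'   telomere).
#' @param genome a `genome_model`.
#' @export
apply_terminal <- function(k, chrom, homolog, breakpoint, sign, genome) {
  L <- genome$lengths[[chrom]]
  if (breakpoint <= 0 || breakpoint >= L) stop("breakpoint must be interior")
  kar_edit(k, chrom, homolog, breakpoint, L, as.integer(sign))
}

#' Apply one event specification to a karyotype
#'
#' Dispatch helper used by the clone-tree simulator.  An event spec is a
#' list with a `kind` field and kind-specific parameters (see
#' [simulate_clone_tree()]).
#'
#' @param k a `karyotype`.
#' @param ev event spec list.
#' @param genome a `genome_model`.
#' @return a `karyotype`.
#' @export
apply_event <- function(k, ev, genome) {
  switch(ev$kind,
    wgd = apply_wgd(k),
    missegregation = apply_missegregation(k, ev$chrom, ev$homolog, ev$sign),
    upd = apply_upd(k, ev$chrom, ev$region, ev$homolog),
    terminal = apply_terminal(k, ev$chrom, ev$homolog, ev$breakpoint,
                              ev$sign, genome),
    bfb_terminal = apply_terminal(k, ev$chrom, ev$homolog, ev$breakpoint,
                                  ev$sign, genome),
    bfb_paracentric = ,
    bfb_pericentric = ,
    internal = apply_internal_segment(k, ev$chrom, ev$homolog,
                                      ev$region[1], ev$region[2],
                                      ev$sign, genome),
    chromothripsis = apply_chromothripsis(k, ev$chrom, ev$homolog,
                                          ev$region, ev$n_fragments,
                                          ev$retention_p),
    bfb_amplification = apply_bfb_amplification(k, ev$chrom, ev$homolog,
                                                ev$region, ev$rounds, genome),
    focal_del = apply_focal(k, ev$chrom, ev$homolog, ev$region, -1L),
    focal_dup = apply_focal(k, ev$chrom, ev$homolog, ev$region, +1L),
    stop("unknown event kind: ", ev$kind)
  )
}

#' Draw a random single-event karyotype of a given category
#'
#' Applies exactly one alteration of the requested category to a
#' diploid karyotype, with breakpoints drawn at random but respecting
#' the category's definition (e.g. arm-level events end at the
#' centromere, chromothripsis instances are redrawn until the
#' fragmentation actually exhibits the oscillation signature of at
#' least `osc_min` switches).  Used for classifier oracle studies.
#'
#' @param genome a `genome_model`.
#' @param category one of terminal_gain, terminal_loss,
#'   paracentric_gain, paracentric_loss, pericentric_gain,
#'   pericentric_loss, UPD, arm_gain, arm_loss, whole_chrom_gain,
#'   whole_chrom_loss, focal_del, focal_dup, amplification,
#'   chromothripsis.
#' @param chrom target chromosome (default: random).
#' @param osc_min minimum oscillation switches for a chromothripsis
#'   instance (default 8).
#' @return list with `karyotype`, `category`, `chrom`, `homolog`.
#' @export
simulate_single_event <- function(genome, category,
                                  chrom = sample(genome$chroms, 1),
                                  osc_min = 8) {
  L <- genome$lengths[[chrom]]
  cen <- genome$centromeres[genome$centromeres$chrom == chrom, ]
  hom <- sample(c("A", "B"), 1)
  k0 <- diploid_karyotype(genome)
  margin <- 2e6
  k <- switch(category,
    terminal_gain = ,
    terminal_loss = {
      repeat {  # keep the breakpoint clear of the centromere zone:
        bp <- stats::runif(1, 0.15 * L, 0.85 * L)
        if (bp < cen$start - margin || bp > cen$end + margin) break
      }
      apply_terminal(k0, chrom, hom, bp,
                     if (category == "terminal_gain") 1L else -1L, genome)
    },
    paracentric_gain = ,
    paracentric_loss = {
      q <- stats::runif(1) < 0.5
      lo <- if (q) cen$end + margin else margin
      hi <- if (q) L - margin else cen$start - margin
      b <- sort(stats::runif(2, lo, hi))
      while (b[2] - b[1] < 6e6) b <- sort(stats::runif(2, lo, hi))
      apply_internal_segment(k0, chrom, hom, b[1], b[2],
                             if (grepl("gain", category)) 1L else -1L, genome)
    },
    pericentric_gain = ,
    pericentric_loss = {
      b1 <- stats::runif(1, margin, cen$start - margin)
      b2 <- stats::runif(1, cen$end + margin, L - margin)
      apply_internal_segment(k0, chrom, hom, b1, b2,
                             if (grepl("gain", category)) 1L else -1L, genome)
    },
    UPD = {
      q <- stats::runif(1) < 0.5
      apply_upd(k0, chrom,
                if (q) c(cen$end, L) else c(0, cen$start),
                hom)
    },
    arm_gain = ,
    arm_loss = {
      q <- stats::runif(1) < 0.5
      sign <- if (category == "arm_gain") 1L else -1L
      if (q) kar_edit(k0, chrom, hom, cen$end, L, sign)
      else kar_edit(k0, chrom, hom, 0, cen$start, sign)
    },
    whole_chrom_gain = apply_missegregation(k0, chrom, hom, 1L),
    whole_chrom_loss = apply_missegregation(k0, chrom, hom, -1L),
    focal_del = ,
    focal_dup = {
      len <- stats::runif(1, 5e5, 4e6)
      s <- stats::runif(1, margin, L - len - margin)
      apply_focal(k0, chrom, hom, c(s, s + len),
                  if (category == "focal_dup") 1L else -1L)
    },
    amplification = {
      q <- stats::runif(1) < 0.5
      len <- stats::runif(1, 1e6, 3e6)
      s <- if (q) stats::runif(1, 0.85 * L, 0.95 * L - len)
           else stats::runif(1, 0.05 * L, 0.15 * L)
      apply_bfb_amplification(k0, chrom, hom, c(s, s + len), 3, genome)
    },
    chromothripsis = {
      repeat {
        len <- stats::runif(1, 0.2 * L, 0.35 * L)
        s <- stats::runif(1, margin, L - len - margin)
        kk <- apply_chromothripsis(k0, chrom, hom, c(s, s + len), 24, 0.5)
        fr <- attr(kk, "fragments")
        r <- rle(fr$retained)
        ends <- cumsum(r$lengths)
        span <- fr$end[ends] - fr$start[ends - r$lengths + 1]
        if (length(r$lengths) - 1 >= osc_min && max(span) < 9e6) break
      }
      kk
    },
    stop("unknown category ", category)
  )
  list(karyotype = simplify_karyotype(as_karyotype(as.data.frame(k))),
       category = category, chrom = chrom, homolog = hom)
}
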
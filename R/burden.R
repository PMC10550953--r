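#' Per-sample SCNA burden summary
#'
#' Counts altered autosomal homologs (each parental homolog of each
#' autosome at most once, for a maximum of 44 on a 22-autosome genome),
#' subdividing by the most complex category present on the homolog with
#' precedence segmental > arm-level > UPD > local.
#'
#' @param events classified `ScnaEvent` data.frame for one sample.
#' @param genome a `genome_model`.
#' @param autosomes chromosomes that count (default all in the genome).
#' @return data.frame sample, total, local, upd, arm, segmental.
#' @export
compute_burden <- function(events, genome, autosomes = genome$chroms) {
  seg_cats <- c("terminal_gain", "terminal_loss", "paracentric_gain",
                "paracentric_loss", "pericentric_gain", "pericentric_loss",
                "chromothripsis", "amplification", "sloping")
  arm_cats <- c("arm_gain", "arm_loss", "whole_chrom_gain",
                "whole_chrom_loss")
  local_cats <- c("focal_del", "focal_dup")
  ev <- events[events$chrom %in% autosomes, , drop = FALSE]
  sample <- if (nrow(events)) events$sample[1] else NA_character_
  if (nrow(ev) == 0)
    return(data.frame(sample = sample, total = 0L, local = 0L, upd = 0L,
                      arm = 0L, segmental = 0L, stringsAsFactors = FALSE))
  key <- paste(ev$chrom, ev$homolog)
  cls <- ifelse(ev$category %in% seg_cats, 4L,
         ifelse(ev$category %in% arm_cats, 3L,
         ifelse(ev$category == "UPD", 2L,
         ifelse(ev$category %in% local_cats, 1L, 0L))))
  top <- tapply(cls, key, max)
  top <- top[top > 0]
  data.frame(sample = sample,
             total = length(top),
             local = sum(top == 1L), upd = sum(top == 2L),
             arm = sum(top == 3L), segmental = sum(top == 4L),
             stringsAsFactors = FALSE)
}

#' Allelic distribution of segmental SCNAs across a patient
#'
#' Per chromosome, across all of a patient's samples: chromosomes with
#' a single SCNA, multiple SCNAs confined to one parental homolog
#' (mono-allelic) or multiple SCNAs on both homologs (bi-allelic),
#' subdivided by whether the breakpoints occur in a single genome or in
#' multiple related genomes.
#'
#' @param events `ScnaEvent` rows from all samples of one patient (the
#'   `sample` column distinguishes genomes).
#' @param categories event categories that count (default: segmental
#'   classes).
#' @return data.frame chrom, pattern ("single"/"mono-allelic"/
#'   "bi-allelic"), scope ("single-genome"/"multi-genome"), n_events.
#' @export
allelic_distribution <- function(events,
                                 categories = c("terminal_gain",
                                                "terminal_loss",
                                                "paracentric_gain",
                                                "paracentric_loss",
                                                "pericentric_gain",
                                                "pericentric_loss",
                                                "chromothripsis",
                                                "amplification",
                                                "focal_del", "focal_dup")) {
  ev <- events[events$category %in% categories, , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(chrom = character(0), pattern = character(0),
                      scope = character(0), n_events = integer(0)))
  out <- lapply(unique(ev$chrom), function(cn) {
    e <- ev[ev$chrom == cn, ]
    # distinct events: collapse identical breakpoints across samples
    key <- paste(e$homolog, e$breakpoints, sign(e$copy_change))
    n_distinct <- length(unique(key))
    pattern <- if (n_distinct == 1) "single"
      else if (length(unique(e$homolog)) == 1) "mono-allelic"
      else "bi-allelic"
    scope <- if (length(unique(e$sample)) > 1) "multi-genome"
      else "single-genome"
    data.frame(chrom = cn, pattern = pattern, scope = scope,
               n_events = n_distinct, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome fraction at deleted, subclonal and duplicated states
#'
#' Evaluates the called allelic copy number on a fine grid and reports
#' the fraction of the germline genome (both homologs) at each state:
#' deletion (allelic CN 0), duplication (allelic CN >= 2, or >= 3 in
#' WGD samples), and subclonal loss/gain (non-integer states flagged by
#' the caller).  Categories are disjoint; fractions sum to <= 1.
#'
#' @param diagnostics segment diagnostics from [call_integer_cn()]
#'   (columns chrom, start, end, rawA, rawB, cnA, cnB).
#' @param wgd is the sample whole-genome duplicated?
#' @param grid_bp evaluation grid (default 1e5).
#' @param subclonal_threshold residual that makes a state subclonal
#'   (default 0.3).
#' @return named numeric: deletion, subclonal_loss, subclonal_gain,
#'   duplication.
#' @export
genome_fraction_states <- function(diagnostics, wgd = FALSE, grid_bp = 1e5,
                                   subclonal_threshold = 0.3) {
  dup_thr <- if (wgd) 3L else 2L
  n_units <- 0; counts <- c(deletion = 0, subclonal_loss = 0,
                            subclonal_gain = 0, duplication = 0)
  for (i in seq_len(nrow(diagnostics))) {
    n <- max(1L, round((diagnostics$end[i] - diagnostics$start[i]) / grid_bp))
    for (col in c("A", "B")) {
      raw <- diagnostics[[paste0("raw", col)]][i]
      cn <- diagnostics[[paste0("cn", col)]][i]
      sub <- abs(raw - cn) > subclonal_threshold
      n_units <- n_units + n
      if (sub) {
        if (raw < 1) counts["subclonal_loss"] <- counts["subclonal_loss"] + n
        else counts["subclonal_gain"] <- counts["subclonal_gain"] + n
      } else if (cn == 0) {
        counts["deletion"] <- counts["deletion"] + n
      } else if (cn >= dup_thr) {
        counts["duplication"] <- counts["duplication"] + n
      }
    }
  }
  counts / max(n_units, 1)
}

#' Compare SCNA burdens between groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests on every group
#' pair, with the rank-biserial effect size and the Hodges-Lehmann
#' shift confidence interval, plus Benjamini-Hochberg adjusted
#' p-values.  An optional 2x2 count table (e.g. gains vs losses by
#' group) is tested with a two-sided Fisher exact test.
#'
#' @param values numeric burden per sample.
#' @param groups group label per sample (>= 3 samples per group for a
#'   test; smaller groups yield NA with a reason).
#' @param counts optional 2x2 matrix for the Fisher test.
#' @return list with `tests` (data.frame group1, group2, n1, n2, p,
#'   effect, ci_lo, ci_hi, fdr, note) and `fisher` (data.frame p,
#'   odds_ratio, ci_lo, ci_hi or NULL).
#' @export
compare_groups <- function(values, groups, counts = NULL) {
  g <- unique(as.character(groups))
  if (length(g) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(g, 2)
  rows <- list()
  for (q in seq_len(ncol(pairs))) {
    g1 <- pairs[1, q]; g2 <- pairs[2, q]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    if (length(v1) < 3 || length(v2) < 3) {
      rows[[q]] <- data.frame(group1 = g1, group2 = g2,
                              n1 = length(v1), n2 = length(v2),
                              p = NA_real_, effect = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              note = "group too small (< 3)",
                              stringsAsFactors = FALSE)
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(v1, v2, conf.int = TRUE,
                                              exact = FALSE))
    u <- wt$statistic
    effect <- 1 - 2 * u / (length(v1) * length(v2))  # rank-biserial
    rows[[q]] <- data.frame(group1 = g1, group2 = g2,
                            n1 = length(v1), n2 = length(v2),
                            p = wt$p.value, effect = as.numeric(effect),
                            ci_lo = wt$conf.int[1], ci_hi = wt$conf.int[2],
                            note = "", stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  tests$fdr <- stats::p.adjust(tests$p, method = "BH")
  fisher <- NULL
  if (!is.null(counts)) {
    ft <- stats::fisher.test(counts)
    fisher <- data.frame(p = ft$p.value, odds_ratio = as.numeric(ft$estimate),
                         ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2])
  }
  list(tests = tests, fisher = fisher)
}
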
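#' Parental (haplotype-resolved) karyotype
#'
#' A karyotype is a data.frame tiling every chromosome with half-open
#' segments carrying non-negative integer copy numbers for each parental
#' homolog (`cnA`, `cnB`).  Ground-truth simulator output and inferred
#' calls share this representation.
#'
#' @param genome a `genome_model`.
#' @param cnA,cnB starting copy number per homolog (default diploid 1/1).
#' @return object of class `karyotype` (a data.frame with columns chrom,
#'   start, end, cnA, cnB).
#' @export
diploid_karyotype <- function(genome, cnA = 1L, cnB = 1L) {
  k <- data.frame(chrom = genome$chroms,
                  start = 0,
                  end = as.numeric(genome$lengths),
                  cnA = as.integer(cnA), cnB = as.integer(cnB),
                  stringsAsFactors = FALSE)
  class(k) <- c("karyotype", "data.frame")
  k
}

as_karyotype <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "cnA", "cnB") %in% names(df)))
  class(df) <- c("karyotype", "data.frame")
  rownames(df) <- NULL
  df
}

#' Validate a karyotype tiling
#'
#' Checks that segments tile each chromosome without gaps or overlaps and
#' that copy numbers are non-negative integers.
#'
#' @param k a `karyotype`.
#' @param genome optional `genome_model`; if given, tilings are checked
#'   against the chromosome lengths.
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_karyotype <- function(k, genome = NULL) {
  if (any(k$end <= k$start)) stop("empty or inverted segment")
  if (any(k$cnA < 0) || any(k$cnB < 0)) stop("negative copy number")
  if (any(k$cnA != round(k$cnA)) || any(k$cnB != round(k$cnB)))
    stop("non-integer copy number")
  for (cn in unique(k$chrom)) {
    s <- k[k$chrom == cn, ]
    s <- s[order(s$start), ]
    if (s$start[1] != 0) stop("tiling does not start at 0 on ", cn)
    if (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)]))
      stop("gap or overlap in tiling on ", cn)
    if (!is.null(genome) && abs(s$end[nrow(s)] - genome$lengths[[cn]]) > 0)
      stop("tiling does not reach chromosome end on ", cn)
  }
  invisible(TRUE)
}

#' Merge adjacent segments with identical copy-number state
#' @param k a `karyotype`.
#' @return simplified `karyotype`.
#' @export
simplify_karyotype <- function(k) {
  out <- lapply(unique(k$chrom), function(cn) {
    s <- k[k$chrom == cn, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1) {
      new_run <- c(TRUE, s$cnA[-1] != s$cnA[-nrow(s)] |
                         s$cnB[-1] != s$cnB[-nrow(s)])
      grp <- cumsum(new_run)
      s <- data.frame(chrom = cn,
                      start = tapply(s$start, grp, min),
                      end = tapply(s$end, grp, max),
                      cnA = s$cnA[new_run], cnB = s$cnB[new_run],
                      stringsAsFactors = FALSE)
    }
    s
  })
  as_karyotype(do.call(rbind, out))
}

# Split segments of one chromosome at the given positions (internal).
kar_split_at <- function(k, chrom, positions) {
  s <- k[k$chrom == chrom, , drop = FALSE]
  rest <- k[k$chrom != chrom, , drop = FALSE]
  positions <- sort(unique(positions))
  for (p in positions) {
    hit <- which(s$start < p & s$end > p)
    if (length(hit) == 1L) {
      left <- s[hit, ]; right <- s[hit, ]
      left$end <- p; right$start <- p
      s <- rbind(s[seq_len(nrow(s)) < hit, ], left, right,
                 s[seq_len(nrow(s)) > hit, ])
    }
  }
  as_karyotype(rbind(rest, s[order(s$start), ]))
}

# Add delta to one homolog over [start, end) (internal); negative results stop.
kar_edit <- function(k, chrom, homolog, start, end, delta) {
  stopifnot(homolog %in% c("A", "B"), end > start)
  k <- kar_split_at(k, chrom, c(start, end))
  col <- paste0("cn", homolog)
  sel <- k$chrom == chrom & k$start >= start & k$end <= end
  newcn <- k[[col]][sel] + as.integer(delta)
  if (any(newcn < 0)) stop("event would produce negative copy number")
  k[[col]][sel] <- newcn
  k
}

# Copy number of one homolog at single positions (internal).
kar_cn_at <- function(k, chrom, homolog, pos) {
  s <- k[k$chrom == chrom, , drop = FALSE]
  s <- s[order(s$start), , drop = FALSE]
  col <- paste0("cn", homolog)
  idx <- findInterval(pos, s$start)
  s[[col]][idx]
}

#' Per-bin copy number of a karyotype
#'
#' Evaluates allelic copy number on a fixed-width bin grid (by bin
#' midpoint; segment boundaries off the grid are rounded to the nearest
#' bin).
#'
#' @param k a `karyotype`.
#' @param genome a `genome_model`.
#' @param bin_width bin width in bp.
#' @return data.frame chrom, start, end, cnA, cnB, total.
#' @export
karyotype_bins <- function(k, genome, bin_width = genome$bin_width) {
  b <- genome_bins(genome, bin_width)
  mid <- (b$start + b$end) / 2
  b$cnA <- NA_integer_; b$cnB <- NA_integer_
  for (cn in unique(b$chrom)) {
    sel <- b$chrom == cn
    b$cnA[sel] <- kar_cn_at(k, cn, "A", mid[sel])
    b$cnB[sel] <- kar_cn_at(k, cn, "B", mid[sel])
  }
  b$total <- b$cnA + b$cnB
  b
}

#' Average ploidy (length-weighted mean total copy number)
#' @param k a `karyotype`.
#' @return numeric scalar.
#' @export
karyotype_ploidy <- function(k) {
  w <- k$end - k$start
  sum(w * (k$cnA + k$cnB)) / sum(w)
}
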
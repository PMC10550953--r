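#' Build a synthetic genome model
#'
#' A genome model holds chromosome lengths, centromere intervals and
#' heterozygous SNP positions, and is the coordinate frame for every
#' simulation and analysis step.  Coordinates are 0-based, half-open.
#' Het sites are drawn as a homogeneous Poisson process along each
#' chromosome at the requested density; typical short-read cohorts
#' yield about one usable heterozygous site per 3 kb, which is the
#' default.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   Default: four synthetic chromosomes (150/120/90/60 Mb), small enough
#'   that whole-pipeline simulations run in seconds.
#' @param centromere_frac position of the centromere midpoint as a fraction
#'   of chromosome length (recycled); the centromere interval spans 1 Mb
#'   around that midpoint.
#' @param het_density expected het sites per bp (default 1/3000).
#' @param bin_width width of coverage bins in bp (default 25000).
#' @param seed integer seed controlling het-site placement.
#' @return an object of class `genome_model`: list with `chroms`,
#'   `lengths`, `centromeres` (data.frame chrom/start/end), `het_sites`
#'   (named list of increasing positions), `bin_width`, `het_density`.
#' @examples
#' gm <- simulate_genome(c(chr1 = 5e7), seed = 1)
#' length(gm$het_sites$chr1)
#' @export
simulate_genome <- function(chrom_lengths = c(chr1 = 150e6, chr2 = 120e6,
                                              chr3 = 90e6, chr4 = 60e6),
                            centromere_frac = 0.4,
                            het_density = 1 / 3000,
                            bin_width = 25000,
                            seed = NULL) {
  if (length(chrom_lengths) < 1L) stop("need at least one chromosome")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (het_density < 0) stop("het_density must be non-negative")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (!is.null(seed)) set.seed(seed)
  centromere_frac <- rep_len(centromere_frac, length(chrom_lengths))
  cen_mid <- chrom_lengths * centromere_frac
  cen <- data.frame(chrom = names(chrom_lengths),
                    start = pmax(1, round(cen_mid - 5e5)),
                    end = pmin(chrom_lengths - 1, round(cen_mid + 5e5)),
                    row.names = NULL, stringsAsFactors = FALSE)
  het <- lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    n <- stats::rpois(1, L * het_density)
    sort(round(stats::runif(n, 0, L - 1)))
  })
  names(het) <- names(chrom_lengths)
  structure(list(chroms = names(chrom_lengths),
                 lengths = chrom_lengths,
                 centromeres = cen,
                 het_sites = het,
                 bin_width = bin_width,
                 het_density = het_density),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp,",
      sum(lengths(x$het_sites)), "het sites, bin width",
      x$bin_width, "bp\n")
  invisible(x)
}

#' Fixed-width bins over a genome
#'
#' The last bin of each chromosome is truncated at the chromosome end.
#'
#' @param genome a `genome_model`.
#' @param bin_width bin width in bp; defaults to the genome's.
#' @return data.frame with chrom, start, end (0-based half-open).
#' @export
genome_bins <- function(genome, bin_width = genome$bin_width) {
  out <- lapply(genome$chroms, function(cn) {
    L <- genome$lengths[[cn]]
    s <- seq(0, L - 1, by = bin_width)
    data.frame(chrom = cn, start = s, end = pmin(s + bin_width, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chromosome arms of a genome model
#'
#' @param genome a `genome_model`.
#' @return data.frame chrom, arm ("p"/"q"), start, end; the p arm runs from
#'   the telomere to the centromere start, the q arm from the centromere end
#'   to the other telomere.
#' @export
genome_arms <- function(genome) {
  cen <- genome$centromeres
  do.call(rbind, lapply(seq_len(nrow(cen)), function(i) {
    cn <- cen$chrom[i]
    data.frame(chrom = cn, arm = c("p", "q"),
               start = c(0, cen$end[i]),
               end = c(cen$start[i], genome$lengths[[cn]]),
               stringsAsFactors = FALSE)
  }))
}
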
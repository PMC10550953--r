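#' Rendering configuration for simulated sequencing observations
#'
#' Controls how ground-truth karyotypes are turned into binned read
#' counts and per-site allelic depths that emulate multi-sample bulk
#' FFPE whole-genome sequencing (about 20x, variable purity) and
#' low-pass single cells.
#'
#' @param mean_bin_count expected read count of a copy-neutral bin
#'   (default 3000, roughly 20x coverage in 25 kb bins with short reads).
#' @param site_depth expected total allelic depth per het site
#'   (default 20).
#' @param nb_size negative-binomial size (inverse overdispersion) for
#'   bin counts; smaller is noisier (default 60, FFPE-like).
#' @param ad_rho beta-binomial intra-class correlation for allelic
#'   depths (default 0.01).
#' @param bias_scale log-scale amplitude of the recurrent (shared)
#'   FFPE coverage bias (default 0.1).
#' @param gc_strength amplitude of the GC-dependent coverage effect
#'   (default 1).
#' @param switch_rate statistical-phasing switch-error rate per bp
#'   (default 1/250000, i.e. about one switch per 250 kb).
#' @param n_panel number of germline (diploid) reference-panel samples
#'   rendered alongside the tumor samples (default 4).
#' @return list of class `render_config`.
#' @export
render_config <- function(mean_bin_count = 3000, site_depth = 20,
                          nb_size = 60, ad_rho = 0.01,
                          bias_scale = 0.1, gc_strength = 1,
                          switch_rate = 1 / 250000, n_panel = 4) {
  structure(list(mean_bin_count = mean_bin_count, site_depth = site_depth,
                 nb_size = nb_size, ad_rho = ad_rho,
                 bias_scale = bias_scale, gc_strength = gc_strength,
                 switch_rate = switch_rate, n_panel = n_panel),
            class = "render_config")
}

# Smooth random field on [0, L): sum of low-frequency sinusoids (internal).
smooth_field <- function(pos, L, n_harmonics = 5, scale = 1) {
  f <- numeric(length(pos))
  for (k in seq_len(n_harmonics)) {
    f <- f + stats::rnorm(1, 0, 1 / k) * sin(2 * pi * k * pos / L +
                                             stats::runif(1, 0, 2 * pi))
  }
  scale * f / sqrt(sum(1 / (seq_len(n_harmonics))^2))
}

#' Shared coverage-bias profile for one patient
#'
#' Builds the per-bin GC content and the recurrent multiplicative
#' coverage bias shared by all samples of a patient (the signal that
#' reference-panel normalization is meant to remove).
#'
#' @param genome a `genome_model`.
#' @param cfg a `render_config`.
#' @param bin_width bin width in bp.
#' @return data.frame chrom, start, end, gc, bias.
#' @export
make_bias_profile <- function(genome, cfg = render_config(),
                              bin_width = genome$bin_width) {
  b <- genome_bins(genome, bin_width)
  gc <- numeric(nrow(b)); bias <- numeric(nrow(b))
  for (cn in genome$chroms) {
    sel <- b$chrom == cn
    mid <- (b$start[sel] + b$end[sel]) / 2
    L <- genome$lengths[[cn]]
    # GC content varies at the tens-of-kb scale (isochore-like noise),
    # far below the scale of copy-number segments
    z <- stats::filter(stats::rnorm(sum(sel) + 8), rep(1 / 9, 9),
                       sides = 2)
    z <- z[!is.na(z)][seq_len(sum(sel))]
    gc[sel] <- 0.45 + 0.05 * z / stats::sd(z) * 0.8
    bias[sel] <- exp(smooth_field(mid, L, 8, cfg$bias_scale))
  }
  b$gc <- pmin(0.7, pmax(0.25, gc))
  # GC effect folded into the shared bias (same dependence in all samples)
  b$bias <- bias * exp(cfg$gc_strength *
                       (-2 * (b$gc - 0.45)^2 + 0.5 * (b$gc - 0.45)))
  b
}

# Poisson switch process: reported orientation per het site (internal).
draw_switch_orientation <- function(genome, rate) {
  ori <- lapply(genome$chroms, function(cn) {
    pos <- genome$het_sites[[cn]]
    if (length(pos) == 0) return(integer(0))
    L <- genome$lengths[[cn]]
    n_sw <- stats::rpois(1, rate * L)
    sw <- sort(stats::runif(n_sw, 0, L))
    flips <- findInterval(pos, sw)
    ifelse(flips %% 2 == 0, 1L, -1L)
  })
  names(ori) <- genome$chroms
  ori
}

# Mixture expected allelic CN per position set (internal).
mixture_cn <- function(karyotypes, fractions, chrom, pos) {
  f_norm <- 1 - sum(fractions)
  cnA <- rep(f_norm, length(pos)); cnB <- rep(f_norm, length(pos))
  for (i in seq_along(karyotypes)) {
    cnA <- cnA + fractions[i] * kar_cn_at(karyotypes[[i]], chrom, "A", pos)
    cnB <- cnB + fractions[i] * kar_cn_at(karyotypes[[i]], chrom, "B", pos)
  }
  list(cnA = cnA, cnB = cnB)
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  ab <- (1 - rho) / rho
  p <- stats::rbeta(n, pmax(ab * prob, 1e-6), pmax(ab * (1 - prob), 1e-6))
  stats::rbinom(n, size, p)
}

#' Render one bulk sample from a clone mixture
#'
#' Expected bin depth is proportional to the purity-weighted total copy
#' number (clone mixture plus diploid normal), modulated by the shared
#' bias profile, with negative-binomial counts.  Per-het-site haplotype
#' depths are beta-binomial around the mixture allelic fraction, and
#' reported under the (possibly switch-errored) orientation.
#'
#' @param karyotypes list of clone `karyotype`s in the sample.
#' @param fractions clone fractions (sum <= 1; remainder is diploid
#'   normal). A single clone at fraction p is a sample of purity p.
#' @param genome a `genome_model`.
#' @param cfg a `render_config`.
#' @param bias bias profile from [make_bias_profile()] (required so all
#'   samples of a patient share it).
#' @param orientation per-chromosome list of reported phase orientation
#'   (+1/-1 per het site); NULL means perfect phasing.
#' @return list with `counts` (per-bin counts aligned to `bias` rows)
#'   and `allelic` (data.frame chrom, pos, depthA, depthB as reported).
#' @export
render_bulk <- function(karyotypes, fractions, genome, cfg = render_config(),
                        bias = make_bias_profile(genome, cfg),
                        orientation = NULL) {
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-9)
    stop("fractions must be in [0,1] and sum to <= 1")
  if (inherits(karyotypes, "karyotype")) karyotypes <- list(karyotypes)
  b <- bias
  mid <- (b$start + b$end) / 2
  tot <- numeric(nrow(b))
  for (cn in genome$chroms) {
    sel <- b$chrom == cn
    cns <- mixture_cn(karyotypes, fractions, cn, mid[sel])
    tot[sel] <- cns$cnA + cns$cnB
  }
  mu <- cfg$mean_bin_count * (tot / 2) * b$bias *
    (b$end - b$start) / genome$bin_width
  counts <- stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size)
  allelic <- lapply(genome$chroms, function(cn) {
    pos <- genome$het_sites[[cn]]
    if (length(pos) == 0)
      return(data.frame(chrom = character(0), pos = numeric(0),
                        depthA = integer(0), depthB = integer(0)))
    cns <- mixture_cn(karyotypes, fractions, cn, pos)
    tot_s <- cns$cnA + cns$cnB
    bin_idx <- findInterval(pos, b$start[b$chrom == cn])
    site_bias <- b$bias[b$chrom == cn][bin_idx]
    n <- stats::rnbinom(length(pos), mu = cfg$site_depth * tot_s / 2 * site_bias,
                        size = cfg$nb_size)
    fA <- ifelse(tot_s > 0, cns$cnA / tot_s, 0.5)
    dA <- rbetabinom(length(pos), n, fA, cfg$ad_rho)
    dB <- n - dA
    if (!is.null(orientation)) {
      o <- orientation[[cn]]
      flip <- o == -1L
      tmp <- dA[flip]; dA[flip] <- dB[flip]; dB[flip] <- tmp
    }
    data.frame(chrom = cn, pos = pos, depthA = dA, depthB = dB,
               stringsAsFactors = FALSE)
  })
  list(counts = counts, allelic = do.call(rbind, allelic))
}

#' Render a full multi-sample patient
#'
#' Renders every requested leaf of a clone tree plus a germline
#' reference panel, all sharing one bias profile and one
#' statistical-phasing switch process (phasing is per patient).
#'
#' @param tree a `clone_tree`.
#' @param samples leaf labels to render (default all leaves).
#' @param purities tumor-cell fraction per sample (recycled).
#' @param cfg a `render_config`.
#' @param genome defaults to the tree's genome.
#' @return list of class `patient_obs` with `bins` (chrom/start/end/gc),
#'   `counts` (bins x samples matrix), `panel_counts` (bins x panel),
#'   `allelic` (`sites` data.frame plus `depthA`/`depthB` site x sample
#'   matrices, reported orientation), `orientation` (true orientation of
#'   the reported phase, +1 correct / -1 flipped), `purities`, `samples`.
#' @export
render_patient <- function(tree, samples = tree_leaves(tree),
                           purities = 0.6, cfg = render_config(),
                           genome = tree$genome) {
  purities <- rep_len(purities, length(samples))
  bias <- make_bias_profile(genome, cfg)
  ori <- draw_switch_orientation(genome, cfg$switch_rate)
  counts <- matrix(0L, nrow(bias), length(samples),
                   dimnames = list(NULL, samples))
  dA <- NULL; dB <- NULL; sites <- NULL
  for (i in seq_along(samples)) {
    k <- tree_karyotype(tree, samples[i])
    r <- render_bulk(list(k), purities[i], genome, cfg, bias, ori)
    counts[, i] <- r$counts
    if (is.null(sites)) {
      sites <- r$allelic[, c("chrom", "pos")]
      dA <- matrix(0L, nrow(sites), length(samples),
                   dimnames = list(NULL, samples))
      dB <- dA
    }
    dA[, i] <- r$allelic$depthA
    dB[, i] <- r$allelic$depthB
  }
  normal <- diploid_karyotype(genome)
  panel <- matrix(0L, nrow(bias), cfg$n_panel)
  colnames(panel) <- paste0("germline", seq_len(cfg$n_panel))
  for (j in seq_len(cfg$n_panel))
    panel[, j] <- render_bulk(list(normal), 1, genome, cfg, bias, ori)$counts
  structure(list(bins = bias[, c("chrom", "start", "end", "gc")],
                 counts = counts, panel_counts = panel,
                 allelic = list(sites = sites, depthA = dA, depthB = dB),
                 orientation = ori,
                 purities = stats::setNames(purities, samples),
                 samples = samples, genome = genome, cfg = cfg,
                 tree = tree),
            class = "patient_obs")
}

#' Render a population with progressive terminal erosion (sloping)
#'
#' Emulates a cell population whose subclones carry progressively more
#' proximal terminal losses on one homolog, so the population-average
#' copy number attenuates gradually ("slopes") toward the chromosome
#' end instead of stepping.
#'
#' @param base a `karyotype` shared by all subclones before erosion.
#' @param chrom,homolog eroded homolog.
#' @param boundaries vector of terminal-loss breakpoints (bp), one per
#'   subclone; loss extends from each boundary to the q telomere.
#' @param fractions subclone fractions (sum <= 1; remainder diploid
#'   normal).
#' @param genome a `genome_model`.
#' @param cfg a `render_config`.
#' @param bias optional shared bias profile.
#' @return as [render_bulk()].
#' @export
render_sloping_population <- function(base, chrom, homolog, boundaries,
                                      fractions, genome,
                                      cfg = render_config(),
                                      bias = make_bias_profile(genome, cfg)) {
  stopifnot(length(boundaries) == length(fractions))
  ks <- lapply(boundaries, function(bp)
    apply_terminal(base, chrom, homolog, bp, -1L, genome))
  render_bulk(ks, fractions, genome, cfg, bias)
}

#' Render a low-pass single cell
#'
#' Sparse 10 kb counts with long-range whole-genome-amplification-style
#' multiplicative noise, and mostly 0/1 allelic depths per het site.
#'
#' @param k the cell's `karyotype`.
#' @param genome a `genome_model`.
#' @param depth mean reads per 10 kb bin at the cell's average copy
#'   number (default 100, about 1x with short reads).
#' @param bin_width depth bin width (default 10000).
#' @param wga_scale log-scale amplitude of the amplification noise
#'   (default 0.25).
#' @param site_depth mean allelic depth per het site (default 0.3).
#' @param nb_size negative-binomial size for bin counts (default 8).
#' @param orientation reported phase orientation (as in [render_bulk()]).
#' @return list with `bins` (chrom,start,end,count) and `allelic`
#'   (chrom,pos,depthA,depthB).
#' @export
render_single_cell <- function(k, genome, depth = 100, bin_width = 10000,
                               wga_scale = 0.25, site_depth = 0.3,
                               nb_size = 8, orientation = NULL) {
  b <- genome_bins(genome, bin_width)
  mid <- (b$start + b$end) / 2
  cnA <- numeric(nrow(b)); cnB <- numeric(nrow(b))
  wga <- numeric(nrow(b))
  for (cn in genome$chroms) {
    sel <- b$chrom == cn
    cnA[sel] <- kar_cn_at(k, cn, "A", mid[sel])
    cnB[sel] <- kar_cn_at(k, cn, "B", mid[sel])
    wga[sel] <- smooth_field(mid[sel], genome$lengths[[cn]], 12, wga_scale)
  }
  tot <- cnA + cnB
  mu <- depth * tot / mean(tot) * exp(wga) * (b$end - b$start) / bin_width
  b$count <- stats::rnbinom(length(mu), mu = mu, size = nb_size)
  allelic <- lapply(genome$chroms, function(cn) {
    pos <- genome$het_sites[[cn]]
    a <- kar_cn_at(k, cn, "A", pos); bb <- kar_cn_at(k, cn, "B", pos)
    t <- a + bb
    n <- stats::rpois(length(pos), site_depth * ifelse(t > 0, t / 2, 0.01))
    fA <- ifelse(t > 0, a / t, 0.5)
    dA <- stats::rbinom(length(pos), n, fA)
    dB <- n - dA
    if (!is.null(orientation)) {
      o <- orientation[[cn]]
      flip <- o == -1L
      tmp <- dA[flip]; dA[flip] <- dB[flip]; dB[flip] <- tmp
    }
    data.frame(chrom = cn, pos = pos, depthA = dA, depthB = dB,
               stringsAsFactors = FALSE)
  })
  list(bins = b, allelic = do.call(rbind, allelic))
}
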
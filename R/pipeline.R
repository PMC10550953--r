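#' Shared-breakpoint incidence matrix from per-sample events
#'
#' Clusters classified events across samples (same chromosome and
#' homolog, relation "shared" under the breakpoint-match tolerance)
#' into characters for phylogeny construction.  Character support is
#' the number of breakpoints backing the cluster.
#'
#' @param events combined `ScnaEvent` data.frame with a `sample`
#'   column.
#' @param samples sample labels (columns may carry no event).
#' @param tol breakpoint match tolerance (default 1e5).
#' @return list with `incidence` (samples x characters), `support`,
#'   `chrom` per character.
#' @export
event_incidence <- function(events, samples = unique(events$sample),
                            tol = 1e5) {
  ev <- events[!is.na(events$sample) & events$breakpoints != "", ,
               drop = FALSE]
  n <- nrow(ev)
  if (n == 0)
    return(list(incidence = matrix(0L, length(samples), 0,
                                   dimnames = list(samples, NULL)),
                support = numeric(0), chrom = character(0)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (ev$chrom[i] != ev$chrom[j] || ev$homolog[i] != ev$homolog[j]) next
    if (ev$sample[i] == ev$sample[j]) next
    if (classify_event_relation(ev[i, ], ev[j, ], tol) == "shared") {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  clusters <- split(seq_len(n), root)
  inc <- matrix(0L, length(samples), length(clusters),
                dimnames = list(samples, paste0("chr_", seq_along(clusters))))
  support <- numeric(length(clusters))
  chrom <- character(length(clusters))
  for (q in seq_along(clusters)) {
    ix <- clusters[[q]]
    inc[unique(ev$sample[ix]), q] <- 1L
    support[q] <- max(lengths(lapply(ix, function(i)
      event_breakpoints(ev[i, ]))))
    chrom[q] <- ev$chrom[ix[1]]
    colnames(inc)[q] <- paste0(ev$chrom[ix[1]], "_", ev$homolog[ix[1]], "_",
                               round(event_breakpoints(ev[ix[1], ])[1]))
  }
  list(incidence = inc, support = support, chrom = chrom)
}

#' Run the full simulation-to-report pipeline
#'
#' Simulates a patient (clone tree + rendered bulk observations),
#' corrects phasing switch errors, calls haplotype-specific copy
#' number per sample, classifies SCNAs, reconstructs the sample
#' phylogeny from shared breakpoints, places WGD, and summarizes
#' burdens.  Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param n_leaves samples per patient (default 4).
#' @param purities per-sample purity (default 0.6).
#' @param genome optional `genome_model` (default: the 4-chromosome
#'   test genome).
#' @param cfg a `render_config`.
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV/JSON with a manifest.
#' @param ... passed to [simulate_clone_tree()].
#' @return list with `tree`, `obs`, `corrected`, `calls` (per sample),
#'   `events`, `sample_tree`, `wgd_flags`, `burdens`.
#' @export
run_pipeline <- function(seed = 1, n_leaves = 4, purities = 0.6,
                         genome = NULL, cfg = render_config(),
                         out_dir = NULL, ...) {
  set.seed(seed)
  if (is.null(genome)) genome <- simulate_genome(seed = seed)
  tree <- simulate_clone_tree(genome, n_leaves = n_leaves, ...)
  obs <- render_patient(tree, purities = purities, cfg = cfg)
  corrected <- correct_switch_errors(obs$allelic)
  calls <- list(); events <- list(); wgd_flags <- logical(0)
  for (s in obs$samples) {
    cl <- call_sample_cn(obs, s, corrected$allelic)
    calls[[s]] <- cl
    if (!is.null(cl$call)) {
      ev <- classify_karyotype(cl$call$karyotype, genome, sample = s)
      events[[s]] <- ev
      wgd_flags[s] <- infer_wgd_bulk(cl$call$karyotype)
    } else {
      wgd_flags[s] <- FALSE
    }
  }
  events_all <- do.call(rbind, events)
  inc <- event_incidence(events_all, samples = obs$samples)
  stree <- if (ncol(inc$incidence) > 0)
    build_tree(inc$incidence, inc$support, inc$chrom) else NULL
  if (!is.null(stree)) stree <- assign_wgd_to_branches(stree, wgd_flags)
  burdens <- do.call(rbind, lapply(events, compute_burden, genome = genome))
  result <- list(tree = tree, obs = obs, corrected = corrected,
                 calls = calls, events = events_all, sample_tree = stree,
                 wgd_flags = wgd_flags, burdens = burdens, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}
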
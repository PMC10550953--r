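#' Write binned depth, allelic depths and segment calls as plain text
#'
#' Standard TSV dialects: binned depth (chrom, start, end, sample,
#' count), allelic depths (chrom, pos, sample, depthA, depthB), and
#' SEG-like segment calls (sample, chrom, start, end, cnA, cnB,
#' subclonal).
#'
#' @param obs a `patient_obs`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_depth_tsv <- function(obs, path) {
  rows <- lapply(obs$samples, function(s)
    data.frame(obs$bins[, c("chrom", "start", "end")], sample = s,
               count = obs$counts[, s]))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @param allelic allelic list (sites + depthA/depthB matrices).
#' @export
write_allelic_tsv <- function(allelic, path) {
  dA <- as.matrix(allelic$depthA); dB <- as.matrix(allelic$depthB)
  samples <- colnames(dA)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(dA)))
  rows <- lapply(seq_along(samples), function(j)
    data.frame(allelic$sites, sample = samples[j],
               depthA = dA[, j], depthB = dB[, j]))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @param calls named list of per-sample call results (from
#'   [call_sample_cn()]).
#' @export
write_seg_tsv <- function(calls, path) {
  rows <- lapply(names(calls), function(s) {
    d <- calls[[s]]$call
    if (is.null(d)) return(NULL)
    data.frame(sample = s, d$diagnostics[, c("chrom", "start", "end",
                                             "cnA", "cnB", "subclonal")])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every pipeline stage output with a manifest
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_depth_tsv(result$obs, p("depth.tsv"))
  write_allelic_tsv(result$corrected$allelic, p("allelic_corrected.tsv"))
  write_seg_tsv(result$calls, p("segments.seg.tsv"))
  if (!is.null(result$events))
    utils::write.table(result$events, p("events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(result$sample_tree))
    writeLines(sample_tree_newick(result$sample_tree), p("tree.nwk"))
  writeLines(tree_newick(result$tree), p("true_tree.nwk"))
  if (!is.null(result$burdens))
    utils::write.table(result$burdens, p("burdens.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  sidecar <- list(seed = result$seed,
                  samples = result$obs$samples,
                  purities = as.list(result$obs$purities),
                  wgd_flags = as.list(result$wgd_flags))
  jsonlite::write_json(sidecar, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(p("manifest.json"))
}
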
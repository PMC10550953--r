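#' Breakpoints of a classified SCNA event
#'
#' @param event one `ScnaEvent` row.
#' @return numeric vector of breakpoint positions (bp), possibly empty.
#' @export
event_breakpoints <- function(event) {
  s <- event$breakpoints
  if (is.na(s) || s == "") return(numeric(0))
  as.numeric(strsplit(s, ",")[[1]])
}

#' Match the breakpoints of two SCNA events
#'
#' Breakpoints on the same chromosome and homolog within `tol` of each
#' other are identical when associated with the same type of
#' copy-number change (gain vs loss) and complementary when associated
#' with opposite changes; everything else (including any pair on
#' different homologs) is distinct.
#'
#' @param eA,eB single `ScnaEvent` rows.
#' @param tol matching tolerance in bp (default 1e5, absorbing
#'   segmentation inaccuracy).
#' @return list with `relation` ("identical"/"complementary"/
#'   "distinct") and `distance` (bp between the closest breakpoint
#'   pair, NA if none).
#' @export
match_breakpoints <- function(eA, eB, tol = 1e5) {
  if (eA$chrom != eB$chrom || eA$homolog != eB$homolog)
    return(list(relation = "distinct", distance = NA_real_))
  bA <- event_breakpoints(eA); bB <- event_breakpoints(eB)
  if (length(bA) == 0 || length(bB) == 0)
    return(list(relation = "distinct", distance = NA_real_))
  d <- abs(outer(bA, bB, "-"))
  dmin <- min(d)
  if (dmin > tol) return(list(relation = "distinct", distance = dmin))
  same_dir <- sign(eA$copy_change) == sign(eB$copy_change)
  list(relation = if (same_dir) "identical" else "complementary",
       distance = dmin)
}

#' Relation between two SCNA events on the same homolog
#'
#' Events are `shared` when every breakpoint of one has an identical
#' match in the other (and vice versa), `branching` when only a proper
#' subset matches or when breakpoints are complementary (reciprocal
#' daughters of a single bridge break), and `unrelated` otherwise.
#'
#' @inheritParams match_breakpoints
#' @return "shared", "branching" or "unrelated".
#' @export
classify_event_relation <- function(eA, eB, tol = 1e5) {
  if (eA$chrom != eB$chrom || eA$homolog != eB$homolog) return("unrelated")
  bA <- event_breakpoints(eA); bB <- event_breakpoints(eB)
  if (length(bA) == 0 || length(bB) == 0) return("unrelated")
  same_dir <- sign(eA$copy_change) == sign(eB$copy_change)
  d <- abs(outer(bA, bB, "-"))
  # greedy one-to-one matching of closest pairs within tolerance
  n_match <- 0L
  while (length(d) && min(d) <= tol) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    n_match <- n_match + 1L
    d <- d[-ij[1], -ij[2], drop = FALSE]
  }
  if (n_match == 0L) return("unrelated")
  if (same_dir && n_match == length(bA) && n_match == length(bB))
    return("shared")
  "branching"
}

#' Build a sample phylogeny from shared-breakpoint characters
#'
#' Greedy perfect-phylogeny construction on a binary incidence matrix
#' of shared SCNA breakpoints.  Characters are processed in order of
#' decreasing support (number of breakpoints backing the character);
#' a character incompatible with the already-accepted set (its carrier
#' set neither nests within nor is disjoint from an accepted carrier
#' set) is dropped and logged, never silently discarded.  The root is
#' the germline (all-zero character state); branch length is the
#' number of altered chromosomes assigned to the branch.
#'
#' @param incidence samples x characters binary matrix (rownames =
#'   sample labels).
#' @param support numeric vector of per-character support (default:
#'   1 per character).
#' @param chrom optional character vector giving the chromosome of each
#'   character (used for branch lengths); default one pseudo-chromosome
#'   per character.
#' @return object of class `sample_tree`: list with `nodes` (id,
#'   parent, label, is_leaf), `clades` (leaf labels per node),
#'   `branch_characters` (character names per node's incoming branch),
#'   `branch_length` (altered-chromosome count per node), `conflicts`
#'   (data.frame of dropped characters), `samples`.
#' @export
build_tree <- function(incidence, support = NULL, chrom = NULL) {
  incidence <- as.matrix(incidence)
  samples <- rownames(incidence)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(incidence)))
  if (nrow(incidence) < 2) stop("need >= 2 samples")
  chars <- colnames(incidence)
  if (is.null(chars)) chars <- paste0("c", seq_len(ncol(incidence)))
  if (is.null(support)) support <- rep(1, length(chars))
  if (is.null(chrom)) chrom <- chars
  carriers <- lapply(seq_len(ncol(incidence)),
                     function(j) unname(which(incidence[, j] > 0)))
  ord <- order(-support, -lengths(carriers))
  accepted <- integer(0)
  conflicts <- list()
  compatible <- function(s, t) {
    i <- length(intersect(s, t))
    i == 0 || i == length(s) || i == length(t)
  }
  for (j in ord) {
    s <- carriers[[j]]
    if (length(s) == 0) next
    if (all(vapply(accepted, function(q) compatible(s, carriers[[q]]), TRUE))) {
      accepted <- c(accepted, j)
    } else {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        character = chars[j], support = support[j],
        carriers = paste(samples[s], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  # laminar family: unique accepted carrier sets + singletons (leaves)
  keysets <- unique(lapply(accepted, function(j) sort(carriers[[j]])))
  singles <- lapply(seq_along(samples), function(i) i)
  for (s in singles)
    if (!any(vapply(keysets, identical, TRUE, y = s)))
      keysets <- c(keysets, list(s))
  sizes <- lengths(keysets)
  ordset <- order(-sizes)
  keysets <- keysets[ordset]
  n_nodes <- length(keysets) + 1L            # +1 for germline root
  parent <- rep(1L, n_nodes)                 # default: attach to root
  parent[1] <- NA_integer_
  for (i in seq_along(keysets)) {
    s <- keysets[[i]]
    # parent = smallest strictly-containing earlier set
    best <- NA_integer_; best_size <- Inf
    for (q in seq_along(keysets)) {
      t <- keysets[[q]]
      if (q != i && length(t) > length(s) && all(s %in% t) &&
          length(t) < best_size) {
        best <- q; best_size <- length(t)
      }
    }
    parent[i + 1L] <- if (is.na(best)) 1L else best + 1L
  }
  is_leaf <- c(FALSE, sizes == 1L)
  label <- c("germline",
             vapply(keysets, function(s)
               if (length(s) == 1L) samples[s]
               else paste(samples[s], collapse = "+"), ""))
  clades <- c(list(samples), lapply(keysets, function(s) samples[s]))
  branch_chars <- vector("list", n_nodes)
  branch_len <- numeric(n_nodes)
  for (j in accepted) {
    s <- sort(carriers[[j]])
    node <- which(vapply(keysets, identical, TRUE, y = s)) + 1L
    branch_chars[[node]] <- c(branch_chars[[node]], chars[j])
  }
  for (i in seq_len(n_nodes))
    branch_len[i] <- length(unique(chrom[match(branch_chars[[i]], chars)]))
  structure(list(nodes = data.frame(id = seq_len(n_nodes), parent = parent,
                                    label = label, is_leaf = is_leaf,
                                    stringsAsFactors = FALSE),
                 clades = clades, branch_characters = branch_chars,
                 branch_length = branch_len,
                 conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                             else data.frame(character = character(0),
                                             support = numeric(0),
                                             carriers = character(0)),
                 samples = samples),
            class = "sample_tree")
}

#' Newick export of a sample tree (germline attached as outgroup leaf)
#' @param tree a `sample_tree` (or `clone_tree`).
#' @return Newick string.
#' @export
sample_tree_newick <- function(tree) {
  if (inherits(tree, "clone_tree")) {
    nd <- tree$nodes
    rec <- function(id) {
      kids <- nd$id[!is.na(nd$parent) & nd$parent == id]
      if (length(kids) == 0) return(nd$label[id])
      inner <- paste(vapply(kids, rec, ""), collapse = ",")
      if (length(kids) == 1) inner else paste0("(", inner, ")")
    }
    return(paste0("(", rec(1L), ",germline);"))
  }
  nd <- tree$nodes
  rec <- function(id) {
    kids <- nd$id[!is.na(nd$parent) & nd$parent == id]
    if (length(kids) == 0) return(nd$label[id])
    inner <- paste(vapply(kids, rec, ""), collapse = ",")
    if (length(kids) == 1) inner else paste0("(", inner, ")")
  }
  kids <- nd$id[!is.na(nd$parent) & nd$parent == 1L]
  inner <- paste(vapply(kids, rec, ""), collapse = ",")
  paste0("(", if (length(kids) > 1) paste0("(", inner, ")") else inner,
         ",germline);")
}

#' Time an SCNA relative to duplication
#'
#' Segmental SCNAs with more than one copy difference across their
#' changepoints must predate the duplication (the change was doubled);
#' single-copy changes postdate it.  Whole-chromosome or arm-level
#' states in WGD samples follow the odd/even rules: a final copy
#' number of 1 implies duplication followed by loss (post-WGD); an odd
#' state of 3 or more implies duplication to the nearest even state
#' followed by a single-copy gain or loss (post-WGD); an even state
#' other than 2 implies a pre-WGD change that was doubled.
#'
#' @param event one `ScnaEvent` row.
#' @param wgd does the sample's lineage carry a WGD?
#' @param final_cn final allelic copy number of the altered chromosome
#'   or arm (used for whole-chromosome/arm events).
#' @return "pre-WGD", "post-WGD" or NA.
#' @export
time_scna_vs_wgd <- function(event, wgd, final_cn = NULL) {
  if (!isTRUE(wgd)) return(NA_character_)
  whole <- event$category %in% c("whole_chrom_gain", "whole_chrom_loss",
                                 "arm_gain", "arm_loss")
  if (whole && !is.null(final_cn)) {
    if (final_cn == 1) return("post-WGD")        # duplicated then lost
    if (final_cn %% 2 == 1 && final_cn >= 3) return("post-WGD")
    if (final_cn %% 2 == 0 && final_cn != 2) return("pre-WGD")
    return(NA_character_)
  }
  dc <- abs(event$copy_change)
  if (dc >= 2) return("pre-WGD")
  if (dc == 1) return("post-WGD")
  NA_character_
}

#' Place WGD events on tree branches
#'
#' Each maximal clade whose leaves are all WGD-positive receives one
#' WGD event on its stem branch; disjoint WGD clades receive
#' independent events.  A WGD pattern that is not a union of clades is
#' impossible under this placement, so each maximal all-WGD clade is
#' still placed and the placements logged.
#'
#' @param tree a `sample_tree`.
#' @param wgd_flags named logical vector (names = sample labels).
#' @return the tree with `wgd_branch` (logical per node: WGD on the
#'   incoming branch) and `wgd_placements` (list of leaf sets).
#' @export
assign_wgd_to_branches <- function(tree, wgd_flags) {
  nd <- tree$nodes
  wgd_branch <- rep(FALSE, nrow(nd))
  placements <- list()
  pos <- names(wgd_flags)[wgd_flags]
  if (length(pos) > 0) {
    # candidate nodes whose clade is entirely WGD-positive
    ok <- vapply(seq_len(nrow(nd)), function(i)
      length(tree$clades[[i]]) > 0 && all(tree$clades[[i]] %in% pos), TRUE)
    ok[1] <- FALSE  # the germline root never carries a WGD
    # maximal: parent not ok
    for (i in which(ok)) {
      p <- nd$parent[i]
      if (is.na(p) || !ok[p]) {
        wgd_branch[i] <- TRUE
        placements[[length(placements) + 1L]] <- tree$clades[[i]]
      }
    }
  }
  tree$wgd_branch <- wgd_branch
  tree$wgd_placements <- placements
  tree
}

#' Pairwise somatic-SNV similarity between samples
#'
#' A variant is present in a sample when it has at least `min_support`
#' supporting reads; similarity of A to B is the fraction of A's
#' variants shared with B (the asymmetric pair is reported as a full
#' matrix).
#'
#' @param support sites x samples matrix of variant-supporting read
#'   counts.
#' @param min_support presence threshold (default 3).
#' @return list with `similarity` (samples x samples matrix,
#'   `similarity[a, b]` = |shared| / |variants of a|) and
#'   `empty_samples` (labels with zero variants, similarity 0).
#' @export
snv_similarity <- function(support, min_support = 3) {
  support <- as.matrix(support)
  if (ncol(support) < 2) stop("need >= 2 samples")
  pres <- support >= min_support
  n <- colSums(pres)
  samples <- colnames(pres)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(pres)))
  sim <- matrix(0, ncol(pres), ncol(pres),
                dimnames = list(samples, samples))
  for (a in seq_len(ncol(pres))) {
    for (b in seq_len(ncol(pres))) {
      shared <- sum(pres[, a] & pres[, b])
      sim[a, b] <- if (n[a] > 0) shared / n[a] else 0
    }
  }
  list(similarity = sim, empty_samples = samples[n == 0])
}
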
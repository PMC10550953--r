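#' Simulate a ground-truth clone evolution tree
#'
#' Grows a random rooted binary tree of clones from a diploid germline
#' root, drawing structural events on each branch from a mechanistic
#' repertoire.  Event acquisition is gated by TP53 status: before the
#' TP53-loss branch only copy-neutral or focal events (UPD, focal
#' deletion/duplication) can fixate; after it the full repertoire
#' (terminal and internal bridge-type events, chromothripsis, focal
#' amplification, missegregation, whole-genome duplication) is open.
#' Every event records its realized breakpoints so downstream recovery
#' can be scored against the truth.
#'
#' @param genome a `genome_model`.
#' @param n_leaves number of observed clones (>= 2).
#' @param events_per_branch Poisson mean of the number of events per
#'   branch (default 2).
#' @param wgd_prob per-branch probability of whole-genome duplication on
#'   post-TP53-loss branches (default 0.2, giving roughly half of
#'   post-loss lineages a WGD in small trees).
#' @param tp53_node node id whose incoming branch carries the TP53 loss;
#'   NULL (default) picks a random non-root node.
#' @param tp53_rules if FALSE, the full event menu is available
#'   everywhere.
#' @param seed integer seed; the tree is deterministic given the seed.
#' @return object of class `clone_tree`: list with `genome`, `nodes`
#'   (data.frame id, parent, label, is_leaf, tp53_lost, wgd_branch),
#'   `karyotypes` (list by node id), `events` (list of event-spec lists
#'   by node id, the events on the incoming branch).
#' @export
simulate_clone_tree <- function(genome, n_leaves = 4,
                                events_per_branch = 2,
                                wgd_prob = 0.2,
                                tp53_node = NULL,
                                tp53_rules = TRUE,
                                seed = NULL) {
  if (n_leaves < 2) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  # topology: root (germline) -> MRCA; split random leaves until n_leaves
  parent <- c(NA_integer_, 1L)
  is_leaf <- c(FALSE, TRUE)
  while (sum(is_leaf) < n_leaves) {
    leaves <- which(is_leaf)
    split <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
    parent <- c(parent, split, split)
    is_leaf[split] <- FALSE
    is_leaf <- c(is_leaf, TRUE, TRUE)
  }
  n <- length(parent)
  if (is.null(tp53_node)) tp53_node <- sample(2:n, 1L)
  # TP53 status: lost on tp53_node's incoming branch and in its subtree
  lost <- rep(FALSE, n)
  for (i in 2:n) lost[i] <- (i == tp53_node) || lost[parent[i]]
  pre_menu <- c("upd", "focal_del", "focal_dup")
  post_menu <- c(pre_menu, "terminal", "internal", "chromothripsis",
                 "bfb_amplification", "missegregation")
  karyotypes <- vector("list", n)
  events <- vector("list", n)
  wgd_branch <- rep(FALSE, n)
  karyotypes[[1]] <- diploid_karyotype(genome)
  for (i in 2:n) {
    k <- karyotypes[[parent[i]]]
    menu <- if (tp53_rules && !lost[i]) pre_menu else post_menu
    evs <- list()
    if ((!tp53_rules || lost[i]) && stats::runif(1) < wgd_prob) {
      k <- apply_wgd(k)
      wgd_branch[i] <- TRUE
      evs <- c(evs, list(list(kind = "wgd")))
    }
    n_ev <- stats::rpois(1, events_per_branch)
    for (j in seq_len(n_ev)) {
      for (try in 1:5) {
        ev <- draw_event(genome, sample(menu, 1L))
        k2 <- try(apply_event(k, ev, genome), silent = TRUE)
        if (!inherits(k2, "try-error")) {
          if (ev$kind == "chromothripsis")
            ev$fragments <- attr(k2, "fragments")
          k <- as_karyotype(as.data.frame(k2))
          evs <- c(evs, list(ev))
          break
        }
      }
    }
    karyotypes[[i]] <- simplify_karyotype(k)
    events[[i]] <- evs
  }
  labels <- ifelse(is_leaf, paste0("S", cumsum(is_leaf)), paste0("N", seq_len(n)))
  labels[1] <- "germline"
  structure(list(genome = genome,
                 nodes = data.frame(id = seq_len(n), parent = parent,
                                    label = labels, is_leaf = is_leaf,
                                    tp53_lost = lost,
                                    wgd_branch = wgd_branch,
                                    stringsAsFactors = FALSE),
                 karyotypes = karyotypes,
                 events = events),
            class = "clone_tree")
}

# Draw one random event spec of the given kind (internal).
draw_event <- function(genome, kind) {
  cn <- sample(genome$chroms, 1L)
  L <- genome$lengths[[cn]]
  hom <- sample(c("A", "B"), 1L)
  switch(kind,
    upd = {
      arms <- genome_arms(genome)
      a <- arms[arms$chrom == cn, ][sample(1:2, 1L), ]
      list(kind = "upd", chrom = cn, homolog = hom,
           region = c(a$start, a$end))
    },
    focal_del = ,
    focal_dup = {
      len <- stats::runif(1, 5e5, 4e6)
      s <- stats::runif(1, 0, L - len)
      list(kind = kind, chrom = cn, homolog = hom, region = c(s, s + len))
    },
    terminal = list(kind = "terminal", chrom = cn, homolog = hom,
                    breakpoint = stats::runif(1, 0.1 * L, 0.9 * L),
                    sign = sample(c(-1L, 1L), 1L)),
    internal = {
      len <- stats::runif(1, 0.1 * L, 0.4 * L)
      s <- stats::runif(1, 0.02 * L, L - len - 0.02 * L)
      list(kind = "internal", chrom = cn, homolog = hom,
           region = c(s, s + len), sign = sample(c(-1L, 1L), 1L))
    },
    chromothripsis = {
      len <- stats::runif(1, 0.15 * L, 0.3 * L)
      s <- stats::runif(1, 0, L - len)
      list(kind = "chromothripsis", chrom = cn, homolog = hom,
           region = c(s, s + len),
           n_fragments = sample(8:16, 1L), retention_p = 0.5)
    },
    bfb_amplification = {
      q_side <- stats::runif(1) < 0.5
      len <- stats::runif(1, 1e6, 3e6)
      s <- if (q_side) stats::runif(1, 0.85 * L, 0.95 * L - len)
           else stats::runif(1, 0.05 * L, 0.15 * L)
      list(kind = "bfb_amplification", chrom = cn, homolog = hom,
           region = c(s, s + len), rounds = sample(3:4, 1L))
    },
    missegregation = list(kind = "missegregation", chrom = cn,
                          homolog = hom, sign = sample(c(-1L, 1L), 1L)),
    stop("unknown kind ", kind)
  )
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", sum(x$nodes$is_leaf), "leaves,",
      nrow(x$nodes), "nodes,",
      sum(lengths(x$events)), "events,",
      sum(x$nodes$wgd_branch), "WGD branch(es)\n")
  invisible(x)
}

#' Leaf labels of a clone tree
#' @param tree a `clone_tree`.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tree) tree$nodes$label[tree$nodes$is_leaf]

#' Karyotype of a named node
#' @param tree a `clone_tree`.
#' @param label node label (e.g. "S1").
#' @return a `karyotype`.
#' @export
tree_karyotype <- function(tree, label) {
  id <- tree$nodes$id[tree$nodes$label == label]
  if (length(id) != 1L) stop("unknown node ", label)
  tree$karyotypes[[id]]
}

#' Has a node's lineage undergone WGD?
#' @param tree a `clone_tree`.
#' @param label node label.
#' @return logical.
#' @export
tree_has_wgd <- function(tree, label) {
  id <- tree$nodes$id[tree$nodes$label == label]
  while (!is.na(id)) {
    if (tree$nodes$wgd_branch[id]) return(TRUE)
    id <- tree$nodes$parent[id]
  }
  FALSE
}

#' Export a clone tree as Newick
#' @param tree a `clone_tree`.
#' @return Newick string (leaves only, germline as root).
#' @export
tree_newick <- function(tree) {
  nd <- tree$nodes
  rec <- function(id) {
    kids <- nd$id[!is.na(nd$parent) & nd$parent == id]
    if (length(kids) == 0) return(nd$label[id])
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
  }
  paste0(rec(1L), "germline;")
}

#' Simulate a patient with clean lineage-marker breakpoints
#'
#' Grows a random clone-tree topology and plants a fixed number of
#' unique focal deletions on every branch, spaced widely enough
#' (> 10 Mb on each homolog) that no two markers merge and no
#' oscillating pattern arises.  This is the idealized regime for
#' breakpoint-based phylogeny: every branch is identifiable from
#' shared breakpoints and no later event erases an earlier one.
#'
#' @param genome a `genome_model`.
#' @param n_leaves samples (>= 2).
#' @param events_per_branch markers per branch (default 3).
#' @param seed integer seed.
#' @return a `clone_tree` whose branch events are focal deletions.
#' @export
simulate_breakpoint_patient <- function(genome, n_leaves = 6,
                                        events_per_branch = 3,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_clone_tree(genome, n_leaves = n_leaves,
                              events_per_branch = 0, wgd_prob = 0)
  slots <- do.call(rbind, lapply(genome$chroms, function(cn) {
    offs <- seq(2e6, genome$lengths[[cn]] - 4e6, by = 11.5e6)
    expand.grid(chrom = cn, homolog = c("A", "B"), off = offs,
                stringsAsFactors = FALSE)
  }))
  need <- (nrow(tree$nodes) - 1) * events_per_branch
  if (need > nrow(slots)) stop("genome too small for the requested markers")
  slots <- slots[sample(nrow(slots), need), ]
  si <- 1
  nd <- tree$nodes
  for (i in nd$id[-1]) {
    k <- tree$karyotypes[[nd$parent[i]]]
    evs <- list()
    for (q in seq_len(events_per_branch)) {
      sl <- slots[si, ]; si <- si + 1
      region <- c(sl$off, sl$off + 1e6)
      k <- apply_focal(k, sl$chrom, sl$homolog, region, -1L)
      evs <- c(evs, list(list(kind = "focal_del", chrom = sl$chrom,
                              homolog = sl$homolog, region = region)))
    }
    tree$karyotypes[[i]] <- simplify_karyotype(k)
    tree$events[[i]] <- evs
  }
  tree
}
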
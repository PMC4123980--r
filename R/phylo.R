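# Parsimony trees with bootstrap support, plus a distance-tree fallback and
# Newick I/O. Characters are unordered and equally weighted; gaps, N and
# ambiguity codes act as wildcard/partial states via IUPAC bitmasks, so a
# missing observation never forces a change.

DNA_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
              M = 3L, R = 5L, S = 6L, V = 7L, W = 9L, Y = 10L, H = 11L,
              K = 12L, D = 13L, B = 14L, N = 15L, "-" = 15L, "?" = 15L)

# alignment -> list(masks = ntip x npat integer matrix, weights = pattern
# counts); site patterns are compressed because parsimony scores are
# additive over identical columns
compress_patterns <- function(aln) {
  m <- unclass(aln)
  masks <- matrix(DNA_MASK[m], nrow(m), ncol(m))
  rownames(masks) <- rownames(m)
  key <- apply(masks, 2L, paste0, collapse = ",")
  first <- which(!duplicated(key))
  list(masks = masks[, first, drop = FALSE],
       weights = as.integer(table(key)[key[first]]))
}

# Fitch's pass folds a node's children sequentially (intersection if
# non-empty, else union and one change). For a binary node this is the
# textbook rule; at the basal trifurcation of an unrooted binary tree the
# sequential fold equals binary Fitch rooted on one of that node's child
# edges, so the unrooted score is exact without re-rooting.

#' Fitch parsimony length of a tree
#'
#' Counts the minimum number of state changes over the tree, summed over
#' alignment columns, with ambiguous/missing symbols treated as wildcard
#' state sets (Fitch's intersection/union pass). The score is an unrooted
#' quantity: rooting does not affect it.
#'
#' @param tree A `phylo` tree whose tip labels are a subset of the alignment
#'   row names.
#' @param aln A `"barcode_alignment"` (or character) matrix.
#' @return Integer parsimony score.
#' @export
fitch_length <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss)) stop("leaf without sequence: ", paste(miss, collapse = ", "))
  cp <- compress_patterns(aln)
  fitch_score_patterns(tree, cp$masks, cp$weights)
}

fitch_score_patterns <- function(tree, masks, weights) {
  ntip <- length(tree$tip.label)
  if (ntip == 2L) {
    inc <- bitwAnd(masks[tree$tip.label[1], ], masks[tree$tip.label[2], ]) == 0L
    return(sum(weights[inc]))
  }
  edge <- tree$edge
  npat <- ncol(masks)
  nnode <- ntip + tree$Nnode
  # DFS postorder over edges (cheaper than reorder.phylo for many small trees)
  kids <- split(seq_len(nrow(edge)), factor(edge[, 1], levels = seq_len(nnode)))
  root <- which(tabulate(edge[, 2], nnode) == 0L)[1]
  eorder <- integer(nrow(edge)); k <- 0L
  visit <- function(node) {
    for (e in kids[[node]]) {
      visit(edge[e, 2])
      k <<- k + 1L
      eorder[k] <<- e
    }
  }
  visit(root)
  states <- matrix(0L, nnode, npat)
  states[seq_len(ntip), ] <- masks[tree$tip.label, , drop = FALSE]
  seen <- logical(nnode)
  changes <- integer(npat)
  for (e in eorder) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    if (!seen[p]) {
      states[p, ] <- states[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(states[p, ], states[ch, ])
      empty <- inter == 0L
      inter[empty] <- bitwOr(states[p, ], states[ch, ])[empty]
      changes <- changes + empty
      states[p, ] <- inter
    }
  }
  sum(changes * weights)
}

# stepwise random-addition starting tree: taxa added in random order, each
# attached to the edge minimising the Fitch score
random_addition_tree <- function(masks, weights, labels) {
  ord <- sample(labels)
  tr <- trivial_tree(ord[1:3])
  for (tax in ord[-(1:3)]) {
    cands <- lapply(seq_len(nrow(tr$edge)), function(e) attach_tip(tr, e, tax))
    sc <- vapply(cands, fitch_score_patterns, numeric(1),
                 masks = masks, weights = weights)
    tr <- cands[[which.min(sc)]]
  }
  tr
}

trivial_tree <- function(labels) {
  n <- length(labels)
  tr <- structure(list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    tip.label = labels, Nnode = 1L), class = "phylo")
  tr$edge.length <- rep(1, n)
  tr
}

# insert a new tip midway along edge e of `tree`
attach_tip <- function(tree, e, label) {
  tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                        edge.length = 1, Nnode = 1L), class = "phylo")
  child <- tree$edge[e, 2]
  out <- ape::bind.tree(tree, tip, where = child, position = 0.5)
  out$edge.length <- rep(1, nrow(out$edge))
  out
}

#' Heuristic / exhaustive parsimony search
#'
#' Random-addition starting trees followed by NNI hill-climbing, repeated
#' `n_starts` times; all distinct topologies attaining the best score are
#' returned. For small taxon sets (<= `exhaustive_limit`) every unrooted
#' topology is evaluated instead, so the optimum is guaranteed.
#'
#' @param aln A `"barcode_alignment"` (or character) matrix; >= 2 rows.
#' @param seed Optional RNG seed for reproducible searches.
#' @param n_starts Number of random-addition starts (heuristic mode).
#' @param exhaustive_limit Maximum taxon count for exhaustive enumeration
#'   (default 9).
#' @return List: `trees` (a `multiPhylo` of distinct best topologies),
#'   `score` (integer), `method` (`"exhaustive"` or `"heuristic"`). Fewer
#'   than 4 taxa return the single trivial topology.
#' @export
parsimony_search <- function(aln, seed = NULL, n_starts = 10L,
                             exhaustive_limit = 9L) {
  if (!is.null(seed)) set.seed(seed)
  labels <- rownames(aln)
  n <- length(labels)
  cp <- compress_patterns(aln)
  if (n < 4L) {
    tr <- trivial_tree(labels)
    return(list(trees = c(tr), score = fitch_score_patterns(tr, cp$masks, cp$weights),
                method = "trivial"))
  }
  if (n <= exhaustive_limit) {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
    sc <- vapply(trees, fitch_score_patterns, numeric(1),
                 masks = cp$masks, weights = cp$weights)
    best <- which(sc == min(sc))
    return(list(trees = trees[best], score = as.integer(min(sc)),
                method = "exhaustive"))
  }
  best_score <- Inf
  best_trees <- list()
  for (s in seq_len(n_starts)) {
    tr <- random_addition_tree(cp$masks, cp$weights, labels)
    sc <- fitch_score_patterns(tr, cp$masks, cp$weights)
    repeat {
      nb <- phangorn::nni(tr)
      nsc <- vapply(nb, fitch_score_patterns, numeric(1),
                    masks = cp$masks, weights = cp$weights)
      if (min(nsc) < sc) {
        sc <- min(nsc)
        tr <- nb[[which.min(nsc)]]
      } else break
    }
    if (sc < best_score) {
      best_score <- sc
      best_trees <- list(tr)
    } else if (sc == best_score) {
      best_trees <- c(best_trees, list(tr))
    }
  }
  trees <- do.call(c, lapply(best_trees, function(x) c(x)))
  class(trees) <- "multiPhylo"
  trees <- unique(trees)
  list(trees = trees, score = as.integer(best_score), method = "heuristic")
}

#' Bootstrap support for the best parsimony tree
#'
#' Columns are resampled with replacement `reps` times; each replicate is
#' re-searched and the support of each internal edge of the reference tree is
#' the percentage of replicate best trees containing that bipartition.
#' Values below 50 are conventionally not displayed but are reported here.
#'
#' @param aln A `"barcode_alignment"` (or character) matrix.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param tree Optional reference tree; defaults to the best tree from
#'   [parsimony_search()] on the full alignment.
#' @param n_starts Starts per replicate search.
#' @return The reference `phylo` tree with `node.label` set to integer
#'   percent support (NA for the root).
#' @export
bootstrap_support <- function(aln, reps = 100L, seed = NULL, tree = NULL,
                              n_starts = 2L) {
  stopifnot(reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- parsimony_search(aln)$trees[[1]]
  rep_trees <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    sub <- unclass(aln)[, cols, drop = FALSE]
    rownames(sub) <- rownames(aln)
    rep_trees[[r]] <- parsimony_search(sub, n_starts = n_starts)$trees[[1]]
  }
  class(rep_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  out <- tree
  out$node.label <- round(100 * counts / reps)
  out
}

#' Neighbour-joining tree from a K2P distance matrix
#'
#' A lightweight distance-tree companion to the parsimony search, built on
#' the standard NJ agglomeration; negative branch lengths are clamped to
#' zero with a warning.
#'
#' @param dm A `"k2p_dist"` object with no undefined entries, >= 3 taxa.
#' @return A `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (nrow(dm$undefined_pairs) > 0L) {
    stop("distance matrix has undefined entries: ",
         nrow(dm$undefined_pairs), " pair(s)")
  }
  tr <- ape::nj(dm$d)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Read / write Newick trees
#'
#' Thin wrappers over the standard Newick parser supporting branch lengths
#' and node (support) labels.
#'
#' @param path File path.
#' @return `read_newick`: a `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree on declared outgroups for display
#'
#' Rooting is cosmetic for parsimony (scores are unrooted); this places the
#' root on the branch to the given outgroup(s).
#'
#' @param tree A `phylo` object.
#' @param outgroups Character vector of tip labels.
#' @return Rooted `phylo` object.
#' @export
root_on_outgroup <- function(tree, outgroups) {
  missing <- setdiff(outgroups, tree$tip.label)
  if (length(missing)) stop("outgroup(s) not in tree: ",
                            paste(missing, collapse = ", "))
  ape::root(tree, outgroup = outgroups, resolve.root = TRUE)
}
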
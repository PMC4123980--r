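# Minimum-spanning haplotype networks annotated by country.
#
# Edges are weighted by integer nucleotide differences between haplotype
# sequences. The MST is built with Kruskal's algorithm under a deterministic
# ordering (weight, then lexicographic node pair); because equal-weight
# alternatives are genuinely ambiguous in a displayed network, every
# non-tree edge that could replace a tree edge of the same weight on its
# cycle is reported in `alt_edges`.

#' Pairwise nucleotide-difference matrix between haplotypes
#'
#' @param ht A `"haplotype_table"`.
#' @return Symmetric integer matrix (haplotype ids as dimnames) of counts of
#'   differing retained columns; off-diagonal entries are >= 1 by
#'   construction (identical sequences collapse to one haplotype).
#' @export
haplotype_diff_matrix <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  m <- hap_hamming(ht$haplotypes$sequence)
  dimnames(m) <- list(ht$haplotypes$haplotype_id, ht$haplotypes$haplotype_id)
  m
}

#' Minimum spanning tree over haplotypes
#'
#' @param diff_matrix Symmetric matrix of positive off-diagonal integer
#'   weights, with dimnames.
#' @return Object of class `"hap_mst"`: list with `nodes` (ids), `edges`
#'   (data.frame `a`, `b`, `weight`, tree edges only), `alt_edges`
#'   (data.frame of co-minimal non-tree edges: each closes a cycle whose
#'   maximum tree-edge weight equals its own weight), and `total_weight`.
#' @export
minimum_spanning_tree <- function(diff_matrix) {
  stopifnot(is.matrix(diff_matrix), nrow(diff_matrix) >= 1L)
  ids <- rownames(diff_matrix)
  n <- length(ids)
  if (n == 1L) {
    return(structure(list(nodes = ids,
                          edges = data.frame(a = character(0), b = character(0),
                                             weight = numeric(0)),
                          alt_edges = data.frame(a = character(0), b = character(0),
                                                 weight = numeric(0)),
                          total_weight = 0),
                     class = "hap_mst"))
  }
  idx <- which(upper.tri(diff_matrix), arr.ind = TRUE)
  cand <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                     weight = diff_matrix[idx], stringsAsFactors = FALSE)
  swap <- cand$a > cand$b
  tmp <- cand$a[swap]; cand$a[swap] <- cand$b[swap]; cand$b[swap] <- tmp
  cand <- cand[order(cand$weight, cand$a, cand$b), , drop = FALSE]
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) { parent[[x]] <<- parent[[parent[[x]]]]; x <- parent[[x]] }; x }
  in_tree <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ra <- find(cand$a[r]); rb <- find(cand$b[r])
    if (ra != rb) { parent[[rb]] <- ra; in_tree[r] <- TRUE }
  }
  edges <- cand[in_tree, , drop = FALSE]
  rownames(edges) <- NULL
  # adjacency of the tree for path-max queries
  adj <- lapply(setNames(vector("list", n), ids), function(x) x)
  for (r in seq_len(nrow(edges))) {
    adj[[edges$a[r]]] <- rbind(adj[[edges$a[r]]],
                               data.frame(to = edges$b[r], w = edges$weight[r]))
    adj[[edges$b[r]]] <- rbind(adj[[edges$b[r]]],
                               data.frame(to = edges$a[r], w = edges$weight[r]))
  }
  path_max <- function(from, to) {
    seen <- setNames(rep(FALSE, n), ids)
    stack <- list(list(node = from, mx = 0))
    seen[from] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$node == to) return(cur$mx)
      nb <- adj[[cur$node]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        if (!seen[nb$to[r]]) {
          seen[nb$to[r]] <- TRUE
          stack[[length(stack) + 1L]] <- list(node = nb$to[r],
                                              mx = max(cur$mx, nb$w[r]))
        }
      }
      stack <- stack[!vapply(stack, is.null, logical(1))]
    }
    Inf
  }
  nt <- cand[!in_tree, , drop = FALSE]
  alt <- nt[vapply(seq_len(nrow(nt)), function(r) {
    nt$weight[r] == path_max(nt$a[r], nt$b[r])
  }, logical(1)), , drop = FALSE]
  rownames(alt) <- NULL
  structure(list(nodes = ids, edges = edges, alt_edges = alt,
                 total_weight = sum(edges$weight)),
            class = "hap_mst")
}

#' @export
print.hap_mst <- function(x, ...) {
  cat("Haplotype MST:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, total weight", x$total_weight,
      paste0("(", nrow(x$alt_edges), " co-minimal alternative edge(s))\n"))
  invisible(x)
}

#' Annotate a haplotype network with country composition
#'
#' Tags each haplotype node with its frequency and a country class mirroring
#' the usual two-country display encoding: found only in the first country,
#' only in the second, or shared.
#'
#' @param mst A `"hap_mst"`.
#' @param ht The `"haplotype_table"` the MST was built from.
#' @param metadata data.frame with `id` and `country` columns.
#' @param countries Length-2 character vector naming the two focal countries
#'   (defaults to the two most frequent in the metadata).
#' @return data.frame `nodes`: `haplotype_id`, `count`, `country_class` in
#'   `{<first>_only, <second>_only, shared, other, unknown}`, plus one count
#'   column per observed country.
#' @export
annotate_network <- function(mst, ht, metadata, countries = NULL) {
  stopifnot(inherits(mst, "hap_mst"), inherits(ht, "haplotype_table"))
  ctry_of <- setNames(metadata$country, metadata$id)
  all_ctry <- ctry_of[unlist(ht$members, use.names = FALSE)]
  if (is.null(countries)) {
    tab <- sort(table(all_ctry), decreasing = TRUE)
    countries <- names(tab)[seq_len(min(2L, length(tab)))]
  }
  rows <- lapply(mst$nodes, function(h) {
    ids <- ht$members[[h]]
    cc <- ctry_of[ids]
    known <- cc[!is.na(cc) & nzchar(cc)]
    cls <- if (length(known) == 0L) "unknown"
      else {
        in1 <- countries[1] %in% known
        in2 <- length(countries) > 1 && countries[2] %in% known
        if (in1 && in2) "shared"
        else if (in1) paste0(countries[1], "_only")
        else if (in2) paste0(countries[2], "_only")
        else "other"
      }
    data.frame(haplotype_id = h, count = length(ids), country_class = cls,
               stringsAsFactors = FALSE)
  })
  nodes <- do.call(rbind, rows)
  if (length(unique(all_ctry[!is.na(all_ctry)])) > 0) {
    per <- as.data.frame.matrix(table(
      factor(rep(names(ht$members), lengths(ht$members)), levels = mst$nodes),
      factor(all_ctry)))
    nodes <- cbind(nodes, per[nodes$haplotype_id, , drop = FALSE])
  }
  rownames(nodes) <- NULL
  nodes
}

#' Export a haplotype network as edge and node TSVs
#'
#' @param mst A `"hap_mst"`.
#' @param nodes Optional annotated node table from [annotate_network()].
#' @param edge_path,node_path Output paths (node table written only when
#'   `nodes` is supplied).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(mst, edge_path, nodes = NULL, node_path = NULL) {
  ed <- mst$edges
  ed$in_tree <- rep(TRUE, nrow(ed))
  alt <- mst$alt_edges
  alt$in_tree <- rep(FALSE, nrow(alt))
  ed <- rbind(ed, alt)
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodes) && !is.null(node_path)) {
    utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(edge_path, node_path))
}
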
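# Threshold OTU delimitation, per-cluster summaries, consensus barcodes,
# reference assignment and the COI-5'/COI-3' translation table.
#
# OTUs are single-linkage clusters at a K2P threshold: the transitive
# closure of the relation d <= t. This is a documented proxy for BIN-style
# clustering; thresholds default to 0.035 for COI-3' species delimitation
# and 0.02 for COI-5' OTUs (most intraspecific barcode distances fall well
# below 2%).

#' Single-linkage OTU clusters at a distance threshold
#'
#' Clusters are the connected components of the graph joining pairs with
#' `d <= threshold`; undefined pairs are treated as exceeding the threshold.
#' Cluster labels are deterministic: each cluster is named after its
#' lexicographically smallest member id.
#'
#' @param dm A `"k2p_dist"` object.
#' @param threshold Delimitation distance (substitutions/site), > 0.
#' @return An object of class `"otu_partition"`: named character vector
#'   mapping id to cluster label, with attributes `threshold` and `linkage`.
#' @export
single_linkage_clusters <- function(dm, threshold) {
  stopifnot(threshold > 0)
  labels <- dm$labels
  n <- length(labels)
  if (n == 0L) stop("empty distance matrix")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  adj <- which(dm$d <= threshold & !is.na(dm$d) & upper.tri(dm$d), arr.ind = TRUE)
  for (r in seq_len(nrow(adj))) {
    a <- find(adj[r, 1]); b <- find(adj[r, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, 1L)
  cl_label <- vapply(split(labels, roots), function(ids) min(ids), character(1))
  assignment <- setNames(cl_label[as.character(roots)], labels)
  structure(assignment, threshold = threshold, linkage = "single",
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat("OTU partition:", length(unique(unclass(x))), "cluster(s) over",
      length(x), "sequences at threshold", attr(x, "threshold"), "\n")
  invisible(x)
}

#' Per-cluster summary statistics
#'
#' For each cluster: size, maximum intra-cluster K2P distance, nearest
#' neighbouring cluster and its distance (minimum distance from any member to
#' any non-member), and the union of host plants and countries from the
#' metadata.
#'
#' @param dm A `"k2p_dist"` object.
#' @param partition Named vector (e.g. an `"otu_partition"`) over `dm$labels`.
#' @param metadata Optional data.frame with columns `id` and any of `host`,
#'   `country`.
#' @return data.frame with columns `cluster_id`, `n`, `max_intra`,
#'   `nn_cluster`, `nn_dist`, `hosts`, `countries`. Distances are in
#'   substitutions/site; singletons have `max_intra` NA; with a single
#'   cluster the NN fields are NA.
#' @export
cluster_summaries <- function(dm, partition, metadata = NULL) {
  stopifnot(all(dm$labels %in% names(partition)))
  cl <- as.character(partition[dm$labels])
  clusters <- sort(unique(cl))
  meta_union <- function(ids, col) {
    if (is.null(metadata) || !col %in% names(metadata)) return(NA_character_)
    v <- metadata[[col]][match(ids, metadata$id)]
    v <- sort(unique(v[!is.na(v) & nzchar(v)]))
    if (length(v)) paste(v, collapse = ";") else NA_character_
  }
  rows <- lapply(clusters, function(cc) {
    i <- which(cl == cc)
    j <- which(cl != cc)
    sub <- dm$d[i, i, drop = FALSE]
    intra <- sub[lower.tri(sub)]
    intra <- intra[!is.na(intra)]
    if (length(j)) {
      cross <- dm$d[i, j, drop = FALSE]
      if (all(is.na(cross))) {
        nn_dist <- NA_real_; nn_cluster <- NA_character_
      } else {
        k <- which.min(cross)
        nn_dist <- cross[k]
        nn_cluster <- cl[j[(k - 1L) %/% length(i) + 1L]]
      }
    } else {
      nn_dist <- NA_real_; nn_cluster <- NA_character_
    }
    data.frame(cluster_id = cc, n = length(i),
               max_intra = if (length(intra)) max(intra) else NA_real_,
               nn_cluster = nn_cluster, nn_dist = nn_dist,
               hosts = meta_union(dm$labels[i], "host"),
               countries = meta_union(dm$labels[i], "country"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimal IUPAC code covering a set of bases
iupac_for <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste0(bases, collapse = "")
  sets <- vapply(IUPAC_CODES, function(s) paste0(sort(charvec(s)), collapse = ""),
                 character(1))
  names(sets)[match(key, sets)]
}

#' Consensus barcode for a set of aligned sequences
#'
#' Per column: the strict-majority base among A/C/G/T (missing and ambiguous
#' symbols excluded from the tally); ties produce the minimal IUPAC code
#' covering the tied bases; all-missing columns give N.
#'
#' @param aln A `"barcode_alignment"` matrix (or character matrix) of the
#'   cluster's sequences.
#' @return A single consensus sequence string.
#' @export
consensus_barcode <- function(aln) {
  m <- unclass(aln)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    acgt <- col[col %in% c("A", "C", "G", "T")]
    if (length(acgt) == 0L) {
      # no unambiguous base: fall back to the union of the ambiguity sets so
      # that consensus-of-consensus is a fixed point; all-missing gives N
      amb <- col[col %in% setdiff(names(IUPAC_CODES), c("A", "C", "G", "T"))]
      if (length(amb) == 0L) return("N")
      return(iupac_for(unlist(strsplit(IUPAC_CODES[amb], ""))))
    }
    tab <- table(acgt)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else iupac_for(top)
  }, character(1))
  paste0(cons, collapse = "")
}

#' Assign a query sequence to a reference panel species
#'
#' Computes the K2P distance from the query to every panel consensus and
#' assigns the nearest species when its distance is within the threshold;
#' queries whose minimum distance exceeds the threshold are flagged as novel
#' lineages (the distance is always reported so a stricter novelty margin can
#' be applied). An exact tie between two species gives status `"unresolved"`
#' with both names reported.
#'
#' @param query_seq Query sequence string (aligned to the panel window).
#' @param panel Named character vector: species name -> consensus sequence,
#'   all the same length as the query.
#' @param threshold Assignment threshold; default 0.035, the standard COI-3'
#'   species delimitation distance.
#' @return List: `species` (character, possibly length 2 on a tie, or
#'   `"NOVEL"`), `dist_to_nearest_reference`, `status` in
#'   `{"assigned","novel","unresolved"}`, and `distances` (named vector).
#' @export
assign_to_reference <- function(query_seq, panel, threshold = 0.035) {
  stopifnot(length(panel) >= 1L, !is.null(names(panel)))
  dists <- vapply(panel, function(ref) {
    res <- tryCatch(k2p_distance(query_seq, ref),
                    error = function(e) list(distance = NA_real_))
    res$distance
  }, numeric(1))
  if (all(is.na(dists))) {
    return(list(species = NA_character_, dist_to_nearest_reference = NA_real_,
                status = "unresolved", distances = dists))
  }
  dmin <- min(dists, na.rm = TRUE)
  nearest <- names(dists)[!is.na(dists) & dists == dmin]
  if (dmin > threshold) {
    list(species = "NOVEL", dist_to_nearest_reference = dmin,
         status = "novel", distances = dists)
  } else if (length(nearest) > 1L) {
    list(species = sort(nearest), dist_to_nearest_reference = dmin,
         status = "unresolved", distances = dists)
  } else {
    list(species = nearest, dist_to_nearest_reference = dmin,
         status = "assigned", distances = dists)
  }
}

#' Build the COI-5'/COI-3' translation table
#'
#' Connects each COI-5' OTU to the species its COI-3' representative(s) were
#' assigned to. Several OTUs may legitimately map to the same species
#' (many-to-one); an OTU whose representatives map to different species is a
#' conflict and raises an error naming them; OTUs with no representative are
#' reported `"unresolved"`.
#'
#' @param coi5_partition An `"otu_partition"` over the COI-5' ids.
#' @param representative_map Named character vector: representative COI-3'
#'   record id -> COI-5' cluster label it represents.
#' @param coi3_assignments Named list: representative id ->
#'   [assign_to_reference()] result.
#' @return data.frame with `coi5_cluster_id`, `coi3_species`,
#'   `representative_ids`, `dist_to_nearest_reference`, `status`.
#' @export
build_translation_table <- function(coi5_partition, representative_map,
                                    coi3_assignments) {
  clusters <- sort(unique(as.character(unclass(coi5_partition))))
  rows <- lapply(clusters, function(cc) {
    reps <- names(representative_map)[representative_map == cc]
    reps <- intersect(reps, names(coi3_assignments))
    if (length(reps) == 0L) {
      return(data.frame(coi5_cluster_id = cc, coi3_species = NA_character_,
                        representative_ids = NA_character_,
                        dist_to_nearest_reference = NA_real_,
                        status = "unresolved", stringsAsFactors = FALSE))
    }
    asg <- coi3_assignments[reps]
    sp <- vapply(asg, function(a) paste(a$species, collapse = "|"), character(1))
    st <- vapply(asg, function(a) a$status, character(1))
    dd <- vapply(asg, function(a) a$dist_to_nearest_reference, numeric(1))
    usp <- unique(sp[st != "unresolved"])
    if (length(usp) > 1L) {
      stop("conflicting species assignments for cluster ", cc, ": ",
           paste(usp, collapse = " vs "))
    }
    status <- if (all(st == "unresolved")) "unresolved"
              else if (any(st == "novel")) "novel" else "assigned"
    data.frame(coi5_cluster_id = cc,
               coi3_species = if (length(usp)) usp else NA_character_,
               representative_ids = paste(reps, collapse = ";"),
               dist_to_nearest_reference = min(dd, na.rm = TRUE),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
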
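# Coalescent-based sequence simulator with known ground truth.
#
# The generator emulates the structure of a barcode survey of a cryptic
# species complex: K deeply divergent clusters (star phylogeny between
# cluster ancestors, expected pairwise divergence d_between), each cluster a
# neutral constant-size Kingman coalescent sample with scaled mutation
# parameter theta, finite-sites mutation with a transition/transversion rate
# ratio kappa (so K2P's machinery is genuinely exercised), coding-frame
# sequences free of stop codons, country labels drawn from stated weights,
# and (optionally) a second linked marker evolving on the same genealogy.

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study conditions of a two-province barcode survey:
#' five species-level clusters, within-cluster diversity well below the
#' delimitation threshold (theta = 2 on a 600 bp marker gives pi around
#' 0.003), between-cluster divergence of 10% (within the observed
#' nearest-neighbour range of 1-17%), kappa = 4 (typical insect mtDNA), and
#' two countries with a 70/30 sampling split.
#'
#' @param K Number of clusters (>= 1).
#' @param n_per Samples per cluster (>= 2).
#' @param L Marker length in bp, a codon multiple (>= 60).
#' @param theta Per-cluster scaled mutation parameter (> 0).
#' @param d_between Expected between-cluster divergence, substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @param countries Named numeric vector of country sampling weights.
#' @param dual_marker Emit a linked second marker (COI-3') on the same
#'   genealogy.
#' @param L3 Second-marker length (codon multiple).
#' @param n_coi3_reps Representatives per cluster sequenced for the second
#'   marker.
#' @param seed Integer RNG seed; all outputs are deterministic given it.
#' @return A `"synthetic_config"` list.
#' @export
synthetic_config <- function(K = 5L, n_per = 20L, L = 600L, theta = 2,
                             d_between = 0.10, kappa = 4,
                             countries = c(Pakistan = 0.7, India = 0.3),
                             dual_marker = FALSE, L3 = 600L,
                             n_coi3_reps = 3L, seed = 1L) {
  stopifnot(K >= 1L, n_per >= 2L, L >= 60L, L %% 3L == 0L, theta > 0,
            d_between > 0, kappa > 0, all(countries > 0),
            !is.null(names(countries)), L3 %% 3L == 0L)
  structure(list(K = as.integer(K), n_per = as.integer(n_per),
                 L = as.integer(L), theta = theta, d_between = d_between,
                 kappa = kappa, countries = countries / sum(countries),
                 dual_marker = isTRUE(dual_marker), L3 = as.integer(L3),
                 n_coi3_reps = as.integer(n_coi3_reps),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Random stop-free coding sequence
#'
#' Codons are drawn uniformly from the non-stop codons of the genetic code,
#' so the frame-0 reading frame never contains a stop.
#'
#' @param L Length in bp (codon multiple).
#' @param genetic_code Codon table; default [invert_mito_code()].
#' @return A sequence string.
#' @export
random_coding_sequence <- function(L, genetic_code = invert_mito_code()) {
  stopifnot(L %% 3L == 0L)
  codons <- names(genetic_code)[genetic_code != "*"]
  paste0(sample(codons, L / 3L, replace = TRUE), collapse = "")
}

# apply n_events kappa-biased substitutions to a character vector; when
# preserve_orf, an event that would create a frame-0 stop codon is relocated
# to a fresh random site (event count preserved, so E[S] is unbiased)
mutate_charvec <- function(v, n_events, kappa,
                           preserve_orf = TRUE,
                           genetic_code = invert_mito_code(),
                           max_tries = 200L) {
  if (n_events == 0L) return(v)
  L <- length(v)
  p_ts <- kappa / (kappa + 2)
  for (e in seq_len(n_events)) {
    for (try in seq_len(max_tries)) {
      site <- sample.int(L, 1L)
      base <- v[site]
      new <- if (stats::runif(1) < p_ts) TRANSITION_OF[[base]]
             else sample(TRANSVERSIONS_OF[[base]], 1L)
      if (!preserve_orf) { v[site] <- new; break }
      codon_i <- (site - 1L) %/% 3L
      cod <- v[(3L * codon_i + 1L):(3L * codon_i + 3L)]
      cod[(site - 1L) %% 3L + 1L] <- new
      if (genetic_code[[paste0(cod, collapse = "")]] != "*") {
        v[site] <- new
        break
      }
      if (try == max_tries) stop("could not place mutation without creating a stop codon")
    }
  }
  v
}

#' Simulate cluster ancestor sequences
#'
#' A random stop-free root sequence is mutated independently along each arm
#' of a star phylogeny so that the expected pairwise divergence between any
#' two cluster ancestors is `d_between` substitution events per site.
#'
#' @param config A `"synthetic_config"` (fields `K`, `L`, `d_between`,
#'   `kappa` are used). The caller controls the RNG state.
#' @param L Length override (defaults to `config$L`).
#' @return Named character vector of `K` ancestor sequences
#'   (`C1`, ..., `CK`), all passing [translation_qc()].
#' @export
simulate_cluster_ancestors <- function(config, L = config$L) {
  root <- charvec(random_coding_sequence(L))
  anc <- vapply(seq_len(config$K), function(k) {
    n_ev <- stats::rpois(1L, L * config$d_between / 2)
    paste0(mutate_charvec(root, n_ev, config$kappa), collapse = "")
  }, character(1))
  names(anc) <- paste0("C", seq_len(config$K))
  anc
}

# Kingman coalescent genealogy for n tips; returns an ape phylo with branch
# lengths in coalescent time units
coalescent_tree <- function(n) {
  if (n == 1L) stop("need n >= 2")
  n_nodes <- 2L * n - 1L
  height <- numeric(n_nodes)
  parent <- integer(n_nodes)
  active <- seq_len(n)
  t <- 0
  next_node <- n
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample(active, 2L)
    next_node <- next_node + 1L
    height[next_node] <- t
    parent[pair] <- next_node
    active <- c(setdiff(active, pair), next_node)
  }
  edge <- cbind(parent[-n_nodes], seq_len(n_nodes)[-n_nodes])
  # ape numbering: tips 1..n, root n+1, others following; remap internals
  root <- n_nodes
  internal_old <- (n + 1L):n_nodes
  map <- integer(n_nodes)
  map[seq_len(n)] <- seq_len(n)
  map[root] <- n + 1L
  map[setdiff(internal_old, root)] <- (n + 2L):n_nodes
  edge_m <- cbind(map[edge[, 1]], map[edge[, 2]])
  len <- height[edge[, 1]] - height[edge[, 2]]
  ord <- order(edge_m[, 1], edge_m[, 2])
  structure(list(edge = edge_m[ord, , drop = FALSE],
                 edge.length = len[ord],
                 tip.label = paste0("t", seq_len(n)),
                 Nnode = n - 1L),
            class = "phylo")
}

#' Simulate a neutral coalescent sample of sequences
#'
#' A constant-size Kingman genealogy is drawn, Poisson(theta/2 x branch
#' length) mutation events are placed on each branch, and the ancestor
#' sequence is propagated from the root to the tips under the kappa-biased
#' finite-sites process. Expectations: E[S] = theta x a1(n) and
#' E[mean pairwise differences] = theta (up to the small finite-sites
#' correction).
#'
#' @param ancestor Ancestor sequence string.
#' @param n Sample size (>= 2).
#' @param theta Scaled mutation parameter.
#' @param kappa Transition/transversion rate ratio.
#' @param preserve_orf Keep the frame-0 reading frame stop-free.
#' @param tree Optional pre-drawn genealogy (a `phylo` from this simulator),
#'   e.g. to evolve a second marker on the same genealogy.
#' @return List: `sequences` (named character vector, tips `t1..tn`),
#'   `tree` (the genealogy), `haplotype` (named vector: true haplotype id of
#'   each tip), `n_mutations` (total events placed).
#' @export
simulate_coalescent_sample <- function(ancestor, n, theta, kappa = 4,
                                       preserve_orf = TRUE, tree = NULL) {
  stopifnot(n >= 2L)
  if (is.null(tree)) tree <- coalescent_tree(n)
  anc <- charvec(ancestor)
  n_nodes <- 2L * n - 1L
  seqs <- vector("list", n_nodes)
  root <- n + 1L
  seqs[[root]] <- anc
  # topological order: an edge is processed once its parent's sequence exists
  ord <- integer(0)
  ready <- rep(FALSE, n_nodes)
  ready[root] <- TRUE
  pending <- seq_len(nrow(tree$edge))
  while (length(pending)) {
    can <- pending[ready[tree$edge[pending, 1]]]
    ord <- c(ord, can)
    ready[tree$edge[can, 2]] <- TRUE
    pending <- setdiff(pending, can)
  }
  total_mut <- 0L
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    stopifnot(!is.null(seqs[[p]]))
    n_ev <- stats::rpois(1L, theta / 2 * tree$edge.length[e])
    total_mut <- total_mut + n_ev
    seqs[[ch]] <- mutate_charvec(seqs[[p]], n_ev, kappa,
                                 preserve_orf = preserve_orf)
  }
  tips <- vapply(seq_len(n), function(i) paste0(seqs[[i]], collapse = ""),
                 character(1))
  names(tips) <- tree$tip.label
  hap <- match(tips, unique(tips))
  names(hap) <- tree$tip.label
  list(sequences = tips, tree = tree,
       haplotype = setNames(paste0("H", hap), names(hap)),
       n_mutations = total_mut)
}

#' Emit a full synthetic dataset with ground truth
#'
#' Deterministic for a fixed seed. Generates cluster ancestors, a coalescent
#' sample per cluster, country/province labels, and (for `dual_marker`) a
#' second marker evolved on the same genealogies plus the true species
#' reference panel.
#'
#' @param config A `"synthetic_config"`.
#' @param dir Optional output directory; when given, writes `coi5.fasta`,
#'   `metadata.tsv`, `truth.tsv` (and `coi3.fasta`, `panel_coi3.fasta` for
#'   dual-marker configs).
#' @return List: `coi5` (named sequences), `coi3` (or NULL), `coi3_panel`
#'   (species -> reference sequence, or NULL), `metadata` (data.frame with
#'   id, marker, country, province, region, host, species_label), `truth`
#'   (data.frame with id, cluster, species, country, haplotype), `config`.
#' @export
emit_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  provinces <- list(Pakistan = c("Punjab", "Sindh"),
                    India = c("Uttar Pradesh", "Gujarat"))
  hosts <- c("cotton", "tomato", "brinjal", "okra")
  anc5 <- simulate_cluster_ancestors(config)
  anc3 <- if (config$dual_marker)
    simulate_cluster_ancestors(config, L = config$L3) else NULL
  species <- setNames(paste0("species_", seq_len(config$K)), names(anc5))
  coi5 <- character(0); coi3 <- character(0)
  truth <- list(); meta <- list()
  for (k in seq_len(config$K)) {
    cl <- names(anc5)[k]
    sim5 <- simulate_coalescent_sample(anc5[[cl]], config$n_per, config$theta,
                                       config$kappa)
    ids <- paste0(cl, "_S", sprintf("%02d", seq_len(config$n_per)))
    s5 <- setNames(sim5$sequences, ids)
    coi5 <- c(coi5, s5)
    ctry <- sample(names(config$countries), config$n_per, replace = TRUE,
                   prob = config$countries)
    prov <- vapply(ctry, function(cc) {
      pp <- provinces[[cc]]
      if (is.null(pp)) cc else sample(pp, 1L)
    }, character(1))
    host <- sample(hosts, config$n_per, replace = TRUE)
    meta[[k]] <- data.frame(id = ids, marker = "COI5", country = ctry,
                            province = prov, region = prov, host = host,
                            species_label = "", stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(id = ids, cluster = cl, species = species[[cl]],
                             country = ctry,
                             haplotype = unname(sim5$haplotype),
                             stringsAsFactors = FALSE)
    if (config$dual_marker) {
      reps <- seq_len(min(config$n_coi3_reps, config$n_per))
      sim3 <- simulate_coalescent_sample(anc3[[cl]], config$n_per,
                                         config$theta, config$kappa,
                                         tree = sim5$tree)
      s3 <- setNames(sim3$sequences[reps], ids[reps])
      coi3 <- c(coi3, s3)
      meta[[k]] <- rbind(meta[[k]],
                         data.frame(id = ids[reps], marker = "COI3",
                                    country = ctry[reps], province = prov[reps],
                                    region = prov[reps], host = host[reps],
                                    species_label = "", stringsAsFactors = FALSE))
    }
  }
  metadata <- do.call(rbind, meta)
  truth <- do.call(rbind, truth)
  panel <- if (config$dual_marker) setNames(unname(anc3), species) else NULL
  out <- list(coi5 = coi5, coi3 = if (config$dual_marker) coi3 else NULL,
              coi3_panel = panel, metadata = metadata, truth = truth,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(coi5, file.path(dir, "coi5.fasta"))
    utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (config$dual_marker) {
      write_fasta(coi3, file.path(dir, "coi3.fasta"))
      write_fasta(panel, file.path(dir, "panel_coi3.fasta"))
    }
  }
  out
}
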
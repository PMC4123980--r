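# Kimura 2-parameter distances and barcode-gap diagnostics.
#
# K2P corrects separately for transitions (P = A<->G, C<->T) and
# transversions (Q): d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), with P and Q
# the per-site proportions over columns where both sequences carry an
# unambiguous base (pairwise deletion). Pairs where either logarithm's
# argument is <= 0 are undefined and are flagged, never clamped: a clamped
# ceiling would corrupt the barcode gap.

#' Kimura 2-parameter distance between two aligned sequences
#'
#' @param seq_a,seq_b Equal-length aligned sequences (strings or character
#'   vectors).
#' @return List: `distance` (substitutions/site; NA when undefined),
#'   `defined`, `valid_sites`, `transitions`, `transversions`, `P`, `Q`.
#' @details Columns where either sequence has anything other than A/C/G/T are
#'   excluded (pairwise deletion). Zero comparable sites is an error;
#'   saturation (1 - 2P - Q <= 0 or 1 - 2Q <= 0) gives `defined = FALSE`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) charvec(seq_a) else seq_a
  b <- if (length(seq_b) == 1L) charvec(seq_b) else seq_b
  stopifnot(length(a) == length(b))
  acgt <- c("A", "C", "G", "T")
  ok <- a %in% acgt & b %in% acgt
  v <- sum(ok)
  if (v == 0L) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  tv <- sum(diff) - ts
  P <- ts / v; Q <- tv / v
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 && w2 > 0
  d <- if (defined) -0.5 * log(w1) - 0.25 * log(w2) else NA_real_
  list(distance = d, defined = defined, valid_sites = v,
       transitions = ts, transversions = tv, P = P, Q = Q)
}

#' All pairwise K2P distances for an alignment
#'
#' Computed with indicator-matrix cross-products, so the cost is a handful of
#' dense matrix products rather than an explicit pair loop.
#'
#' @param aln A `"barcode_alignment"` matrix (or any character matrix of
#'   aligned single characters with row names).
#' @return An object of class `"k2p_dist"`: list with `labels`, `d`
#'   (symmetric numeric matrix, NA where undefined), `valid_sites`,
#'   `transitions`, `transversions` (integer matrices), and
#'   `undefined_pairs` (data.frame `id_a`, `id_b`, `reason`).
#' @export
distance_matrix <- function(aln) {
  m <- unclass(aln)
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  labels <- rownames(m)
  n <- nrow(m)
  ind <- function(b) (m == b) * 1
  MA <- ind("A"); MC <- ind("C"); MG <- ind("G"); MT <- ind("T")
  NM <- MA + MC + MG + MT
  valid <- tcrossprod(NM)
  match <- tcrossprod(MA) + tcrossprod(MC) + tcrossprod(MG) + tcrossprod(MT)
  ts <- tcrossprod(MA, MG) + tcrossprod(MG, MA) +
        tcrossprod(MC, MT) + tcrossprod(MT, MC)
  tv <- valid - match - ts
  P <- ifelse(valid > 0, ts / valid, NA_real_)
  Q <- ifelse(valid > 0, tv / valid, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- valid > 0 & w1 > 0 & w2 > 0
  d <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  diag(d) <- 0
  undef <- which(!ok & upper.tri(ok), arr.ind = TRUE)
  undefined_pairs <- data.frame(
    id_a = labels[undef[, 1]],
    id_b = labels[undef[, 2]],
    reason = ifelse(valid[undef] == 0, "no comparable sites", "saturated"),
    stringsAsFactors = FALSE
  )
  dimnames(valid) <- dimnames(ts) <- dimnames(tv) <- list(labels, labels)
  structure(list(labels = labels, d = d, valid_sites = valid,
                 transitions = ts, transversions = tv,
                 undefined_pairs = undefined_pairs),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix:", length(x$labels), "sequences,",
      nrow(x$undefined_pairs), "undefined pair(s)\n")
  invisible(x)
}

# lower-triangle values of a k2p_dist (defined and undefined)
pair_values <- function(dm) dm$d[lower.tri(dm$d)]

#' Summary statistics over the defined pairwise distances
#'
#' @param dm A `"k2p_dist"` object.
#' @return List: `min`, `max`, `mean` (unweighted over defined pairs),
#'   `n_pairs` (defined pairs), `n_undefined`.
#' @export
summarize_distances <- function(dm) {
  stopifnot(length(dm$labels) >= 2L)
  v <- pair_values(dm)
  def <- v[!is.na(v)]
  if (length(def) == 0L) stop("all pairs undefined")
  list(min = min(def), max = max(def), mean = mean(def),
       n_pairs = length(def), n_undefined = sum(is.na(v)))
}

#' Histogram of pairwise distances
#'
#' Half-open bins `[k*w, (k+1)*w)`, as used for barcode-gap distance
#' histograms.
#'
#' @param dm A `"k2p_dist"` object.
#' @param bin_width Bin width (substitutions/site).
#' @return data.frame with `bin_low`, `bin_high`, `count`; counts sum to the
#'   number of defined pairs.
#' @export
distance_histogram <- function(dm, bin_width = 0.005) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  v <- pair_values(dm)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no defined pairs")
  k <- floor(v / bin_width)
  tab <- table(k)
  ks <- as.integer(names(tab))
  data.frame(bin_low = ks * bin_width, bin_high = (ks + 1) * bin_width,
             count = as.integer(tab))
}

#' Ranked (sorted ascending) pairwise distances
#'
#' @param dm A `"k2p_dist"` object.
#' @return Numeric vector of defined pairwise distances, non-decreasing.
#' @export
ranked_distances <- function(dm) {
  v <- pair_values(dm)
  sort(v[!is.na(v)])
}

#' Intra- vs inter-cluster distance summary (barcode gap)
#'
#' @param dm A `"k2p_dist"` object.
#' @param partition Named character/factor vector mapping every label in `dm`
#'   to a cluster.
#' @return List: `per_cluster` (data.frame `cluster`, `n`, `max_intra`; NA
#'   max_intra for singletons), `intra` and `inter` (defined distance
#'   vectors), and `gap` = min(inter) - max(intra) (NA when either side is
#'   empty).
#' @export
intra_inter_summary <- function(dm, partition) {
  stopifnot(all(dm$labels %in% names(partition)))
  cl <- as.character(partition[dm$labels])
  n <- length(dm$labels)
  same <- outer(cl, cl, "==")
  lt <- lower.tri(dm$d)
  intra <- dm$d[lt & same]
  inter <- dm$d[lt & !same]
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  per_cluster <- do.call(rbind, lapply(split(seq_len(n), cl), function(i) {
    sub <- dm$d[i, i, drop = FALSE]
    vals <- sub[lower.tri(sub)]
    vals <- vals[!is.na(vals)]
    data.frame(cluster = cl[i[1]], n = length(i),
               max_intra = if (length(vals)) max(vals) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_cluster) <- NULL
  gap <- if (length(intra) && length(inter)) min(inter) - max(intra) else NA_real_
  list(per_cluster = per_cluster, intra = intra, inter = inter, gap = gap)
}

#' Export a distance matrix as TSV
#'
#' @param dm A `"k2p_dist"` object.
#' @param path Output path.
#' @param format `"square"` (matrix with ids) or `"long"` (`id_a`, `id_b`,
#'   `distance`, `valid_sites`, one row per unordered pair).
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(id = dm$labels, dm$d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(lower.tri(dm$d), arr.ind = TRUE)
    df <- data.frame(id_a = dm$labels[idx[, 2]], id_b = dm$labels[idx[, 1]],
                     distance = dm$d[idx], valid_sites = dm$valid_sites[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Format a distance as percent, 1 decimal
#'
#' Table-style percent reporting (internal values stay full precision).
#' @param d Numeric distances (substitutions/site).
#' @return Numeric percent rounded to 1 decimal.
#' @export
as_percent <- function(d) round(100 * d, 1)
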
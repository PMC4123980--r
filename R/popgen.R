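# Haplotype collapsing and genetic diversity / neutrality statistics:
# S, Eta(s), k, pi, Hd, Tajima's D and Fu's Fs.
#
# All statistics are computed on the columns retained by the deletion
# policy; the default (complete deletion) drops every column containing a
# missing or ambiguous symbol in any sequence, matching the usual DnaSP
# behaviour. Haplotype identity is defined after deletion, so two sequences
# differing only at removed columns collapse to one haplotype.

# columns where every sequence carries an unambiguous base
complete_deletion_cols <- function(m) {
  which(colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m))
}

#' Collapse aligned sequences into haplotypes
#'
#' @param aln A `"barcode_alignment"` (or character) matrix.
#' @param deletion `"complete"` (default: drop columns with any
#'   missing/ambiguous symbol before comparing) or `"none"`.
#' @param metadata Optional data.frame with `id` and `country` columns for
#'   per-country haplotype counts.
#' @return An object of class `"haplotype_table"`: list with `haplotypes`
#'   (data.frame `haplotype_id`, `sequence`, `count`), `members` (named list
#'   of id vectors), `country_counts` (table or NULL), `n`, `L_used`.
#'   Haplotype ids are ordered by descending count, then first appearance.
#' @export
collapse_haplotypes <- function(aln, deletion = c("complete", "none"),
                                metadata = NULL) {
  deletion <- match.arg(deletion)
  m <- unclass(aln)
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  cols <- if (deletion == "complete") complete_deletion_cols(m) else seq_len(ncol(m))
  if (length(cols) == 0L) stop("no columns retained under complete deletion")
  key <- apply(m[, cols, drop = FALSE], 1L, paste0, collapse = "")
  first <- !duplicated(key)
  counts <- table(factor(key, levels = key[first]))
  ord <- order(-as.integer(counts), seq_along(counts))
  ids <- paste0("H", seq_along(ord))
  seqs <- names(counts)[ord]
  members <- split(rownames(m), factor(key, levels = seqs))
  names(members) <- ids
  country_counts <- NULL
  if (!is.null(metadata) && "country" %in% names(metadata)) {
    hap_of <- rep(names(members), lengths(members))
    id_of <- unlist(members, use.names = FALSE)
    ctry <- metadata$country[match(id_of, metadata$id)]
    country_counts <- table(haplotype = factor(hap_of, levels = ids),
                            country = ctry)
  }
  structure(list(
    haplotypes = data.frame(haplotype_id = ids, sequence = seqs,
                            count = as.integer(counts)[ord],
                            stringsAsFactors = FALSE),
    members = members, country_counts = country_counts,
    n = nrow(m), L_used = length(cols)),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", nrow(x$haplotypes), "haplotypes over", x$n,
      "sequences (", x$L_used, "columns used )\n")
  invisible(x)
}

#' Segregating sites and singleton mutations
#'
#' @param aln A `"barcode_alignment"` (or character) matrix, n >= 2 rows.
#' @return List with `S` (columns showing >= 2 distinct bases on the
#'   complete-deletion columns) and `Eta_s` (biallelic columns whose minor
#'   allele occurs in exactly one sequence), plus `L_used`.
#' @export
segregating_sites <- function(aln) {
  m <- unclass(aln)
  stopifnot(nrow(m) >= 2L)
  cols <- complete_deletion_cols(m)
  if (length(cols) == 0L) stop("no columns retained under complete deletion")
  S <- 0L; Eta_s <- 0L
  for (j in cols) {
    tab <- table(m[, j])
    if (length(tab) >= 2L) {
      S <- S + 1L
      if (length(tab) == 2L && min(tab) == 1L) Eta_s <- Eta_s + 1L
    }
  }
  list(S = S, Eta_s = Eta_s, L_used = length(cols))
}

# pairwise Hamming differences between haplotype sequences (equal length)
hap_hamming <- function(seqs) {
  H <- length(seqs)
  mat <- matrix(0L, H, H)
  if (H >= 2L) {
    ch <- lapply(seqs, charvec)
    for (i in 1:(H - 1)) for (j in (i + 1):H) {
      mat[i, j] <- mat[j, i] <- sum(ch[[i]] != ch[[j]])
    }
  }
  mat
}

#' Nucleotide and haplotype diversity
#'
#' @param aln A `"barcode_alignment"` (or character) matrix, n >= 2 rows.
#' @return List: `k` (mean pairwise nucleotide differences per sequence),
#'   `pi` (= k / L_used, per site), `Hd` (haplotype diversity
#'   n/(n-1) * (1 - sum p_i^2)), plus `L_used` and `n_haplotypes`.
#' @details `k` is computed from haplotype counts: sum over haplotype pairs
#'   of c_i c_j h_ij divided by n(n-1)/2, which is algebraically identical to
#'   the mean over all sequence pairs.
#' @export
diversity <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  stopifnot(n >= 2L)
  ht <- collapse_haplotypes(m)
  cnt <- ht$haplotypes$count
  hm <- hap_hamming(ht$haplotypes$sequence)
  npairs <- n * (n - 1) / 2
  k <- sum((cnt %o% cnt) * hm) / 2 / npairs
  p <- cnt / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  list(k = k, pi = k / ht$L_used, Hd = Hd,
       L_used = ht$L_used, n_haplotypes = nrow(ht$haplotypes))
}

#' Tajima's D constants
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 coefficients of Tajima's test, all
#' functions of the sample size only.
#'
#' @param n Sample size (>= 4 for the test).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S-1)). Negative values indicate an
#' excess of low-frequency polymorphism (e.g. population expansion).
#'
#' @param S Number of segregating sites (>= 1 for a defined value).
#' @param k Mean pairwise nucleotide differences.
#' @param n Sample size (>= 4).
#' @return The D statistic, or NA when S = 0 (undefined, not zero).
#' @export
tajimas_d <- function(S, k, n) {
  stopifnot(n >= 4)
  if (S == 0) return(NA_real_)
  cst <- tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# log |S(n, k)| for unsigned Stirling numbers of the first kind, row n.
# Recurrence |S(n,k)| = |S(n-1,k-1)| + (n-1)|S(n-1,k)| run in log space.
# Cached per n within a session.
.stirling_cache <- new.env(parent = emptyenv())

logsumexp2 <- function(x, y) {
  if (is.infinite(x) && x < 0) return(y)
  if (is.infinite(y) && y < 0) return(x)
  m <- max(x, y)
  m + log(exp(x - m) + exp(y - m))
}

#' Log unsigned Stirling numbers of the first kind (one row)
#'
#' @param n Row index (>= 1).
#' @return Numeric vector of length `n`: log|S(n, k)| for k = 1..n.
#' @export
stirling_log_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- 0  # n = 1: |S(1,1)| = 1
  if (n > 1L) {
    for (m in 2:n) {
      prev <- c(-Inf, row)            # |S(m-1, k-1)|, k = 1..m
      carry <- c(row, -Inf) + log(m - 1)  # (m-1)|S(m-1, k)|
      row <- mapply(logsumexp2, prev, carry)
    }
  }
  .stirling_cache[[key]] <- row
  row
}

#' Fu's Fs
#'
#' Fs = ln(S' / (1 - S')) where S' = Pr(K >= k_obs | theta) under the Ewens
#' sampling formula, with theta estimated by the mean pairwise difference k
#' (the pi-estimator). Computed in log space via unsigned Stirling numbers of
#' the first kind so that large samples (n in the hundreds) are stable.
#' Strongly negative values indicate an excess of alleles (recent
#' expansion).
#'
#' @param n Sample size (>= 2).
#' @param k_obs Observed number of haplotypes (alleles).
#' @param theta Scaled mutation parameter, > 0 (conventionally the observed
#'   mean pairwise difference k).
#' @return The Fs statistic; NA when `k_obs = 1` (S' = 1, Fs undefined).
#' @export
fus_fs <- function(n, k_obs, theta) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (theta <= 0) stop("theta must be > 0")
  if (k_obs == 1L) return(NA_real_)
  lrow <- stirling_log_row(n)
  j <- seq_len(n)
  lterm <- lrow + j * log(theta) - sum(log(theta + 0:(n - 1)))
  lse <- function(v) { m <- max(v); if (is.infinite(m)) return(-Inf); m + log(sum(exp(v - m))) }
  logSp <- lse(lterm[j >= k_obs])
  log1mSp <- lse(lterm[j < k_obs])
  logSp - log1mSp
}

#' Diversity and neutrality report per group
#'
#' One row per group with the full set of indices: n, S, k, pi, Eta(s), Hd,
#' Fu's Fs and Tajima's D (undefined statistics reported as NA).
#'
#' @param alignments Named list of `"barcode_alignment"` matrices, one per
#'   group (e.g. per species).
#' @return data.frame with columns `group`, `n`, `S`, `k`, `pi`, `Eta_s`,
#'   `Hd`, `n_haplotypes`, `fu_Fs`, `tajima_D`.
#' @export
diversity_report <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L)
  rows <- lapply(names(alignments), function(g) {
    aln <- alignments[[g]]
    n <- nrow(aln)
    stopifnot(n >= 2L)
    ss <- segregating_sites(aln)
    dv <- diversity(aln)
    D <- if (n >= 4) tajimas_d(ss$S, dv$k, n) else NA_real_
    Fs <- if (dv$k > 0) fus_fs(n, dv$n_haplotypes, dv$k) else NA_real_
    data.frame(group = g, n = n, S = ss$S, k = dv$k, pi = dv$pi,
               Eta_s = ss$Eta_s, Hd = dv$Hd, n_haplotypes = dv$n_haplotypes,
               fu_Fs = Fs, tajima_D = D, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
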
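test_that("K2P matches the closed form on enumerated toy pairs", {
  # identical sequences
  r0 <- k2p_distance(strrep("ACGT", 150), strrep("ACGT", 150))
  expect_equal(r0$distance, 0)
  expect_equal(c(r0$P, r0$Q), c(0, 0))

  # one transition in ten sites: P = 0.1, Q = 0 -> -0.5 ln(0.8)
  r1 <- k2p_distance("AAAAAAAAAA", "GAAAAAAAAA")
  expect_equal(r1$distance, oracle_k2p(0.1, 0), tolerance = 1e-12)
  expect_equal(r1$transitions, 1L)
  expect_equal(r1$transversions, 0L)

  # mixed: 2 transitions + 1 transversion over 12 sites
  a <- "AAAACCCCGGGG"
  b <- "GAAATCCCGGGC"  # A->G ts, C->T ts, G->C tv
  r2 <- k2p_distance(a, b)
  expect_equal(r2$P, 2 / 12)
  expect_equal(r2$Q, 1 / 12)
  expect_equal(r2$distance, oracle_k2p(2 / 12, 1 / 12), tolerance = 1e-12)

  # swapping the sequences leaves d unchanged
  expect_equal(k2p_distance(b, a)$distance, r2$distance)

  # pairwise deletion: N and gap columns excluded
  r3 <- k2p_distance("ANG-AAAAAA", "AAGCAAAAAG")
  expect_equal(r3$valid_sites, 8L)

  # saturation is flagged undefined, not clamped
  r4 <- k2p_distance(strrep("A", 20), strrep("G", 20))
  expect_false(r4$defined)
  expect_true(is.na(r4$distance))
  expect_error(k2p_distance("NNNN", "ACGT"), "no comparable sites")
})

test_that("distance matrix agrees with per-pair K2P and with ape's K80", {
  set.seed(21)
  ds <- emit_dataset(synthetic_config(K = 2, n_per = 6, L = 300, seed = 21))
  aln <- as_alignment(ds$coi5)
  dm <- distance_matrix(aln)
  seqs <- alignment_to_seqs(aln)
  for (pr in list(c(1, 2), c(3, 9), c(5, 12))) {
    expect_equal(dm$d[pr[1], pr[2]],
                 k2p_distance(seqs[[pr[1]]], seqs[[pr[2]]])$distance,
                 tolerance = 1e-12)
  }
  # independent implementation cross-check
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[rownames(dm$d), colnames(dm$d)]),
               tolerance = 1e-9)
  # symmetric, zero diagonal, permutation-equivariant
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  perm <- sample(nrow(aln))
  dm2 <- distance_matrix(aln[perm, , drop = FALSE])
  expect_equal(dm2$d, dm$d[perm, perm])
})

test_that("K2P dominates the raw p-distance whenever defined", {
  set.seed(8)
  for (rep in 1:20) {
    L <- 90
    a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    b <- a
    mut <- sample(L, 12)
    b[mut] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    r <- k2p_distance(a, b)
    if (r$defined) {
      p <- (r$transitions + r$transversions) / r$valid_sites
      expect_gte(r$distance + 1e-12, p)
    }
  }
})

test_that("summary, histogram and ranked distances are consistent", {
  # 3-sequence toy: mean equals arithmetic mean of the three distances
  aln <- aln_of(a = "AAAAAAAAAA", b = "GAAAAAAAAA", c = "GGAAAAAAAA")
  dm <- distance_matrix(aln)
  s <- summarize_distances(dm)
  vals <- c(dm$d["a", "b"], dm$d["a", "c"], dm$d["b", "c"])
  expect_equal(s$mean, mean(vals))
  expect_equal(s$min, min(vals))
  expect_equal(s$max, max(vals))
  expect_equal(s$n_pairs, 3L)

  idm <- distance_matrix(aln_of(a = "ACGT", b = "ACGT", c = "ACGT"))
  si <- summarize_distances(idm)
  expect_equal(c(si$min, si$max, si$mean), c(0, 0, 0))

  # a single pair at d ~ 0.03 falls in the [0.03, 0.035) bin
  one <- distance_matrix(aln_of(a = strrep("A", 100),
                                b = paste0(strrep("A", 97), "GGG")))
  expect_true(one$d[1, 2] > 0.03 && one$d[1, 2] < 0.035)
  h <- distance_histogram(one, 0.005)
  expect_equal(h$count[h$bin_low == 0.03], 1L)
  expect_error(distance_histogram(one, 0), "bin_width")

  dm2 <- distance_matrix(random_aln(8, 60))
  h2 <- distance_histogram(dm2, 0.01)
  expect_equal(sum(h2$count), summarize_distances(dm2)$n_pairs)
  rk <- ranked_distances(dm2)
  expect_true(all(diff(rk) >= 0))
  expect_length(rk, summarize_distances(dm2)$n_pairs)
})

test_that("intra/inter summary exposes the barcode gap", {
  # hand-enumerable 4-sequence, 2-cluster toy
  aln <- aln_of(a1 = strrep("A", 100),
                a2 = paste0("G", strrep("A", 99)),
                b1 = paste0(strrep("C", 10), strrep("A", 90)),
                b2 = paste0(strrep("C", 10), "G", strrep("A", 89)))
  dm <- distance_matrix(aln)
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  s <- intra_inter_summary(dm, part)
  max_intra <- max(dm$d["a1", "a2"], dm$d["b1", "b2"])
  min_inter <- min(dm$d["a1", "b1"], dm$d["a1", "b2"],
                   dm$d["a2", "b1"], dm$d["a2", "b2"])
  expect_equal(s$gap, min_inter - max_intra)
  expect_length(s$intra, 2L)
  expect_length(s$inter, 4L)

  # one cluster only: no inter distribution, gap undefined
  s1 <- intra_inter_summary(dm, setNames(rep("X", 4), names(part)))
  expect_length(s1$inter, 0L)
  expect_true(is.na(s1$gap))

  # generator contract: bimodal with an empty range between modes
  ds <- emit_dataset(synthetic_config(K = 2, n_per = 8, L = 600, theta = 1,
                                      d_between = 0.12, seed = 9))
  dmx <- distance_matrix(as_alignment(ds$coi5))
  truth_part <- setNames(ds$truth$cluster, ds$truth$id)
  sx <- intra_inter_summary(dmx, truth_part)
  expect_gt(min(sx$inter), max(sx$intra))
  expect_gt(sx$gap, 0)
})

test_that("K2P approaches Jukes-Cantor when transitions are not favoured", {
  # kappa = 0.5 makes all substitution types equally likely
  set.seed(33)
  cfg <- synthetic_config(K = 1, n_per = 2, L = 6000, theta = 0.001,
                          d_between = 0.05, kappa = 0.5, seed = 33)
  anc <- simulate_cluster_ancestors(cfg, L = 6000)
  root <- charvec(anc[[1]])
  der <- barcodeOTU:::mutate_charvec(root, 300, kappa = 0.5)
  r <- k2p_distance(root, der)
  p <- (r$transitions + r$transversions) / r$valid_sites
  jc <- -3 / 4 * log(1 - 4 / 3 * p)
  expect_equal(r$distance, jc, tolerance = 0.02)
})
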
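test_that("single linkage equals the connected components of the threshold graph", {
  # all-zero distances: one cluster
  dm0 <- distance_matrix(aln_of(a = "ACGT", b = "ACGT", c = "ACGT"))
  p0 <- single_linkage_clusters(dm0, 0.01)
  expect_length(unique(unclass(p0)), 1L)

  # random 5-sequence toys against the boolean-closure oracle
  set.seed(14)
  for (rep in 1:25) {
    n <- 5
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0, 0.1)
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    dm <- structure(list(labels = letters[1:n], d = d,
                         undefined_pairs = data.frame()), class = "k2p_dist")
    thr <- stats::runif(1, 0.01, 0.09)
    got <- single_linkage_clusters(dm, thr)
    want <- oracle_components(d, thr)
    # same partition up to labeling
    expect_equal(length(unique(unclass(got))), length(unique(want)))
    expect_true(all(tapply(want, unclass(got), function(x) length(unique(x))) == 1))
  }
  expect_error(single_linkage_clusters(
    structure(list(labels = character(0),
                   d = matrix(numeric(0), 0, 0),
                   undefined_pairs = data.frame()), class = "k2p_dist"), 0.02),
    "empty")
})

test_that("raising the threshold never increases the cluster count", {
  set.seed(3)
  dm <- distance_matrix(random_aln(10, 120))
  ks <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
               function(t) length(unique(unclass(single_linkage_clusters(dm, t)))),
               numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("well-separated synthetic clusters are recovered exactly", {
  ds <- emit_dataset(synthetic_config(K = 4, n_per = 8, L = 600, theta = 1,
                                      d_between = 0.12, seed = 17))
  dm <- distance_matrix(as_alignment(ds$coi5))
  part <- single_linkage_clusters(dm, 0.05)
  truth <- setNames(ds$truth$cluster, ds$truth$id)[names(part)]
  expect_length(unique(unclass(part)), 4L)
  # perfect agreement: each inferred cluster maps to exactly one true cluster
  expect_true(all(tapply(truth, unclass(part), function(x) length(unique(x))) == 1))
  expect_true(all(tapply(unclass(part), truth, function(x) length(unique(x))) == 1))

  # every inferred cluster is separated from the rest by more than the threshold
  cs <- cluster_summaries(dm, part)
  expect_true(all(cs$nn_dist > 0.05))
})

test_that("cluster summaries match exhaustive pair enumeration", {
  aln <- aln_of(a1 = strrep("A", 100),
                a2 = paste0("G", strrep("A", 99)),
                b1 = paste0(strrep("C", 8), strrep("A", 92)),
                b2 = paste0(strrep("C", 8), "GG", strrep("A", 90)))
  dm <- distance_matrix(aln)
  part <- structure(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  cs <- cluster_summaries(dm, part,
                          metadata = data.frame(
                            id = c("a1", "a2", "b1", "b2"),
                            host = c("cotton", "okra", "cotton", "cotton"),
                            country = c("PK", "PK", "IN", "PK")))
  expect_equal(cs$max_intra[cs$cluster_id == "A"], dm$d["a1", "a2"])
  expect_equal(cs$nn_dist[cs$cluster_id == "A"],
               min(dm$d[c("a1", "a2"), c("b1", "b2")]))
  expect_equal(cs$nn_cluster, c("B", "A"))
  expect_equal(cs$hosts[cs$cluster_id == "A"], "cotton;okra")
  expect_equal(cs$countries[cs$cluster_id == "B"], "IN;PK")

  # identical members: max_intra 0; single cluster: nn fields absent
  dmi <- distance_matrix(aln_of(x = "ACGT", y = "ACGT"))
  csi <- cluster_summaries(dmi, c(x = "X", y = "X"))
  expect_equal(csi$max_intra, 0)
  expect_true(is.na(csi$nn_dist))
})

test_that("consensus barcode applies majority and IUPAC tie rules", {
  expect_equal(consensus_barcode(aln_of("ACGT", "ACGT", "ACGT")), "ACGT")
  # {A,A,G} -> A ; ties -> minimal IUPAC code ; all-missing -> N
  maj <- rbind(c("A"), c("A"), c("G"))
  expect_equal(consensus_barcode(maj), "A")
  ties <- rbind(c("A", "A", "N"), c("G", "C", "N"))
  expect_equal(consensus_barcode(ties), "RMN")
  # idempotent
  set.seed(2)
  aln <- random_aln(10, 40)
  cons <- consensus_barcode(aln)
  expect_equal(consensus_barcode(as_alignment(c(c1 = cons))), cons)
  # independent per-column tally
  tally <- vapply(seq_len(40), function(j) {
    tab <- sort(table(unclass(aln)[, j]), decreasing = TRUE)
    if (length(tab) == 1L || tab[1] > tab[2]) names(tab)[1] else NA_character_
  }, character(1))
  got <- charvec(cons)
  expect_true(all(got[!is.na(tally)] == tally[!is.na(tally)]))
})

test_that("reference assignment separates assigned, novel and tied queries", {
  set.seed(41)
  panel <- c(speciesA = random_coding_sequence(300),
             speciesB = random_coding_sequence(300))
  # identical to a panel entry
  r <- assign_to_reference(panel[["speciesA"]], panel)
  expect_equal(r$status, "assigned")
  expect_equal(r$species, "speciesA")
  expect_equal(r$dist_to_nearest_reference, 0)

  # ~1% mutated query stays assigned to its source species
  q <- paste0(barcodeOTU:::mutate_charvec(charvec(panel[["speciesB"]]), 3, 4),
              collapse = "")
  r2 <- assign_to_reference(q, panel, threshold = 0.035)
  expect_equal(r2$status, "assigned")
  expect_equal(r2$species, "speciesB")

  # deeply divergent (~12%) query is flagged novel with its distance reported
  far <- paste0(barcodeOTU:::mutate_charvec(charvec(panel[["speciesA"]]), 36, 4),
                collapse = "")
  r3 <- assign_to_reference(far, panel, threshold = 0.035)
  expect_equal(r3$status, "novel")
  expect_equal(r3$species, "NOVEL")
  expect_gt(r3$dist_to_nearest_reference, 0.035)

  # exact tie -> unresolved with both species named
  tie_panel <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA")
  r4 <- assign_to_reference("AAAAAAAAAG", tie_panel, threshold = 0.2)
  expect_equal(r4$status, "unresolved")
  expect_setequal(r4$species, c("s1", "s2"))
})

test_that("translation table supports many-to-one maps and flags conflicts", {
  part <- structure(c(x1 = "c1", x2 = "c1", y1 = "c2", z1 = "c3"),
                    threshold = 0.02, linkage = "single",
                    class = "otu_partition")
  mk <- function(sp, st = "assigned", d = 0.01)
    list(species = sp, dist_to_nearest_reference = d, status = st)
  tt <- build_translation_table(
    part,
    c(x1 = "c1", y1 = "c2", z1 = "c3"),
    list(x1 = mk("Asia II 7"), y1 = mk("Asia II 7"),
         z1 = mk("NOVEL", "novel", 0.137)))
  expect_equal(nrow(tt), 3L)
  expect_equal(tt$coi3_species[tt$coi5_cluster_id %in% c("c1", "c2")],
               rep("Asia II 7", 2))
  expect_equal(tt$status[tt$coi5_cluster_id == "c3"], "novel")

  # cluster with no representative is unresolved
  tt2 <- build_translation_table(part, c(x1 = "c1"), list(x1 = mk("sp")))
  expect_equal(tt2$status[tt2$coi5_cluster_id == "c2"], "unresolved")

  # conflicting representatives raise an error naming both species
  expect_error(build_translation_table(
    part, c(x1 = "c1", x2 = "c1"),
    list(x1 = mk("spA"), x2 = mk("spB"))), "spA.*spB|spB.*spA")
})
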
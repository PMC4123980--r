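test_that("Fitch counting matches the textbook cases", {
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  # invariant column contributes 0
  expect_equal(fitch_length(tr, aln_of(t1 = "A", t2 = "A", t3 = "A", t4 = "A")), 0L)
  # A,A,G,G on ((1,2),(3,4)): one change
  expect_equal(fitch_length(tr, aln_of(t1 = "A", t2 = "A", t3 = "G", t4 = "G")), 1L)
  # A,G,A,G needs two
  expect_equal(fitch_length(tr, aln_of(t1 = "A", t2 = "G", t3 = "A", t4 = "G")), 2L)
  # missing data is a wildcard, never forcing a change
  expect_equal(fitch_length(tr, aln_of(t1 = "A", t2 = "N", t3 = "G", t4 = "-")), 1L)
  expect_error(fitch_length(tr, aln_of(t1 = "A", t2 = "A", t3 = "A")),
               "leaf without sequence")
})

test_that("Fitch score equals brute-force state minimisation and is unrooted", {
  set.seed(51)
  for (rep in 1:5) {
    aln <- random_aln(6, 12)
    tr <- ape::unroot(ape::rtree(6, tip.label = rownames(aln)))
    got <- fitch_length(tr, aln)
    expect_equal(got, oracle_fitch(tr, aln))
    # invariance under re-rooting
    rooted <- ape::root(tr, outgroup = rownames(aln)[rep], resolve.root = TRUE)
    expect_equal(fitch_length(rooted, aln), got)
  }
  # phangorn cross-check on a larger case
  aln <- random_aln(10, 40)
  tr <- ape::unroot(ape::rtree(10, tip.label = rownames(aln)))
  pd <- phangorn::phyDat(ape::as.DNAbin(
    do.call(rbind, strsplit(tolower(alignment_to_seqs(aln)), ""))))
  expect_equal(fitch_length(tr, aln),
               phangorn::parsimony(tr, pd, method = "fitch"))
})

test_that("parsimony search finds the exhaustive optimum", {
  # 4 taxa: all 3 topologies scanned
  aln4 <- aln_of(t1 = "AAAAAA", t2 = "AAAGGG", t3 = "GGGAAA", t4 = "GGGGGG")
  ps4 <- parsimony_search(aln4)
  expect_equal(ps4$method, "exhaustive")
  sc_all <- vapply(phangorn::allTrees(4, rooted = FALSE,
                                      tip.label = rownames(aln4)),
                   fitch_length, numeric(1), aln = aln4)
  expect_equal(ps4$score, as.integer(min(sc_all)))

  # heuristic equals exhaustive on <= 7-taxon synthetic data
  set.seed(61)
  ds <- emit_dataset(synthetic_config(K = 3, n_per = 3, L = 120, theta = 2,
                                      d_between = 0.15, seed = 61))
  aln <- build_alignment(ds$coi5)[1:7, , drop = FALSE]
  ex <- parsimony_search(aln, seed = 1)
  he <- parsimony_search(aln, seed = 2, exhaustive_limit = 4L, n_starts = 5L)
  expect_equal(ex$method, "exhaustive")
  expect_equal(he$method, "heuristic")
  expect_equal(he$score, ex$score)

  # fewer than 4 taxa: the trivial topology
  ps3 <- parsimony_search(aln[1:3, , drop = FALSE])
  expect_equal(ps3$method, "trivial")
  expect_equal(length(ps3$trees[[1]]$tip.label), 3L)
})

test_that("the true generating topology scores no worse than random trees", {
  set.seed(71)
  sim <- simulate_coalescent_sample(random_coding_sequence(300), 8, theta = 6)
  aln <- as_alignment(sim$sequences)
  true_score <- fitch_length(sim$tree, aln)
  rand_scores <- vapply(1:10, function(i)
    fitch_length(ape::rtopology(8, tip.label = names(sim$sequences)), aln),
    numeric(1))
  expect_true(all(true_score <= rand_scores))
})

test_that("bootstrap support is reproducible and saturates on strong signal", {
  # two clusters separated by many fixed differences
  ds <- emit_dataset(synthetic_config(K = 2, n_per = 3, L = 300, theta = 0.5,
                                      d_between = 0.2, seed = 5))
  aln <- as_alignment(ds$coi5)
  bt <- bootstrap_support(aln, reps = 20, seed = 9)
  # the split between the two clusters is in every replicate
  split_node <- ape::getMRCA(bt, ds$truth$id[ds$truth$cluster == "C2"])
  sup <- bt$node.label[split_node - length(bt$tip.label)]
  expect_equal(sup, 100)

  # reps = 1: supports are 0 or 100
  b1 <- bootstrap_support(aln, reps = 1, seed = 2)
  expect_true(all(b1$node.label %in% c(0, 100)))

  # identical seed, identical supports
  b2 <- bootstrap_support(aln, reps = 5, seed = 4)
  b3 <- bootstrap_support(aln, reps = 5, seed = 4)
  expect_identical(b2$node.label, b3$node.label)
})

test_that("NJ recovers additive trees and validates its input", {
  # additive 5-taxon matrix from a known tree
  txt <- "((t1:0.02,t2:0.03):0.05,(t3:0.01,t4:0.04):0.06,t5:0.07);"
  tr <- ape::read.tree(text = txt)
  D <- ape::cophenetic.phylo(tr)
  dm <- structure(list(labels = rownames(D), d = D,
                       undefined_pairs = data.frame()), class = "k2p_dist")
  nj <- neighbor_joining(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), ape::unroot(tr))), 0)

  # undefined entries are refused
  dm_bad <- dm
  dm_bad$undefined_pairs <- data.frame(id_a = "t1", id_b = "t2")
  expect_error(neighbor_joining(dm_bad), "undefined")

  # 2-cluster synthetic data: clusters are monophyletic after outgroup rooting
  ds <- emit_dataset(synthetic_config(K = 2, n_per = 4, L = 402, theta = 1,
                                      d_between = 0.15, seed = 13))
  dmx <- distance_matrix(as_alignment(ds$coi5))
  njx <- suppressWarnings(neighbor_joining(dmx))
  c2 <- ds$truth$id[ds$truth$cluster == "C2"]
  rooted <- ape::root(njx, outgroup = ds$truth$id[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c2))
})

test_that("Newick I/O round-trips topology, lengths and support labels", {
  tr <- ape::rtree(6)
  tr$node.label <- c(NA, 99, 87, 62, 50)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr))), 0)
  expect_error(root_on_outgroup(tr, "missing_tip"), "not in tree")
})
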
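# End-to-end orchestration: qc -> distances -> delimit -> translate ->
# popgen -> network -> tree -> geo, writing plain-text artifacts to an
# output directory. Deterministic stages are bit-identical across reruns
# with the same configuration; every run writes a manifest with the config
# hash and per-file checksums.

#' Pipeline run configuration
#'
#' @param coi5_fasta Path to the COI-5' (barcode) FASTA.
#' @param metadata Path to the metadata TSV (columns id, marker, country,
#'   province, region, host, species_label).
#' @param coi3_fasta Optional COI-3' FASTA for representative specimens.
#' @param panel_fasta Optional species reference panel FASTA (species names
#'   as headers) for COI-3' assignment.
#' @param min_len Barcode-compliance length bound (strict >), default 500.
#' @param coi5_threshold COI-5' OTU delimitation threshold, default 0.02.
#' @param coi3_threshold COI-3' species threshold, default 0.035.
#' @param bootstrap_reps Parsimony bootstrap replicates (0 disables).
#' @param seed RNG seed for the stochastic stages.
#' @param region_level Metadata column for the composition test.
#' @return A `"run_config"` list.
#' @export
run_config <- function(coi5_fasta, metadata, coi3_fasta = NULL,
                       panel_fasta = NULL, min_len = 500L,
                       coi5_threshold = 0.02, coi3_threshold = 0.035,
                       bootstrap_reps = 0L, seed = 1L,
                       region_level = "province") {
  stopifnot(coi5_threshold > 0, coi5_threshold < 1,
            coi3_threshold > 0, coi3_threshold < 1)
  structure(list(coi5_fasta = coi5_fasta, metadata = metadata,
                 coi3_fasta = coi3_fasta, panel_fasta = panel_fasta,
                 min_len = as.integer(min_len),
                 coi5_threshold = coi5_threshold,
                 coi3_threshold = coi3_threshold,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), region_level = region_level),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full barcoding pipeline
#'
#' Executes the stages in dependency order and writes TSV/FASTA/Newick
#' artifacts plus a run log and a manifest (config hash and md5 per file).
#' A stage failure aborts with the stage name in the error message.
#'
#' @param config A `"run_config"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the principal in-memory results:
#'   `alignment`, `distances`, `partition`, `summaries`, `translation`,
#'   `diversity`, `networks`, `tree`, `composition`, `files`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- c(paste("config_hash:", config_hash(config)),
                 paste("seed:", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character(0)

  ## qc
  res_qc <- stage("qc", {
    seqs <- read_fasta(config$coi5_fasta)
    md <- read_metadata(config$metadata)
    flt <- filter_barcode_compliant(seqs, config$min_len)
    qc <- lapply(flt$kept, function(s)
      tryCatch(translation_qc(s), error = function(e)
        list(pass = FALSE, reasons = conditionMessage(e))))
    pass <- vapply(qc, `[[`, logical(1), "pass")
    report <- data.frame(
      id = names(seqs),
      barcode_compliant = names(seqs) %in% names(flt$kept),
      translation_pass = ifelse(names(seqs) %in% names(flt$kept)[pass], TRUE,
                         ifelse(names(seqs) %in% names(flt$kept), FALSE, NA)),
      stringsAsFactors = FALSE)
    kept <- flt$kept[pass]
    if (length(kept) < 2L) stop("fewer than 2 sequences pass QC")
    aln <- build_alignment(kept)
    list(aln = aln, metadata = md, report = report)
  })
  files <- c(files, tsv(res_qc$report, "qc_report.tsv"))
  md <- res_qc$metadata
  aln <- res_qc$aln

  ## distances
  dm <- stage("dist", distance_matrix(aln))
  files <- c(files, write_distances(dm, file.path(out_dir, "distances_long.tsv"),
                                    "long"))
  files <- c(files, tsv(distance_histogram(dm), "distance_histogram.tsv"))

  ## delimit
  part <- stage("delimit", single_linkage_clusters(dm, config$coi5_threshold))
  summaries <- stage("delimit", cluster_summaries(dm, part, md))
  files <- c(files, tsv(data.frame(id = names(part),
                                   cluster = unclass(part),
                                   stringsAsFactors = FALSE),
                        "partition.tsv"))
  files <- c(files, tsv(summaries, "cluster_summaries.tsv"))
  cons <- stage("delimit", {
    vapply(sort(unique(unclass(part))), function(cc)
      consensus_barcode(aln[names(part)[part == cc], , drop = FALSE]),
      character(1))
  })
  p <- file.path(out_dir, "consensus_coi5.fasta")
  write_fasta(cons, p); files <- c(files, p)

  ## translate (optional)
  translation <- NULL
  species_of_cluster <- NULL
  if (!is.null(config$coi3_fasta) && !is.null(config$panel_fasta)) {
    translation <- stage("translate", {
      coi3 <- read_fasta(config$coi3_fasta)
      panel <- read_fasta(config$panel_fasta)
      aln3 <- build_alignment(c(coi3, panel), pad = TRUE)
      s3 <- alignment_to_seqs(aln3)
      panel_aln <- s3[names(panel)]
      asg <- lapply(names(coi3), function(id)
        assign_to_reference(s3[[id]], panel_aln, config$coi3_threshold))
      names(asg) <- names(coi3)
      rep_map <- unclass(part)[names(coi3)]
      rep_map <- rep_map[!is.na(rep_map)]
      build_translation_table(part, rep_map, asg[names(rep_map)])
    })
    files <- c(files, tsv(translation, "translation_table.tsv"))
    species_of_cluster <- setNames(translation$coi3_species,
                                   translation$coi5_cluster_id)
  }

  ## species assignment per specimen: translated species where available,
  ## otherwise the OTU label
  assignments <- stage("translate", {
    sp <- unclass(part)
    if (!is.null(species_of_cluster)) {
      tr <- species_of_cluster[sp]
      sp <- ifelse(is.na(tr), sp, tr)
      names(sp) <- names(part)
    }
    sp
  })

  ## popgen
  div <- stage("popgen", {
    groups <- split(names(assignments), assignments)
    groups <- groups[lengths(groups) >= 2L]
    alns <- lapply(groups, function(ids) aln[ids, , drop = FALSE])
    if (length(alns)) diversity_report(alns) else NULL
  })
  if (!is.null(div)) files <- c(files, tsv(div, "diversity_report.tsv"))

  ## network
  networks <- stage("network", {
    groups <- split(names(assignments), assignments)
    groups <- groups[lengths(groups) >= 2L]
    lapply(groups, function(ids) {
      ht <- collapse_haplotypes(aln[ids, , drop = FALSE], metadata = md)
      mst <- minimum_spanning_tree(haplotype_diff_matrix(ht))
      nodes <- annotate_network(mst, ht, md)
      list(haplotypes = ht, mst = mst, nodes = nodes)
    })
  })
  for (g in names(networks)) {
    safe <- gsub("[^A-Za-z0-9_]+", "_", g)
    files <- c(files, write_network(
      networks[[g]]$mst,
      file.path(out_dir, paste0("network_", safe, "_edges.tsv")),
      networks[[g]]$nodes,
      file.path(out_dir, paste0("network_", safe, "_nodes.tsv"))))
  }

  ## tree on cluster consensus sequences
  tree <- stage("tree", {
    if (length(cons) >= 4L) {
      aln_cons <- as_alignment(cons)
      best <- parsimony_search(aln_cons, seed = config$seed)
      tr <- best$trees[[1]]
      if (config$bootstrap_reps > 0L) {
        tr <- bootstrap_support(aln_cons, reps = config$bootstrap_reps,
                                seed = config$seed, tree = tr)
      }
      tr
    } else NULL
  })
  if (!is.null(tree)) {
    p <- file.path(out_dir, "consensus_parsimony.nwk")
    write_newick(tree, p); files <- c(files, p)
  }

  ## geo
  compo <- stage("geo", {
    lvl <- config$region_level
    if (lvl %in% names(md)) composition(assignments, md, lvl) else NULL
  })
  chi <- NULL
  if (!is.null(compo)) {
    files <- c(files, tsv(as.data.frame.matrix(compo$counts),
                          "composition_counts.tsv"))
    if (nrow(compo$counts) >= 2L && ncol(compo$counts) >= 2L &&
        all(rowSums(compo$counts) > 0) && all(colSums(compo$counts) > 0)) {
      chi <- chi_square(compo$counts)
      log_lines <- c(log_lines, sprintf("chi_square: %.4f df=%d p=%.3g",
                                        chi$statistic, chi$df, chi$p_value))
    }
  }

  ## log + manifest
  log_lines <- c(log_lines,
                 paste("sequences_in:", length(read_fasta(config$coi5_fasta))),
                 paste("sequences_aligned:", nrow(aln)),
                 paste("clusters:", length(unique(unclass(part)))))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         config_hash = config_hash(config),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(alignment = aln, distances = dm, partition = part,
                 summaries = summaries, translation = translation,
                 diversity = div, networks = networks, tree = tree,
                 composition = compo, chi_square = chi, files = files))
}
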
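# Species-by-region composition, chi-square heterogeneity tests, and
# survey-to-survey range comparisons.

#' Species composition percentages
#'
#' @param assignments Named character vector: specimen id -> species (NA or
#'   missing ids are tallied as unresolved and excluded from percentages).
#' @param metadata data.frame with `id` and the region column named by
#'   `level`.
#' @param level Region column to group by (`"country"`, `"province"`,
#'   `"region"`), or NULL for a single overall column.
#' @return List: `counts` (species x region integer table),
#'   `percent` (per-region percentages over assigned specimens; columns sum
#'   to 100), `n_unresolved`.
#' @export
composition <- function(assignments, metadata, level = "province") {
  ids <- metadata$id
  sp <- assignments[ids]
  unresolved <- is.na(sp)
  reg <- if (is.null(level)) rep("all", length(ids)) else {
    if (!level %in% names(metadata)) stop("metadata has no column '", level, "'")
    metadata[[level]]
  }
  counts <- table(species = sp[!unresolved], region = reg[!unresolved])
  percent <- sweep(counts, 2L, colSums(counts), "/") * 100
  list(counts = counts, percent = percent,
       n_unresolved = sum(unresolved))
}

#' Pearson chi-square test of composition heterogeneity
#'
#' The plain Pearson statistic sum((O-E)^2/E) on a species-by-region count
#' table, without continuity correction; expected counts come from the
#' margins.
#'
#' @param table Integer matrix/table with >= 2 rows and >= 2 columns.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  stopifnot(nrow(tab) >= 2L, ncol(tab) >= 2L, all(tab >= 0))
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr)) stop("empty row margin: ",
                    paste(rownames(tab)[zr], collapse = ", "))
  if (any(zc)) stop("empty column margin: ",
                    paste(colnames(tab)[zc], collapse = ", "))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Presence/absence range change between two surveys
#'
#' Compares per-species regional presence between an earlier and a later
#' survey, the data statement behind range-shift claims.
#'
#' @param assignments_t1,assignments_t2 Named species assignment vectors for
#'   the two surveys.
#' @param metadata_t1,metadata_t2 Metadata for each survey (columns `id` and
#'   `region_key`).
#' @param region_key Region column shared by the two surveys.
#' @return data.frame `species`, `region`, `survey1`, `survey2`, `change` in
#'   `{stable_present, stable_absent, gained, lost}`.
#' @export
range_comparison <- function(assignments_t1, metadata_t1,
                             assignments_t2, metadata_t2,
                             region_key = "region") {
  for (md in list(metadata_t1, metadata_t2)) {
    if (!region_key %in% names(md)) stop("metadata has no column '", region_key, "'")
  }
  v1 <- unique(metadata_t1[[region_key]])
  v2 <- unique(metadata_t2[[region_key]])
  if (length(v1) && length(v2) && !setequal(v1, v2)) {
    stop("region vocabularies differ between surveys: ",
         paste(c(setdiff(v1, v2), setdiff(v2, v1)), collapse = ", "))
  }
  pres <- function(assign, md) {
    sp <- assign[md$id]
    ok <- !is.na(sp)
    unique(data.frame(species = unname(sp[ok]), region = md[[region_key]][ok],
                      stringsAsFactors = FALSE))
  }
  p1 <- pres(assignments_t1, metadata_t1)
  p2 <- pres(assignments_t2, metadata_t2)
  r1 <- unique(p1$region); r2 <- unique(p2$region)
  species <- sort(unique(c(p1$species, p2$species)))
  regions <- sort(unique(c(r1, r2)))
  grid <- expand.grid(species = species, region = regions,
                      stringsAsFactors = FALSE)
  in1 <- paste(grid$species, grid$region) %in% paste(p1$species, p1$region)
  in2 <- paste(grid$species, grid$region) %in% paste(p2$species, p2$region)
  grid$survey1 <- in1
  grid$survey2 <- in2
  grid$change <- ifelse(in1 & in2, "stable_present",
                 ifelse(!in1 & !in2, "stable_absent",
                 ifelse(in2, "gained", "lost")))
  grid
}
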
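# Data model: long-format site x species records, site metadata, inventory
# summaries, taxon tallies.

#' Normalize species names to canonical binomials
#'
#' Trims and collapses whitespace, replaces underscores with spaces,
#' capitalizes the genus and lower-cases the remaining tokens, then applies
#' an optional synonym map. Names matching any of `invalid_patterns`
#' (defaults catch single-token names and morphospecies markers such as
#' "sp." or "indet.") are flagged invalid rather than dropped, so callers
#' decide what to do with them.
#'
#' @param raw character vector of raw names.
#' @param synonym_map optional named character vector mapping normalized
#'   names to accepted names; applied after normalization.
#' @param invalid_patterns character vector of regular expressions marking a
#'   name as non-binomial / indeterminate.
#' @return data.frame with columns `raw`, `canonical`, `valid`.
#' @examples
#' normalize_species_name("casearia_sylvestris ")
#' normalize_species_name("Cedrela sp.")
#' @export
normalize_species_name <- function(raw, synonym_map = NULL,
                                   invalid_patterns = c(
                                     "^[^ ]+$",          # single token
                                     "(^| )sp{1,2}\\.?( |$)",
                                     "indet", "(^| )cf\\.?( |$)",
                                     "(^| )aff\\.?( |$)")) {
  stopifnot(is.character(raw), all(nzchar(trimws(raw))))
  x <- gsub("_", " ", raw)
  x <- gsub("\\s+", " ", trimws(x))
  norm1 <- function(s) {
    toks <- strsplit(tolower(s), " ", fixed = TRUE)[[1]]
    toks[1] <- paste0(toupper(substring(toks[1], 1, 1)),
                      substring(toks[1], 2))
    paste(toks, collapse = " ")
  }
  x <- vapply(x, norm1, character(1), USE.NAMES = FALSE)
  if (!is.null(synonym_map)) {
    hit <- x %in% names(synonym_map)
    x[hit] <- unname(synonym_map[x[hit]])
  }
  valid <- !Reduce(`|`, lapply(invalid_patterns,
                               function(p) grepl(p, x, ignore.case = TRUE)))
  data.frame(raw = raw, canonical = x, valid = valid,
             stringsAsFactors = FALSE)
}

#' Construct a community table from long-format records
#'
#' Validates and canonicalizes three-column (site, species, abundance)
#' records: species names are normalized, invalid names and non-positive
#' abundances dropped (counted), and duplicate (site, species) rows summed.
#' Aggregation is order-independent: the result is sorted by site then
#' species.
#'
#' @param records data.frame with columns `site_id`, `species_name`,
#'   `abundance` (positive real count or importance value).
#' @param synonym_map,invalid_patterns passed to
#'   [normalize_species_name()]; `invalid_patterns = NULL` keeps defaults.
#' @param normalize normalize names? Set FALSE for already-canonical input.
#' @return data.frame of class `community_table` with attributes
#'   `n_dropped_invalid`, `n_dropped_nonpositive`, `n_aggregated`.
#' @export
community_table <- function(records, synonym_map = NULL,
                            invalid_patterns = NULL, normalize = TRUE) {
  need <- c("site_id", "species_name", "abundance")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  rec <- records[need]
  rec$site_id <- as.character(rec$site_id)
  rec$species_name <- as.character(rec$species_name)
  rec$abundance <- as.numeric(rec$abundance)

  n_invalid <- 0L
  if (normalize) {
    args <- list(raw = rec$species_name, synonym_map = synonym_map)
    if (!is.null(invalid_patterns)) args$invalid_patterns <- invalid_patterns
    nm <- do.call(normalize_species_name, args)
    rec$species_name <- nm$canonical
    n_invalid <- sum(!nm$valid)
    rec <- rec[nm$valid, , drop = FALSE]
  }
  bad <- !is.finite(rec$abundance) | rec$abundance <= 0
  n_nonpos <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no valid records remain")

  agg <- stats::aggregate(abundance ~ site_id + species_name, data = rec,
                          FUN = sum)
  n_agg <- nrow(rec) - nrow(agg)
  agg <- agg[order(agg$site_id, agg$species_name), c("site_id",
                                                     "species_name",
                                                     "abundance")]
  rownames(agg) <- NULL
  structure(agg, class = c("community_table", "data.frame"),
            n_dropped_invalid = n_invalid,
            n_dropped_nonpositive = n_nonpos,
            n_aggregated = n_agg)
}

#' Read a three-column site x species table
#'
#' Ingests the long "three-column format" (site, species, abundance) from
#' CSV, TSV or XLSX (first sheet). Columns are identified by header keywords
#' (site / species|taxon / abundance|count|importance|individuals) or, when
#' no header matches, by position 1:3.
#'
#' @param path file path.
#' @param dialect one of "auto", "csv", "tsv", "xlsx"; "auto" guesses from
#'   the extension.
#' @inheritParams community_table
#' @return a [community_table()].
#' @export
read_community_table <- function(path, dialect = c("auto", "csv", "tsv",
                                                   "xlsx"),
                                 synonym_map = NULL,
                                 invalid_patterns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- switch(tolower(tools::file_ext(path)),
                      csv = "csv", tsv = "tsv", txt = "tsv",
                      xlsx = "xlsx", xls = "xlsx",
                      stop("cannot guess dialect from extension: ", path))
  raw <- switch(dialect,
    csv = read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    tsv = read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE),
    xlsx = as.data.frame(readxl::read_excel(path, sheet = 1),
                         stringsAsFactors = FALSE))
  if (ncol(raw) < 3L) stop("expected at least 3 columns in ", path)
  find_col <- function(patterns) {
    hits <- which(Reduce(`|`, lapply(patterns, function(p)
      grepl(p, names(raw), ignore.case = TRUE))))
    if (length(hits)) hits[1] else NA_integer_
  }
  i_site <- find_col("site|plot|inventory|local")
  i_sp <- find_col("spec|taxon|binom")
  i_ab <- find_col("abund|count|import|individ|n_ind|stems")
  idx <- c(i_site, i_sp, i_ab)
  if (anyNA(idx)) idx <- 1:3  # positional fallback
  rec <- raw[, idx]
  names(rec) <- c("site_id", "species_name", "abundance")
  community_table(rec, synonym_map = synonym_map,
                  invalid_patterns = invalid_patterns)
}

#' Write a community table as canonical long-format CSV
#' @param table a `community_table`.
#' @param path output path.
#' @export
write_community_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a site-metadata table
#'
#' Expects columns `site_id` and `biome`; coordinate columns
#' (`latitude`, `longitude`) and the climate covariates
#' (`mat`, `map_mm`, `p_seasonality`, `t_seasonality`, `dry_months`) are
#' optional and may contain missing values, which downstream climate models
#' drop with a warning.
#'
#' @param path CSV path.
#' @param community optional `community_table`; when given, checks that
#'   every site has exactly one metadata row.
#' @export
read_site_metadata <- function(path, community = NULL) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  site_metadata(md, community = community)
}

#' @rdname read_site_metadata
#' @param metadata data.frame of per-site metadata.
#' @export
site_metadata <- function(metadata, community = NULL) {
  if (!all(c("site_id", "biome") %in% names(metadata)))
    stop("metadata must have columns site_id and biome")
  metadata$site_id <- as.character(metadata$site_id)
  if (anyDuplicated(metadata$site_id))
    stop("duplicated site_id in metadata: ",
         paste(unique(metadata$site_id[duplicated(metadata$site_id)]),
               collapse = ", "))
  if (!is.null(community)) {
    missing <- setdiff(unique(community$site_id), metadata$site_id)
    if (length(missing))
      stop("sites without metadata: ", paste(missing, collapse = ", "))
  }
  structure(metadata, class = c("site_metadata", "data.frame"))
}

# biome label lookup for a set of sites; errors listing offenders
biome_of <- function(site_ids, metadata) {
  lab <- metadata$biome[match(site_ids, metadata$site_id)]
  if (anyNA(lab))
    stop("sites without biome label: ",
         paste(site_ids[is.na(lab)], collapse = ", "))
  lab
}

#' Tally species, genera and (optionally) families
#'
#' Distinct species and genus counts, overall and per biome. The genus is
#' the first token of the canonical binomial. Family counts need a
#' genus-to-family map and are reported as NA ("unavailable") without one.
#'
#' @param table a `community_table`.
#' @param metadata optional `site_metadata` providing biome labels; required
#'   for per-biome breakdowns.
#' @param family_map optional named character vector, genus -> family.
#' @return list of class `taxon_tallies`: `n_species`, `n_genera`,
#'   `n_families`, and `per_biome` data.frame when metadata given.
#' @export
tally_taxa <- function(table, metadata = NULL, family_map = NULL) {
  stopifnot(inherits(table, "community_table"))
  genus <- function(sp) sub(" .*$", "", sp)
  count <- function(sp) {
    sp <- unique(sp)
    g <- unique(genus(sp))
    fam <- if (is.null(family_map)) NA_integer_ else
      length(unique(stats::na.omit(unname(family_map[g]))))
    c(n_species = length(sp), n_genera = length(g), n_families = fam)
  }
  out <- list(overall = count(table$species_name))
  if (!is.null(metadata)) {
    lab <- biome_of(table$site_id, metadata)
    per <- t(vapply(split(table$species_name, lab), count,
                    c(n_species = 0L, n_genera = 0L, n_families = 0L)))
    out$per_biome <- data.frame(biome = rownames(per), per,
                                row.names = NULL)
  }
  structure(out, class = "taxon_tallies")
}

#' Species checklist with per-biome site frequencies
#'
#' One row per species; per-biome columns give the number of sites in that
#' biome where the species occurs, plus a total column.
#'
#' @inheritParams tally_taxa
#' @export
species_checklist <- function(table, metadata) {
  stopifnot(inherits(table, "community_table"))
  lab <- biome_of(table$site_id, metadata)
  tab <- table(table$species_name, lab)
  out <- data.frame(species_name = rownames(tab),
                    as.data.frame.matrix(tab), check.names = FALSE,
                    row.names = NULL)
  out$total_sites <- rowSums(tab)
  out
}

#' Per-site inventory summaries from a community table
#'
#' S is the count of distinct species, N the summed abundance. Non-integer
#' totals (importance values) are kept as-is here; operations that need
#' integer counts round half-to-even and warn.
#'
#' @param table a `community_table`.
#' @export
inventory_summary <- function(table) {
  stopifnot(inherits(table, "community_table"))
  s <- split(table, table$site_id)
  data.frame(
    site_id = names(s),
    n_individuals = vapply(s, function(d) sum(d$abundance), 0),
    n_species = vapply(s, function(d) length(unique(d$species_name)), 0L),
    row.names = NULL)
}

#' @export
print.taxon_tallies <- function(x, ...) {
  cat("Taxon tallies:", x$overall["n_species"], "species,",
      x$overall["n_genera"], "genera,",
      if (is.na(x$overall["n_families"])) "families unavailable" else
        paste(x$overall["n_families"], "families"), "\n")
  if (!is.null(x$per_biome)) {
    print(x$per_biome, ...)
  }
  invisible(x)
}
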
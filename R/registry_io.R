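#' Read a donor genotype table
#'
#' Reads a tab-delimited donor table with header columns
#' `id`, `population`, `A`, `C`, `B`, `DRB1`, `DQB1`, where each locus cell
#' holds a genotype string (`"tokens+tokens"`, with `/` for allelic
#' ambiguity) and an empty cell means the locus was never typed. Donors
#' missing typing at HLA-A or HLA-B are excluded from analysis and itemized
#' in the exclusion report, mirroring the registry inclusion rule.
#'
#' @param path Path to the donor TSV.
#' @param table An `hla_expansion` table used to resolve low-resolution
#'   tokens. Defaults to an empty table (full allele names only).
#' @inheritParams parse_locus_genotype
#' @return A list with `donors` (tibble: `id`, `population`, plus one list
#'   column per locus holding `hla_genotype` objects or `NULL`) and
#'   `exclusions` (tibble: `row`, `id`, `reason`).
#' @export
read_donor_table <- function(path, table = empty_expansion_table(),
                             drop_null = TRUE,
                             single_as_homozygous = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("id", "population", hla_loci())
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("donor table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    stop("duplicate donor id(s): ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  }
  parse_donors(raw, table = table, drop_null = drop_null,
               single_as_homozygous = single_as_homozygous)
}

#' Parse donor genotype strings
#'
#' The string form of a registry (as produced by [simulate_registry()] or
#' read from disk) is a tibble of genotype strings; the parsed form carries
#' per-locus candidate pair sets ready for estimation. Donors missing HLA-A
#' or HLA-B typing are excluded and reported, not parsed.
#'
#' @param donors Tibble with columns `id`, `population` and one character
#'   column per locus (`NA` or `""` = untyped).
#' @inheritParams read_donor_table
#' @return As [read_donor_table()]: list of `donors` and `exclusions`.
#' @export
parse_donors <- function(donors, table = empty_expansion_table(),
                         drop_null = TRUE, single_as_homozygous = FALSE) {
  loci <- hla_loci()
  typed <- function(x) !is.na(x) & nzchar(x)
  miss_a <- !typed(donors$A)
  miss_b <- !typed(donors$B)
  excluded <- miss_a | miss_b
  reason <- dplyr::case_when(
    miss_a & miss_b ~ "missing HLA-A and HLA-B",
    miss_a ~ "missing HLA-A",
    miss_b ~ "missing HLA-B",
    .default = NA_character_
  )
  exclusions <- tibble::tibble(
    row = which(excluded),
    id = donors$id[excluded],
    reason = reason[excluded]
  )
  kept <- donors[!excluded, , drop = FALSE]

  ## genotype strings repeat heavily across a registry: parse each distinct
  ## cell once per locus and fan the result back out
  parse_col <- function(cells, locus, rows) {
    out <- vector("list", length(cells))
    idx <- which(typed(cells))
    if (!length(idx)) return(out)
    ucells <- unique(cells[idx])
    parsed_u <- lapply(ucells, function(s) {
      tryCatch(
        parse_locus_genotype(s, table, locus,
                             drop_null = drop_null,
                             single_as_homozygous = single_as_homozygous),
        error = function(e) {
          hit <- idx[cells[idx] == s][[1L]]
          stop("row ", rows[[hit]], " (id ", kept$id[[hit]], "): ",
               conditionMessage(e), call. = FALSE)
        }
      )
    })
    out[idx] <- parsed_u[match(cells[idx], ucells)]
    out
  }
  rows <- which(!excluded)
  parsed <- tibble::tibble(id = kept$id, population = kept$population)
  for (locus in loci) {
    parsed[[locus]] <- parse_col(kept[[locus]], locus, rows)
  }
  list(donors = parsed, exclusions = exclusions)
}

#' Write a donor genotype table
#'
#' Writes the string form of a registry (see [parse_donors()]) as TSV.
#'
#' @param donors Tibble of genotype strings (`id`, `population`, loci).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_donor_table <- function(donors, path) {
  readr::write_tsv(donors[, c("id", "population", hla_loci())], path,
                   na = "", progress = FALSE)
  invisible(path)
}

#' Populations large enough to report
#'
#' Registry analyses report only subpopulations with at least `min_size`
#' donors (1000 by default).
#'
#' @param donors Tibble with a `population` column (string or parsed form).
#' @param min_size Minimum donor count, inclusive.
#' @return Character vector of population labels meeting the threshold.
#' @export
#' @examples
#' d <- tibble::tibble(population = rep(c("P", "Q"), c(1000, 999)))
#' filter_reportable_populations(d)
filter_reportable_populations <- function(donors, min_size = 1000) {
  stopifnot(min_size >= 1)
  counts <- table(as.character(donors$population))
  sort(as.character(names(counts)[counts >= min_size]))
}

#' Registry coverage by population
#'
#' Computes the fraction of each population's census size present on the
#' registry, as a percentage to three decimals.
#'
#' @param registry_counts Tibble with columns `population`, `registry_count`.
#' @param census_counts Tibble with columns `population`, `census_count`.
#' @return Tibble with `population`, `registry_count`, `census_count`,
#'   `fraction_percent` (rounded to 3 decimals).
#' @export
#' @examples
#' summarize_populations(
#'   tibble::tibble(population = "BINWE", registry_count = 599410),
#'   tibble::tibble(population = "BINWE", census_count = 52424292)
#' )
summarize_populations <- function(registry_counts, census_counts) {
  out <- dplyr::left_join(registry_counts, census_counts, by = "population")
  if (anyNA(out$census_count)) {
    stop("missing census count for population(s): ",
         paste(out$population[is.na(out$census_count)], collapse = ", "),
         call. = FALSE)
  }
  if (any(out$census_count <= 0)) {
    stop("census counts must be positive", call. = FALSE)
  }
  dplyr::mutate(
    out,
    fraction_percent = round(.data$registry_count / .data$census_count * 100, 3)
  )
}

#' Write a frequency table report
#'
#' Applies the reporting cutoff, sorts by descending frequency (ties broken
#' by canonical key order) and writes CSV with frequencies rendered to a
#' fixed number of decimal places. The cutoff affects reporting only; keep
#' the full table for computation.
#'
#' @param table Tibble with a key column (first column) and `frequency`.
#' @param path Output path.
#' @param cutoff Minimum reported frequency (default `1e-4`).
#' @param decimals Decimal places for rendered frequencies (default 6).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path, cutoff = 1e-4, decimals = 6) {
  key <- names(table)[[1L]]
  kept <- table[table$frequency >= cutoff, , drop = FALSE]
  ord <- order(-kept$frequency, kept[[key]])
  kept <- kept[ord, , drop = FALSE]
  kept$frequency <- formatC(kept$frequency, format = "f", digits = decimals)
  readr::write_csv(kept, path, progress = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] tree (as returned by [neighbor_joining()] or
#'   [upgma()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
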
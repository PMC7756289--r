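## Singleton-based diversity statistics on maximum-a-posteriori (MAP)
## diplotype and phenotype assignments, and equal-sample-size resampling.

#' Most likely diplotype per donor
#'
#' Picks, for each donor, the haplotype pair with maximum posterior
#' probability; ties are broken by canonical pair order.
#'
#' @param posteriors Posterior tibble (`id`, `h1`, `h2`, `prob`).
#' @return Tibble with one row per donor: `id`, `h1`, `h2`, `prob`.
#' @export
map_diplotype <- function(posteriors) {
  if (nrow(posteriors) == 0L) stop("empty posterior set", call. = FALSE)
  post <- sort_posterior(posteriors)
  post[!duplicated(post$id), , drop = FALSE]
}

#' Most likely phenotype per donor
#'
#' Sums posterior probability over hypotheses mapping to the same unordered
#' genotype, so the two phasings of a double heterozygote reinforce one
#' phenotype, then takes the maximum; ties broken by canonical phenotype
#' order.
#'
#' @inheritParams map_diplotype
#' @return Tibble with one row per donor: `id`, `phenotype`, `prob`.
#' @export
map_phenotype <- function(posteriors) {
  if (nrow(posteriors) == 0L) stop("empty posterior set", call. = FALSE)
  df <- tibble::tibble(
    id = posteriors$id,
    phenotype = phenotype_of(posteriors$h1, posteriors$h2),
    prob = posteriors$prob
  )
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$id, .data$phenotype),
    prob = sum(.data$prob), .groups = "drop"
  )
  agg <- agg[order(match(agg$id, unique(df$id)), -agg$prob,
                   canonical_key(agg$phenotype)), ]
  agg[!duplicated(agg$id), , drop = FALSE]
}

#' Singleton diversity summary for one population
#'
#' Counts unique haplotypes among the `2N` haplotype copies implied by MAP
#' diplotypes and unique phenotypes among the `N` MAP phenotypes, the
#' percentage of each that occur exactly once (singletons), and the fraction
#' of the population whose phenotype is a singleton.
#'
#' @param diplotypes MAP diplotype tibble from [map_diplotype()].
#' @param phenotypes MAP phenotype tibble from [map_phenotype()].
#' @param population Population label for the summary row.
#' @return One-row tibble: `population`, `n_donors`,
#'   `n_unique_haplotypes`, `pct_haplotype_singletons`,
#'   `n_unique_phenotypes`, `pct_phenotype_singletons`,
#'   `pct_population_phenotype_singletons`.
#' @export
singleton_summary <- function(diplotypes, phenotypes, population = "ALL") {
  n <- nrow(diplotypes)
  if (n == 0L) stop("empty population", call. = FALSE)
  stopifnot(nrow(phenotypes) == n)
  hap_counts <- table(c(diplotypes$h1, diplotypes$h2))
  ph_counts <- table(phenotypes$phenotype)
  n_uh <- length(hap_counts)
  n_sh <- sum(hap_counts == 1L)
  n_up <- length(ph_counts)
  n_sp <- sum(ph_counts == 1L)
  tibble::tibble(
    population = population,
    n_donors = n,
    n_unique_haplotypes = n_uh,
    pct_haplotype_singletons = 100 * n_sh / n_uh,
    n_unique_phenotypes = n_up,
    pct_phenotype_singletons = 100 * n_sp / n_up,
    pct_population_phenotype_singletons = 100 * n_sp / n
  )
}

#' Observed allele counts per locus
#'
#' Counts distinct alleles whose estimated frequency exceeds `threshold`
#' at each locus, for each population's posterior, plus a pooled `"All"`
#' row over the combined posteriors.
#'
#' @param posteriors Named list of posterior tibbles, one per population.
#' @param threshold Minimum frequency for an allele to count as observed
#'   (defaults to the internal pruning floor; the choice of a reporting
#'   threshold is configurable).
#' @return Tibble with `population` and one count column per locus in
#'   [hla_loci()] order.
#' @export
observed_allele_counts <- function(posteriors, threshold = FREQ_FLOOR) {
  stopifnot(is.list(posteriors), !is.null(names(posteriors)))
  count_one <- function(post) {
    vapply(hla_loci(), function(l) {
      f <- allele_frequencies(post, l)
      sum(f$frequency > threshold)
    }, 0L)
  }
  rows <- lapply(posteriors, count_one)
  pooled <- count_one(dplyr::bind_rows(lapply(names(posteriors), function(p) {
    post <- posteriors[[p]]
    post$id <- paste(p, post$id, sep = ":")
    post
  })))
  counts <- do.call(rbind, c(rows, list(All = pooled)))
  dplyr::bind_cols(
    tibble::tibble(population = c(names(posteriors), "All")),
    tibble::as_tibble(counts)
  )
}

#' Fraction of catalogued alleles observed
#'
#' Percentage of the alleles known to the nomenclature catalogue that are
#' observed in a dataset, as printed in registry coverage summaries.
#'
#' @param observed Number of distinct alleles observed.
#' @param known Number of alleles in the catalogue at the same resolution.
#' @param decimals Decimal places (default 2).
#' @return Percentage, rounded.
#' @export
#' @examples
#' fraction_of_known(356, 3720)
fraction_of_known <- function(observed, known, decimals = 2) {
  stopifnot(known > 0, observed >= 0)
  round(100 * observed / known, decimals)
}

#' Equal-sample-size diversity comparison by subsampling
#'
#' Draws `reps` random samples of `n` donors without replacement from a
#' population's MAP assignments and computes a singleton statistic per
#' draw: `"haplotype_singletons"` (percentage of the sample's unique
#' haplotypes occurring once) or `"phenotype_singletons"` (percentage of
#' sampled donors whose phenotype is unique within the sample). Reports the
#' median and 2.5/97.5 percentile bounds.
#'
#' @param diplotypes MAP diplotype tibble from [map_diplotype()].
#' @param phenotypes MAP phenotype tibble from [map_phenotype()] (needed for
#'   the phenotype statistic).
#' @param statistic One of `"haplotype_singletons"`,
#'   `"phenotype_singletons"`.
#' @param n Donors per sample (population must be at least this large).
#' @param reps Number of random samples.
#' @param seed Integer seed.
#' @return One-row tibble: `statistic`, `median`, `ci_low`, `ci_high`,
#'   `n_per_sample`, `n_reps`, `seed`.
#' @export
subsample_statistic_ci <- function(diplotypes, phenotypes = NULL,
                                   statistic = c("haplotype_singletons",
                                                 "phenotype_singletons"),
                                   n = 1000, reps = 10000, seed) {
  statistic <- match.arg(statistic)
  N <- nrow(diplotypes)
  if (N < n) {
    stop("population size ", N, " is smaller than the sample size ", n,
         call. = FALSE)
  }
  if (statistic == "haplotype_singletons") {
    levs <- unique(c(diplotypes$h1, diplotypes$h2))
    i1 <- match(diplotypes$h1, levs)
    i2 <- match(diplotypes$h2, levs)
    nbins <- length(levs)
    stat_fn <- function(idx) {
      counts <- tabulate(c(i1[idx], i2[idx]), nbins)
      100 * sum(counts == 1L) / sum(counts > 0L)
    }
  } else {
    if (is.null(phenotypes)) {
      stop("phenotypes are required for the phenotype statistic",
           call. = FALSE)
    }
    stopifnot(nrow(phenotypes) == N)
    ip <- match(phenotypes$phenotype, unique(phenotypes$phenotype))
    nbins <- max(ip)
    stat_fn <- function(idx) {
      counts <- tabulate(ip[idx], nbins)
      100 * sum(counts == 1L) / length(idx)
    }
  }
  vals <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) stat_fn(sample.int(N, n)), 0)
  })
  q <- stats::quantile(vals, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(
    statistic = statistic,
    median = q[[1L]], ci_low = q[[2L]], ci_high = q[[3L]],
    n_per_sample = as.integer(n), n_reps = as.integer(reps),
    seed = as.integer(seed)
  )
}
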
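#' Generate a truth population of five-locus haplotypes
#'
#' Builds a known haplotype universe with frequencies drawn from a symmetric
#' Dirichlet, the ground truth a synthetic registry is sampled from. Alleles
#' at each locus are drawn from rank-skewed (Zipf-like, weight 1/rank) pools,
#' so haplotypes share common alleles — the structural stand-in for linkage
#' disequilibrium that makes block-wise estimation non-trivial.
#'
#' @param n_haplotypes Number of distinct haplotypes (>= 2).
#' @param alleles_per_locus Pool size per locus: a single integer or a named
#'   vector over [hla_loci()].
#' @param concentration Dirichlet concentration; small values give skewed,
#'   registry-like frequency distributions, large values near-uniform ones.
#' @param seed Integer seed; the truth is deterministic given all arguments.
#' @param population Population label attached to the truth.
#' @return A tibble of class `hla_truth` with columns `haplotype` (alleles
#'   joined by `~` in [block_loci()] order) and `frequency` (sums to 1),
#'   with attributes `population` and `seed`.
#' @export
#' @examples
#' generate_truth(10, 4, concentration = 1, seed = 1)
generate_truth <- function(n_haplotypes, alleles_per_locus,
                           concentration = 0.5, seed,
                           population = "SIM") {
  stopifnot(n_haplotypes >= 2, concentration > 0)
  loci <- block_loci()
  if (length(alleles_per_locus) == 1L) {
    alleles_per_locus <- stats::setNames(rep(alleles_per_locus, 5L), loci)
  }
  alleles_per_locus <- alleles_per_locus[loci]
  if (any(is.na(alleles_per_locus)) || any(alleles_per_locus < 1)) {
    stop("alleles_per_locus must cover all five loci with values >= 1",
         call. = FALSE)
  }
  if (n_haplotypes > prod(alleles_per_locus)) {
    stop("n_haplotypes exceeds the number of distinct haplotypes the ",
         "allele pools can form", call. = FALSE)
  }
  withr::with_seed(seed, {
    pools <- lapply(loci, function(l) {
      m <- alleles_per_locus[[l]]
      render_allele(rep(l, m), seq_len(m), rep(1L, m), rep(NA_character_, m))
    })
    names(pools) <- loci
    draw <- function(k) {
      cols <- lapply(loci, function(l) {
        m <- length(pools[[l]])
        sample(pools[[l]], k, replace = TRUE, prob = 1 / seq_len(m))
      })
      do.call(paste, c(cols, sep = "~"))
    }
    haps <- draw(n_haplotypes)
    for (tries in seq_len(1000L)) {
      dup <- duplicated(haps)
      if (!any(dup)) break
      haps[dup] <- draw(sum(dup))
    }
    if (anyDuplicated(haps)) {
      stop("could not draw ", n_haplotypes, " distinct haplotypes; ",
           "enlarge alleles_per_locus", call. = FALSE)
    }
    g <- stats::rgamma(n_haplotypes, shape = concentration, rate = 1)
    if (sum(g) <= 0) g <- rep(1, n_haplotypes)
    out <- tibble::tibble(haplotype = haps, frequency = g / sum(g))
    out <- out[order(-out$frequency, out$haplotype), ]
    attr(out, "population") <- population
    attr(out, "seed") <- seed
    class(out) <- c("hla_truth", class(out))
    out
  })
}

## haplotype strings -> matrix of alleles, columns in block_loci() order
split_haplotypes <- function(haplotype) {
  m <- do.call(rbind, strsplit(haplotype, "~", fixed = TRUE))
  colnames(m) <- block_loci()[seq_len(ncol(m))]
  m
}

#' Sample fully typed donors from a truth population
#'
#' Each donor receives two haplotypes drawn i.i.d. from the truth frequencies
#' (Hardy-Weinberg random mating); per-locus genotypes are written as
#' unambiguous two-field strings.
#'
#' @param truth An `hla_truth` table from [generate_truth()].
#' @param n Number of donors (> 0).
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated donor ids.
#' @return Tibble of donor genotype strings (`id`, `population`, loci
#'   columns), with attribute `diplotypes` recording the true haplotype pair
#'   per donor.
#' @export
sample_donors <- function(truth, n, seed, id_prefix = "D") {
  stopifnot(n > 0)
  pop <- attr(truth, "population") %||% "SIM"
  H <- split_haplotypes(truth$haplotype)
  withr::with_seed(seed, {
    i1 <- sample.int(nrow(truth), n, replace = TRUE, prob = truth$frequency)
    i2 <- sample.int(nrow(truth), n, replace = TRUE, prob = truth$frequency)
    donors <- tibble::tibble(
      id = sprintf("%s%06d", id_prefix, seq_len(n)),
      population = pop
    )
    for (locus in colnames(H)) {
      a <- H[i1, locus]
      b <- H[i2, locus]
      swap <- allele_key(b) < allele_key(a)
      donors[[locus]] <- paste(ifelse(swap, b, a), ifelse(swap, a, b),
                               sep = "+")
    }
    donors <- donors[, c("id", "population", hla_loci())]
    attr(donors, "diplotypes") <- tibble::tibble(
      id = donors$id,
      h1 = pmin(truth$haplotype[i1], truth$haplotype[i2]),
      h2 = pmax(truth$haplotype[i1], truth$haplotype[i2])
    )
    donors
  })
}

#' Define a typing-era profile
#'
#' A profile describes one recruitment era of a registry: which loci were
#' routinely typed (HLA-A and -B always are), the probability that a typed
#' allele is reported as an ambiguity group rather than a single allele, and
#' the fraction of donors recruited in that era.
#'
#' @param name Profile label.
#' @param loci Loci typed in this era; must include `"A"` and `"B"`.
#' @param ambiguity_rate Per-allele probability of ambiguous reporting.
#' @param weight Fraction of donors assigned to this era.
#' @return A list of class `typing_profile`.
#' @export
typing_profile <- function(name, loci, ambiguity_rate = 0, weight = 1) {
  loci <- as.character(loci)
  if (!all(c("A", "B") %in% loci)) {
    stop("typing profile '", name, "' must type HLA-A and HLA-B",
         call. = FALSE)
  }
  if (!all(loci %in% hla_loci())) {
    stop("unknown locus in profile '", name, "'", call. = FALSE)
  }
  stopifnot(ambiguity_rate >= 0, ambiguity_rate <= 1, weight >= 0)
  structure(list(name = name, loci = loci,
                 ambiguity_rate = ambiguity_rate, weight = weight),
            class = "typing_profile")
}

#' Default typing-era mix
#'
#' A four-era mix emulating the history of a long-running registry: an early
#' serology-like era typed only at A/B with frequent ambiguity, intermediate
#' eras adding DRB1 and then C, and a recent high-resolution era typing all
#' five loci with little ambiguity.
#'
#' @return List of [typing_profile()] objects with weights summing to 1.
#' @export
default_era_profiles <- function() {
  list(
    typing_profile("early_ab",   c("A", "B"),                    0.50, 0.25),
    typing_profile("ab_drb1",    c("A", "B", "DRB1"),            0.20, 0.25),
    typing_profile("acb_drb1",   c("A", "C", "B", "DRB1"),       0.10, 0.20),
    typing_profile("full_5loc",  hla_loci(),                     0.05, 0.30)
  )
}

#' Build a first-field expansion table for an allele universe
#'
#' Groups the given two-field alleles by locus and first field, producing one
#' code per group (e.g. `"A*01"`) whose expansion is every allele of that
#' group in the universe. Used both to inject ambiguity when degrading
#' synthetic typings and to resolve those same tokens in the estimator, so
#' injected ambiguity always contains the true allele.
#'
#' @param alleles Character vector of two-field allele names, or an
#'   `hla_truth` table (its haplotype alleles are used).
#' @return An `hla_expansion` table.
#' @export
build_expansion_table <- function(alleles) {
  if (inherits(alleles, "hla_truth")) {
    alleles <- unique(as.vector(split_haplotypes(alleles$haplotype)))
  }
  p <- parse_allele_name(unique(alleles))
  key <- paste0(p$locus, "*", formatC(p$field1, width = 2, flag = "0"))
  groups <- split(p$allele, key)
  locus <- vapply(groups, function(g) parse_allele_name(g[[1]])$locus, "")
  expansion_table(names(groups), locus, groups, version = "synthetic")
}

#' Degrade fully typed donors through typing-era profiles
#'
#' Assigns each donor to an era by profile weight, removes loci the era did
#' not type, and with probability `ambiguity_rate` replaces a typed allele
#' with the slash-joined expansion of its ambiguity group from `table`
#' (which by construction contains the true allele).
#'
#' @param donors Donor genotype-string tibble from [sample_donors()].
#' @param profiles List of [typing_profile()] objects; weights are
#'   normalized to sum to 1.
#' @param table An `hla_expansion` table supplying ambiguity groups.
#' @param seed Integer seed.
#' @return Donor tibble of the same shape with degraded typings and an
#'   `era` attribute recording each donor's profile name.
#' @export
degrade_typing <- function(donors, profiles, table, seed) {
  weights <- vapply(profiles, function(p) p$weight, 0)
  if (sum(weights) <= 0) stop("profile weights must sum to > 0", call. = FALSE)
  for (p in profiles) {
    if (!inherits(p, "typing_profile")) {
      stop("profiles must be typing_profile objects", call. = FALSE)
    }
  }
  ## allele -> slash-joined ambiguity group (first matching code)
  group_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(table))) {
    g <- paste(table$alleles[[i]], collapse = "/")
    for (a in table$alleles[[i]]) {
      if (is.null(group_of[[a]])) assign(a, g, envir = group_of)
    }
  }
  n <- nrow(donors)
  withr::with_seed(seed, {
    era <- sample.int(length(profiles), n, replace = TRUE,
                      prob = weights / sum(weights))
    out <- donors
    for (locus in hla_loci()) {
      typed_here <- vapply(profiles, function(p) locus %in% p$loci, TRUE)[era]
      rates <- vapply(profiles, function(p) p$ambiguity_rate, 0)[era]
      cells <- out[[locus]]
      sides <- strsplit(cells, "+", fixed = TRUE)
      a1 <- vapply(sides, `[`, "", 1L)
      a2 <- vapply(sides, `[`, "", 2L)
      amb1 <- stats::runif(n) < rates
      amb2 <- stats::runif(n) < rates
      rep1 <- vapply(a1, function(a) {
        if (is.null(group_of[[a]])) a else group_of[[a]]
      }, "", USE.NAMES = FALSE)
      rep2 <- vapply(a2, function(a) {
        if (is.null(group_of[[a]])) a else group_of[[a]]
      }, "", USE.NAMES = FALSE)
      cells <- paste(ifelse(amb1, rep1, a1), ifelse(amb2, rep2, a2),
                     sep = "+")
      cells[!typed_here] <- NA_character_
      out[[locus]] <- cells
    }
    attr(out, "era") <- vapply(profiles, function(p) p$name, "")[era]
    attr(out, "diplotypes") <- attr(donors, "diplotypes")
    out
  })
}

#' Simulate a registry with known truth
#'
#' Composes [generate_truth()], [sample_donors()], [build_expansion_table()]
#' and [degrade_typing()] into one reproducible draw. `config` may be a list
#' or a path to a YAML file with the same keys.
#'
#' @param config List (or YAML path) with keys `population`, `n_donors`,
#'   `n_haplotypes`, `alleles_per_locus`, `concentration`, optional
#'   `truth_seed` (defaults to `seed`, so different `seed`s can share one
#'   haplotype universe), and optional `profiles` (list of lists with
#'   `name`, `loci`, `ambiguity_rate`, `weight`; default
#'   [default_era_profiles()]).
#' @param seed Integer seed driving donor sampling and degradation.
#' @param dir If non-`NULL`, write `donors.tsv`, `truth.csv` and
#'   `expansion.tsv` into this directory.
#' @return List with `donors` (degraded string tibble), `truth`, `table`
#'   (expansion table), and `profiles`.
#' @export
simulate_registry <- function(config = list(), seed, dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    population = "SIM", n_donors = 1000L, n_haplotypes = 30L,
    alleles_per_locus = 8L, concentration = 0.5, truth_seed = NULL,
    profiles = NULL
  ), config)
  profiles <- if (is.null(cfg$profiles)) {
    default_era_profiles()
  } else if (inherits(cfg$profiles[[1]], "typing_profile")) {
    cfg$profiles
  } else {
    lapply(cfg$profiles, function(p) {
      typing_profile(p$name, unlist(p$loci), p$ambiguity_rate, p$weight)
    })
  }
  truth_seed <- cfg$truth_seed %||% seed
  truth <- generate_truth(cfg$n_haplotypes, cfg$alleles_per_locus,
                          concentration = cfg$concentration,
                          seed = truth_seed, population = cfg$population)
  table <- build_expansion_table(truth)
  clean <- sample_donors(truth, cfg$n_donors, seed = seed + 1L)
  donors <- degrade_typing(clean, profiles, table, seed = seed + 2L)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_donor_table(donors, file.path(dir, "donors.tsv"))
    writeLines(
      c(sprintf("# seed: %d truth_seed: %d", seed, truth_seed),
        "haplotype,frequency",
        sprintf("%s,%.12f", truth$haplotype, truth$frequency)),
      file.path(dir, "truth.csv")
    )
    write_expansion_table(table, file.path(dir, "expansion.tsv"))
  }
  list(donors = donors, truth = truth, table = table, profiles = profiles)
}

#' Read a truth frequency file written by [simulate_registry()]
#'
#' @param path Path to `truth.csv`.
#' @return Tibble with `haplotype`, `frequency`.
#' @export
read_truth_table <- function(path) {
  readr::read_csv(path, comment = "#", col_types = "cd", progress = FALSE)
}
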
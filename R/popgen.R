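## Between-population structure on frequency distributions: Nei's standard
## genetic distance, neighbor-joining and UPGMA trees, and shared top-k
## frequency profiles for heatmap-style clustering.

#' Nei's standard genetic distance between two frequency vectors
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))` with `Jxy = sum(x * y)`,
#' `Jx = sum(x^2)`, `Jy = sum(y^2)`. Vectors must be aligned on a shared
#' key universe (missing keys as 0) and each sum to 1. Distributions with
#' no shared support have infinite distance, returned as `Inf` — callers
#' must decide how to handle it (the tree builders refuse it).
#'
#' @param x,y Numeric frequency vectors of equal length.
#' @param tol Tolerance on each vector summing to 1.
#' @return Non-negative number, possibly `Inf`.
#' @export
#' @examples
#' nei_standard_distance(c(0.5, 0.5, 0), c(0.5, 0, 0.5)) # log(2)
nei_standard_distance <- function(x, y, tol = 1e-6) {
  stopifnot(length(x) == length(y))
  if (abs(sum(x) - 1) > tol || abs(sum(y) - 1) > tol) {
    stop("frequency vectors must each sum to 1", call. = FALSE)
  }
  jxy <- sum(x * y)
  if (jxy == 0) return(Inf)
  d <- -log(jxy / sqrt(sum(x^2) * sum(y^2)))
  max(d, 0) # guard tiny negative rounding for identical vectors
}

## Align a named list of frequency tables on the union key universe.
## Returns a populations x keys matrix.
align_frequency_tables <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  key <- names(tables[[1L]])[[1L]]
  universe <- sort(unique(unlist(lapply(tables, function(t) t[[key]]))))
  m <- vapply(tables, function(t) {
    v <- stats::setNames(numeric(length(universe)), universe)
    v[t[[key]]] <- t$frequency
    v
  }, numeric(length(universe)))
  t(m)
}

#' Pairwise Nei distance matrix between populations
#'
#' Computes [nei_standard_distance()] for every pair of populations on the
#' union haplotype universe of their frequency tables. Use the full
#' (uncut) tables: the 0.0001 cutoff is a presentation rule and removing
#' shared rare haplotypes can inflate or even break the distance.
#'
#' @param tables Named list of frequency tables (key column + `frequency`).
#' @return Symmetric matrix with zero diagonal; infinite entries are
#'   reported with the offending pair in a warning.
#' @export
pairwise_nei <- function(tables) {
  m <- align_frequency_tables(tables)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- nei_standard_distance(m[i, ], m[j, ])
    }
  }
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
    warning("infinite Nei distance for pair(s): ",
            paste(rownames(m)[bad[, 1L]], rownames(m)[bad[, 2L]],
                  sep = " / ", collapse = "; "),
            call. = FALSE)
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(d))) {
    stop("distance matrix contains non-finite entries; replace infinite ",
         "distances with an explicit finite cap before tree building",
         call. = FALSE)
  }
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via [ape::nj()]); any negative
#' estimated branch lengths are clamped to 0, as is conventional when NJ is
#' run on non-additive genetic distances.
#'
#' @param d Symmetric, non-negative, finite distance matrix with labels.
#' @return An unrooted [ape::phylo] tree with non-negative branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels", call. = FALSE)
  if (n == 2L) {
    tree <- ape::read.tree(
      text = sprintf("(%s:%.10g,%s:%.10g);",
                     rownames(d)[1L], d[1L, 2L] / 2,
                     rownames(d)[2L], d[1L, 2L] / 2)
    )
  } else {
    tree <- ape::nj(stats::as.dist(d))
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Pearson correlation distance between frequency profiles
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation between the
#' two rows, the distance used for heatmap-style clustering of shared
#' frequency profiles.
#'
#' @param profiles Numeric matrix (rows = populations or keys), or a wide
#'   tibble whose first column holds labels (as from [shared_profile()]).
#' @return Symmetric distance matrix in `[0, 2]` with zero diagonal.
#' @export
pearson_distance <- function(profiles) {
  if (is.data.frame(profiles)) {
    labels <- profiles[[1L]]
    profiles <- as.matrix(profiles[, -1L, drop = FALSE])
    rownames(profiles) <- labels
  }
  v <- apply(profiles, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance profile row(s): ",
         paste(rownames(profiles)[v == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(profiles))
  diag(d) <- 0
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration via [stats::hclust()]; returned as a
#' rooted [ape::phylo] tree whose leaf-to-root path lengths equal half the
#' merge heights. Ties are resolved deterministically by the input label
#' order.
#'
#' @inheritParams neighbor_joining
#' @return A rooted [ape::phylo] tree.
#' @export
upgma <- function(d) {
  d <- validate_distance_matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 labels", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Shared top-k frequency profiles across populations
#'
#' Takes the top `k` keys (haplotypes or alleles) of each population's
#' frequency table, removes duplicates, and tabulates every population's
#' frequency at each retained key (0 where absent). This is the input for
#' correlation-distance clustering of haplotype/allele sharing patterns;
#' with top-5 haplotypes over the registry's ten groups the union has 29
#' members.
#'
#' @param tables Named list of frequency tables.
#' @param k Top entries per population (5 for haplotype sharing, 20 for
#'   allele sharing in the registry analysis).
#' @return Wide tibble: `population` column plus one frequency column per
#'   retained key, in canonical key order.
#' @export
shared_profile <- function(tables, k) {
  if (!length(tables)) stop("no frequency tables supplied", call. = FALSE)
  key <- names(tables[[1L]])[[1L]]
  tops <- unique(unlist(lapply(tables, function(t) top_k(t, k)[[key]])))
  tops <- tops[order(canonical_key(tops))]
  m <- vapply(tables, function(t) {
    v <- stats::setNames(numeric(length(tops)), tops)
    hit <- intersect(t[[key]], tops)
    v[hit] <- t$frequency[match(hit, t[[key]])]
    v
  }, numeric(length(tops)))
  out <- tibble::as_tibble(t(m))
  dplyr::bind_cols(tibble::tibble(population = names(tables)), out)
}

#' Leaf orderings from UPGMA clustering of a shared profile
#'
#' Convenience wrapper reproducing the heatmap row/column orders: clusters
#' populations by correlation distance over their profiles and keys by
#' correlation distance over their across-population frequency vectors.
#'
#' @param profile Wide tibble from [shared_profile()].
#' @return List with `population_order` and `key_order` character vectors.
#' @export
profile_cluster_orders <- function(profile) {
  m <- as.matrix(profile[, -1L, drop = FALSE])
  rownames(m) <- profile$population
  pop_tree <- stats::hclust(stats::as.dist(pearson_distance(m)),
                            method = "average")
  key_tree <- stats::hclust(stats::as.dist(pearson_distance(t(m))),
                            method = "average")
  list(
    population_order = rownames(m)[pop_tree$order],
    key_order = colnames(m)[key_tree$order]
  )
}
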
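## Frequency tables derived from donor posteriors. All derivations use the
## full posterior; the 0.0001 reporting cutoff is applied only when writing
## reports (write_frequency_table()).

## Canonical sort key for a key column: haplotypes (contain "~"), phenotype
## strings (contain "|"), allele names, or arbitrary labels.
canonical_key <- function(x) {
  if (!length(x)) return(character())
  probe <- x[[1L]]
  if (grepl("|", probe, fixed = TRUE)) {
    ## memoized over unique phenotypes and their unique locus genotypes
    ux <- unique(x)
    parts <- strsplit(ux, "|", fixed = TRUE)
    ug <- unique(unlist(parts))
    gp <- strsplit(ug, "+", fixed = TRUE)
    al <- unique(unlist(gp))
    ak <- stats::setNames(safe_allele_key(al), al)
    gkey <- stats::setNames(
      vapply(gp, function(g) paste(ak[g], collapse = "+"), ""), ug
    )
    key <- vapply(parts, function(p) paste(gkey[p], collapse = "|"), "")
    key[match(x, ux)]
  } else if (grepl("~", probe, fixed = TRUE)) {
    hap_key(x)
  } else if (grepl(ALLELE_RX, probe)) {
    safe_allele_key(x)
  } else {
    x
  }
}

n_block_loci <- function(posteriors) {
  lengths(regmatches(posteriors$h1[[1L]],
                     gregexpr("~", posteriors$h1[[1L]], fixed = TRUE))) + 1L
}

#' Allele frequencies at one locus from donor posteriors
#'
#' Sums each donor's diplotype posterior over the allele carried at `locus`:
#' `f(a) = (1 / 2N) * sum of P(pair) * count of a at the locus in the pair`.
#'
#' @param posteriors Posterior tibble (`id`, `h1`, `h2`, `prob`).
#' @param locus One of [hla_loci()], present in the posterior's block.
#' @return Frequency table (`allele`, `frequency`), descending.
#' @export
allele_frequencies <- function(posteriors, locus) {
  if (nrow(posteriors) == 0L) stop("empty posterior set", call. = FALSE)
  pos <- match(locus, block_loci())
  if (is.na(pos) || pos > n_block_loci(posteriors)) {
    stop("locus ", locus, " is not in the posterior's block", call. = FALSE)
  }
  uh <- unique(c(posteriors$h1, posteriors$h2))
  al <- split_haplotypes(uh)[, pos]
  a1 <- al[match(posteriors$h1, uh)]
  a2 <- al[match(posteriors$h2, uh)]
  levs <- unique(al)
  n_donors <- length(unique(posteriors$id))
  f <- accumulate_freqs(match(a1, levs), match(a2, levs), posteriors$prob,
                        length(levs), n_donors)
  out <- tibble::tibble(allele = levs, frequency = f)
  out[order(-out$frequency, safe_allele_key(out$allele)), ]
}

#' Five-locus haplotype frequencies from donor posteriors
#'
#' The counting M-step over the final posteriors. Requires full five-locus
#' posteriors; the full table is returned — apply the 0.0001 reporting
#' cutoff only at output time via [write_frequency_table()].
#'
#' @inheritParams allele_frequencies
#' @return Frequency table (`haplotype`, `frequency`), descending.
#' @export
haplotype_frequencies <- function(posteriors) {
  if (nrow(posteriors) == 0L) stop("empty posterior set", call. = FALSE)
  if (n_block_loci(posteriors) != 5L) {
    stop("posteriors must cover the full five-locus block", call. = FALSE)
  }
  m_step(posteriors)
}

## Unordered five-locus genotype string for haplotype pairs: per locus the
## two carried alleles in canonical order joined by "+", loci joined by "|".
phenotype_of <- function(h1, h2) {
  uh <- unique(c(h1, h2))
  M <- split_haplotypes(uh)
  al <- unique(as.vector(M))
  ak <- stats::setNames(safe_allele_key(al), al)
  m1 <- M[match(h1, uh), , drop = FALSE]
  m2 <- M[match(h2, uh), , drop = FALSE]
  per_locus <- lapply(seq_len(ncol(M)), function(j) {
    a <- m1[, j]
    b <- m2[, j]
    swap <- ak[b] < ak[a]
    paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "+")
  })
  do.call(paste, c(per_locus, sep = "|"))
}

#' Phenotype frequencies from donor posteriors
#'
#' Maps each diplotype hypothesis to its unordered per-locus genotype (the
#' matching-relevant, phase-free summary) and adds the probabilities of
#' pairs mapping to the same phenotype; both phasings of a double
#' heterozygote reinforce a single phenotype. Normalized over donors.
#'
#' @inheritParams allele_frequencies
#' @return Frequency table (`phenotype`, `frequency`), descending.
#' @export
phenotype_frequencies <- function(posteriors) {
  if (nrow(posteriors) == 0L) stop("empty posterior set", call. = FALSE)
  if (n_block_loci(posteriors) != 5L) {
    stop("posteriors must cover the full five-locus block", call. = FALSE)
  }
  ph <- phenotype_of(posteriors$h1, posteriors$h2)
  n_donors <- length(unique(posteriors$id))
  agg <- rowsum(posteriors$prob, ph)
  out <- tibble::tibble(phenotype = rownames(agg),
                        frequency = as.vector(agg) / n_donors)
  out[order(-out$frequency, canonical_key(out$phenotype)), ]
}

#' Top-k entries of a frequency table
#'
#' @param table Frequency table (key column first, then `frequency`).
#' @param k Number of entries (> 0).
#' @return The `k` highest-frequency rows, ties broken by canonical key
#'   order.
#' @export
#' @examples
#' top_k(tibble::tibble(allele = c("A*01:01", "A*02:01", "A*03:01"),
#'                      frequency = c(0.3, 0.5, 0.2)), 2)
top_k <- function(table, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  key <- names(table)[[1L]]
  ord <- order(-table$frequency, canonical_key(table[[key]]))
  utils::head(table[ord, , drop = FALSE], k)
}
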
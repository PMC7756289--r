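# Shared fixtures and independent oracles used across test files.

# Total variation distance between two frequency tables on their union.
tvd <- function(est, truth) {
  key <- names(est)[[1L]]
  u <- union(est[[key]], truth[[key]])
  a <- est$frequency[match(u, est[[key]])]
  b <- truth$frequency[match(u, truth[[key]])]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  0.5 * sum(abs(a - b))
}

empty_table <- function() expansion_table(character(), character(), list())

# Parsed donors built directly from explicit haplotype pairs (block locus
# order A,B,C,DRB1,DQB1 joined by "~"), bypassing the simulator.
donors_from_diplotypes <- function(h1, h2, population = "T") {
  n <- length(h1)
  m1 <- do.call(rbind, strsplit(h1, "~", fixed = TRUE))
  m2 <- do.call(rbind, strsplit(h2, "~", fixed = TRUE))
  loci <- block_loci()[seq_len(ncol(m1))]
  d <- tibble::tibble(id = sprintf("T%04d", seq_len(n)),
                      population = population)
  for (j in seq_along(loci)) {
    d[[loci[j]]] <- paste(pmin(m1[, j], m2[, j]), pmax(m1[, j], m2[, j]),
                          sep = "+")
  }
  for (l in setdiff(hla_loci(), loci)) d[[l]] <- NA_character_
  parse_donors(d)$donors
}

# Independent brute-force enumeration of (A~B) pair hypotheses: nested
# loops over candidate genotypes and both phase assignments, deduplicated
# by sorted pair strings. Kept free of the package's vectorized path.
enumerate_pairs_bruteforce <- function(candA, candB) {
  seen <- character()
  for (i in seq_len(nrow(candA))) {
    for (j in seq_len(nrow(candB))) {
      for (phase in 1:2) {
        if (phase == 1) {
          p1 <- paste(candA[i, 1], candB[j, 1], sep = "~")
          p2 <- paste(candA[i, 2], candB[j, 2], sep = "~")
        } else {
          p1 <- paste(candA[i, 1], candB[j, 2], sep = "~")
          p2 <- paste(candA[i, 2], candB[j, 1], sep = "~")
        }
        pair <- paste(sort(c(p1, p2)), collapse = "|")
        seen <- union(seen, pair)
      }
    }
  }
  sort(seen)
}

# Multi-start maximizer of the multinomial-HWE log-likelihood over the
# frequency simplex, used as the independent MLE oracle on tiny instances.
# hyp: tibble with id, h1, h2 (the hypothesis universe); returns a named
# frequency vector over all haplotypes appearing in hyp.
hwe_mle_oracle <- function(hyp, starts = 25, seed = 99) {
  levs <- sort(unique(c(hyp$h1, hyp$h2)))
  i1 <- match(hyp$h1, levs)
  i2 <- match(hyp$h2, levs)
  d <- match(hyp$id, unique(hyp$id))
  mult <- ifelse(i1 == i2, 1, 2)
  nll <- function(theta) {
    f <- exp(theta - max(theta))
    f <- f / sum(f)
    p <- mult * f[i1] * f[i2]
    -sum(log(rowsum(p, d)))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(starts)) {
      th0 <- stats::rnorm(length(levs))
      o <- stats::optim(th0, nll, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
  })
  f <- exp(best$par - max(best$par))
  stats::setNames(f / sum(f), levs)
}
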
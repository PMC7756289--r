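## Block-wise EM for haplotype frequencies under Hardy-Weinberg equilibrium.
##
## Hypotheses and posteriors are tibbles with one row per (donor, unordered
## haplotype pair): columns id, h1, h2 (haplotype strings, canonically
## ordered h1 <= h2) and prob/w. Frequency tables are tibbles with columns
## haplotype, frequency.

FREQ_FLOOR <- 1e-15   # haplotype frequencies below this are pruned to 0
RESEED_FLOOR <- 1e-12 # floor applied to donors whose posterior collapses

## Sortable key for haplotype strings: per-allele keys joined, so ordering
## follows the allele total ordering position by position. Memoized over
## unique haplotypes (hypothesis frames repeat haplotypes heavily).
hap_key <- function(h) {
  uh <- unique(h)
  parts <- strsplit(uh, "~", fixed = TRUE)
  al <- unique(unlist(parts))
  ak <- stats::setNames(safe_allele_key(al), al)
  key <- vapply(parts, function(p) paste(ak[p], collapse = "~"), "")
  unname(key[match(h, uh)])
}

## Canonicalize unordered haplotype pairs given precomputed keys.
canonical_hap_pairs <- function(h1, h2, k1 = hap_key(h1), k2 = hap_key(h2)) {
  swap <- k2 < k1
  list(h1 = ifelse(swap, h2, h1), h2 = ifelse(swap, h1, h2),
       k1 = ifelse(swap, k2, k1), k2 = ifelse(swap, k1, k2))
}

## Sort a posterior frame per donor by descending probability, ties broken
## by canonical pair order.
sort_posterior <- function(post) {
  ord <- order(match(post$id, unique(post$id)), -post$prob,
               hap_key(post$h1), hap_key(post$h2))
  post[ord, , drop = FALSE]
}

#' Enumerate initial (A~B) haplotype pair hypotheses for one donor
#'
#' Lists every unordered pair of two-locus A~B haplotypes consistent with
#' some candidate genotype at HLA-A and some at HLA-B, including both phase
#' assignments for donors heterozygous at both loci, with uniform initial
#' probabilities.
#'
#' @param donor One row of the parsed donor tibble (see [parse_donors()]),
#'   or any list with `hla_genotype` elements `A` and `B`.
#' @return Tibble with columns `h1`, `h2`, `prob` (uniform).
#' @export
enumerate_initial_pairs <- function(donor) {
  gA <- if (is.data.frame(donor)) donor$A[[1L]] else donor$A
  gB <- if (is.data.frame(donor)) donor$B[[1L]] else donor$B
  if (is.null(gA) || is.null(gB)) {
    stop("donor must be typed at HLA-A and HLA-B", call. = FALSE)
  }
  ca <- gA$candidates
  cb <- gB$candidates
  ia <- rep(seq_len(nrow(ca)), each = nrow(cb))
  ib <- rep(seq_len(nrow(cb)), times = nrow(ca))
  h1 <- c(paste(ca[ia, 1L], cb[ib, 1L], sep = "~"),
          paste(ca[ia, 1L], cb[ib, 2L], sep = "~"))
  h2 <- c(paste(ca[ia, 2L], cb[ib, 2L], sep = "~"),
          paste(ca[ia, 2L], cb[ib, 1L], sep = "~"))
  cp <- canonical_hap_pairs(h1, h2)
  keep <- !duplicated(paste(cp$h1, cp$h2, sep = "|"))
  out <- tibble::tibble(h1 = cp$h1[keep], h2 = cp$h2[keep])
  out <- out[order(cp$k1[keep], cp$k2[keep]), ]
  out$prob <- 1 / nrow(out)
  out
}

## Initial hypothesis frame for all donors (A~B block). Vectorized across
## donors: stacks candidate matrices, crosses them with both phasings, then
## canonicalizes and deduplicates in one pass.
initial_hypotheses <- function(donors) {
  n <- nrow(donors)
  if (any(vapply(donors$A, is.null, TRUE)) ||
      any(vapply(donors$B, is.null, TRUE))) {
    stop("all donors must be typed at HLA-A and HLA-B", call. = FALSE)
  }
  caL <- lapply(donors$A, function(g) g$candidates)
  cbL <- lapply(donors$B, function(g) g$candidates)
  na <- vapply(caL, nrow, 0L)
  nb <- vapply(cbL, nrow, 0L)
  d <- rep.int(seq_len(n), na * nb)
  ia <- unlist(lapply(seq_len(n), function(i) {
    rep(seq_len(na[i]), each = nb[i])
  }))
  ib <- unlist(lapply(seq_len(n), function(i) {
    rep.int(seq_len(nb[i]), na[i])
  }))
  offA <- cumsum(c(0L, na))[d]
  offB <- cumsum(c(0L, nb))[d]
  CA <- do.call(rbind, caL)
  CB <- do.call(rbind, cbL)
  a1 <- CA[offA + ia, 1L]
  a2 <- CA[offA + ia, 2L]
  b1 <- CB[offB + ib, 1L]
  b2 <- CB[offB + ib, 2L]
  h1 <- c(paste(a1, b1, sep = "~"), paste(a1, b2, sep = "~"))
  h2 <- c(paste(a2, b2, sep = "~"), paste(a2, b1, sep = "~"))
  dd <- c(d, d)
  cp <- canonical_hap_pairs(h1, h2)
  keep <- !duplicated(paste(dd, cp$h1, cp$h2, sep = "\r"))
  dd <- dd[keep]
  ord <- order(dd, cp$k1[keep], cp$k2[keep])
  dd <- dd[ord]
  cnt <- tabulate(dd, nbins = n)
  tibble::tibble(
    id = donors$id[dd],
    h1 = cp$h1[keep][ord],
    h2 = cp$h2[keep][ord],
    w = 1 / cnt[dd]
  )
}

## Accumulate haplotype counts weighted by w into a frequency vector of
## length nh; each row contributes w to each of its two haplotype slots.
accumulate_freqs <- function(i1, i2, w, nh, n_donors) {
  v <- numeric(nh)
  s <- rowsum(c(w, w), c(i1, i2))
  v[as.integer(rownames(s))] <- s
  v / (2 * n_donors)
}

#' E-step: posterior over haplotype pair hypotheses
#'
#' Under Hardy-Weinberg equilibrium the probability of an unordered pair is
#' proportional to `2 f(h1) f(h2)` for heterozygous pairs and `f(h)^2` for
#' homozygous ones, normalized per donor. Haplotypes missing from `freqs`
#' count as frequency 0; donors whose hypotheses all get zero probability
#' are re-seeded with a small frequency floor and reported via a warning.
#'
#' @param pairs Tibble with columns `id`, `h1`, `h2`.
#' @param freqs Frequency table (`haplotype`, `frequency`).
#' @return Posterior tibble (`id`, `h1`, `h2`, `prob`), sorted per donor by
#'   descending probability with canonical tie-breaks.
#' @export
e_step <- function(pairs, freqs) {
  f <- stats::setNames(freqs$frequency, freqs$haplotype)
  f1 <- unname(f[pairs$h1])
  f2 <- unname(f[pairs$h2])
  f1[is.na(f1)] <- 0
  f2[is.na(f2)] <- 0
  mult <- ifelse(pairs$h1 == pairs$h2, 1, 2)
  p <- mult * f1 * f2
  d <- match(pairs$id, unique(pairs$id))
  tot <- as.vector(rowsum(p, d))
  deg <- which(tot == 0)
  if (length(deg)) {
    warning(length(deg), " donor(s) had an all-zero posterior; re-seeded ",
            "with frequency floor ", RESEED_FLOOR, call. = FALSE)
    rows <- d %in% deg
    p[rows] <- mult[rows] * pmax(f1[rows], RESEED_FLOOR) *
      pmax(f2[rows], RESEED_FLOOR)
    tot <- as.vector(rowsum(p, d))
  }
  out <- tibble::tibble(id = pairs$id, h1 = pairs$h1, h2 = pairs$h2,
                        prob = p / tot[d])
  sort_posterior(out)
}

#' M-step: haplotype frequencies from donor posteriors
#'
#' `f(h) = (1 / 2N) * sum over donors and pairs of P(pair) * count of h in
#' the pair`; sums to 1 over haplotypes.
#'
#' @param posteriors Posterior tibble (`id`, `h1`, `h2`, `prob`).
#' @return Frequency table sorted by descending frequency, ties in
#'   canonical haplotype order.
#' @export
m_step <- function(posteriors) {
  if (nrow(posteriors) == 0L) {
    stop("empty posterior set", call. = FALSE)
  }
  levs <- unique(c(posteriors$h1, posteriors$h2))
  i1 <- match(posteriors$h1, levs)
  i2 <- match(posteriors$h2, levs)
  n_donors <- length(unique(posteriors$id))
  f <- accumulate_freqs(i1, i2, posteriors$prob, length(levs), n_donors)
  out <- tibble::tibble(haplotype = levs, frequency = f)
  out[order(-out$frequency, hap_key(out$haplotype)), ]
}

#' Fit haplotype frequencies by EM
#'
#' Alternates the HWE E-step and counting M-step starting from a uniform
#' posterior over each donor's hypothesis set (or from supplied seed
#' weights) until the relative log-likelihood improvement falls below `tol`
#' or `max_iter` is reached. The log-likelihood trace is non-decreasing.
#'
#' @param hypotheses Tibble with columns `id`, `h1`, `h2` and optionally
#'   `w` (per-row seed weights, normalized within donor).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `hla_em`: list with `freqs` (frequency
#'   table), `posterior` (final per-donor posterior, sorted), `loglik`
#'   (trace), `iterations`, `converged`, `n_donors`, `n_flagged` (donors
#'   ever re-seeded after posterior collapse).
#' @export
em_fit <- function(hypotheses, tol = 1e-6, max_iter = 1000) {
  stopifnot(tol > 0, max_iter >= 1)
  if (nrow(hypotheses) == 0L) stop("no hypotheses to fit", call. = FALSE)
  ids <- unique(hypotheses$id)
  n_donors <- length(ids)
  d <- match(hypotheses$id, ids)
  levs <- unique(c(hypotheses$h1, hypotheses$h2))
  nh <- length(levs)
  i1 <- match(hypotheses$h1, levs)
  i2 <- match(hypotheses$h2, levs)
  mult <- ifelse(i1 == i2, 1, 2)

  w0 <- hypotheses[["w"]] %||% rep(1, nrow(hypotheses))
  w0 <- w0 / as.vector(rowsum(w0, d))[d]
  f <- accumulate_freqs(i1, i2, w0, nh, n_donors)

  trace <- numeric(0)
  converged <- FALSE
  flagged <- logical(n_donors)
  p <- w0
  for (iter in seq_len(max_iter)) {
    pu <- mult * f[i1] * f[i2]
    tot <- as.vector(rowsum(pu, d))
    deg <- tot == 0
    if (any(deg)) {
      flagged <- flagged | deg
      rows <- deg[d]
      pu[rows] <- mult[rows] * pmax(f[i1[rows]], RESEED_FLOOR) *
        pmax(f[i2[rows]], RESEED_FLOOR)
      tot <- as.vector(rowsum(pu, d))
    }
    ll <- sum(log(tot))
    if (!is.finite(ll)) stop("non-finite log-likelihood", call. = FALSE)
    trace <- c(trace, ll)
    p <- pu / tot[d]
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if ((ll - prev) <= tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
    f <- accumulate_freqs(i1, i2, p, nh, n_donors)
    f[f < FREQ_FLOOR] <- 0
    f <- f / sum(f)
  }
  post <- sort_posterior(tibble::tibble(
    id = hypotheses$id, h1 = hypotheses$h1, h2 = hypotheses$h2, prob = p
  ))
  freqs <- tibble::tibble(haplotype = levs, frequency = f)
  freqs <- freqs[order(-freqs$frequency, hap_key(freqs$haplotype)), ]
  structure(
    list(freqs = freqs, posterior = post, loglik = trace,
         iterations = length(trace), converged = converged,
         n_donors = n_donors, n_flagged = sum(flagged)),
    class = "hla_em"
  )
}

#' Truncate a donor posterior at a cumulative probability mass
#'
#' Retains, per donor, the shortest descending-probability prefix whose
#' cumulative probability reaches `cum` (always at least the top
#' hypothesis), then renormalizes. The registry default keeps 99.9999% of
#' the mass, discarding only a vanishing tail to bound the hypothesis
#' explosion when blocks are extended.
#'
#' @param posterior Posterior tibble (`id`, `h1`, `h2`, `prob`).
#' @param cum Cumulative probability to retain, in `[0, 1]`.
#' @return Truncated, renormalized posterior tibble.
#' @export
truncate_posterior <- function(posterior, cum = 0.999999) {
  stopifnot(cum >= 0, cum <= 1)
  post <- sort_posterior(posterior)
  first <- !duplicated(post$id)
  cs <- stats::ave(post$prob, match(post$id, unique(post$id)), FUN = cumsum)
  keep <- (cs - post$prob) < cum | first
  out <- post[keep, , drop = FALSE]
  tot <- stats::ave(out$prob, match(out$id, unique(out$id)), FUN = sum)
  out$prob <- out$prob / tot
  out
}

#' Extend haplotype-pair hypotheses by one locus
#'
#' For a donor typed at `new_locus`, every retained parent pair is extended
#' by every assignment of a candidate genotype's two alleles to the two
#' haplotypes. For an untyped donor, extensions impute every unordered pair
#' of alleles from `alphabet` (by default, the alleles observed among typed
#' donors' candidates at that locus — imputation is restricted to alleles
#' existing in the population). Children inherit their parent pair's
#' probability, split uniformly, and seed the next EM pass.
#'
#' @param posterior Truncated posterior at the current block.
#' @param donors Parsed donor tibble (see [parse_donors()]).
#' @param new_locus The next locus in [block_loci()] order.
#' @param alphabet Optional character vector of alleles used to impute
#'   untyped donors.
#' @return Hypothesis tibble (`id`, `h1`, `h2`, `w`) for the extended block.
#' @export
extend_block <- function(posterior, donors, new_locus, alphabet = NULL) {
  stopifnot(new_locus %in% block_loci())
  geno <- donors[[new_locus]]
  names(geno) <- donors$id
  typed_ids <- donors$id[!vapply(geno, is.null, TRUE)]

  ## candidate genotype frame for typed donors: id, c1, c2
  cands <- lapply(geno[typed_ids], function(g) g$candidates)
  ncand <- vapply(cands, nrow, 0L)
  cand_df <- tibble::tibble(
    id = rep(typed_ids, ncand),
    c1 = unlist(lapply(cands, function(m) m[, 1L]), use.names = FALSE),
    c2 = unlist(lapply(cands, function(m) m[, 2L]), use.names = FALSE)
  )

  parent <- posterior
  parent$parent <- seq_len(nrow(parent))
  is_typed <- parent$id %in% typed_ids

  pieces <- list()
  if (any(is_typed)) {
    tp <- dplyr::inner_join(parent[is_typed, ], cand_df, by = "id",
                            relationship = "many-to-many")
    pieces$typed <- tibble::tibble(
      id = rep(tp$id, 2L),
      parent = rep(tp$parent, 2L),
      prob = rep(tp$prob, 2L),
      h1 = c(paste(tp$h1, tp$c1, sep = "~"), paste(tp$h1, tp$c2, sep = "~")),
      h2 = c(paste(tp$h2, tp$c2, sep = "~"), paste(tp$h2, tp$c1, sep = "~"))
    )
  }
  if (any(!is_typed)) {
    if (is.null(alphabet)) {
      alphabet <- unique(c(cand_df$c1, cand_df$c2))
    }
    if (length(alphabet) == 0L) {
      stop("no alleles available to impute locus ", new_locus, call. = FALSE)
    }
    grid <- expand.grid(a = alphabet, b = alphabet,
                        stringsAsFactors = FALSE)
    up <- parent[!is_typed, ]
    k <- nrow(grid)
    idx <- rep(seq_len(nrow(up)), each = k)
    pieces$untyped <- tibble::tibble(
      id = up$id[idx],
      parent = up$parent[idx],
      prob = up$prob[idx],
      h1 = paste(up$h1[idx], grid$a, sep = "~"),
      h2 = paste(up$h2[idx], grid$b, sep = "~")
    )
  }
  ext <- dplyr::bind_rows(pieces)
  cp <- canonical_hap_pairs(ext$h1, ext$h2)
  ext$h1 <- cp$h1
  ext$h2 <- cp$h2
  ext <- ext[!duplicated(paste(ext$parent, ext$h1, ext$h2, sep = "\r")), ]
  ## parent mass split uniformly over its distinct children, then summed
  ## over parents contributing the same child pair
  psize <- tabulate(ext$parent, nbins = nrow(parent))
  w <- ext$prob / psize[ext$parent]
  key <- paste(ext$id, ext$h1, ext$h2, sep = "\r")
  agg <- rowsum(w, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- tibble::tibble(id = ext$id[first], h1 = ext$h1[first],
                        h2 = ext$h2[first], w = as.vector(agg))
  out[order(match(out$id, donors$id)), ]
}

#' Run the full block-wise estimation pipeline
#'
#' Executes the registry estimation sequence: enumerate (A~B) hypotheses,
#' fit by EM, truncate posteriors, then repeatedly extend by the next locus
#' (C, DRB1, DQB1), refit and truncate. Returns five-locus per-donor
#' posteriors and the final haplotype frequency table (the counting M-step
#' of the final truncated posteriors, so [haplotype_frequencies()] on the
#' returned posterior reproduces it exactly).
#'
#' @param donors Parsed donor tibble (all donors must pass the HLA-A/B
#'   inclusion rule, e.g. via [read_donor_table()] / [parse_donors()]).
#' @param tol,max_iter EM convergence controls (see [em_fit()]).
#' @param cum Cumulative posterior mass retained at each truncation.
#' @param verbose Log per-block progress to `stderr`.
#' @return An object of class `hla_pipeline`: list with `posterior`
#'   (five-locus donor posteriors), `freqs` (frequency table), `blocks`
#'   (per-block summary tibble), `n_donors`, `n_flagged`.
#' @export
run_block_pipeline <- function(donors, tol = 1e-6, max_iter = 1000,
                               cum = 0.999999, verbose = FALSE) {
  if (nrow(donors) == 0L) stop("no donors", call. = FALSE)
  say <- function(...) if (verbose) message(...)

  hyp <- initial_hypotheses(donors)
  blocks <- list()
  post <- NULL
  n_flagged <- 0L
  loci_so_far <- c("A", "B")
  for (step in seq_len(4L)) {
    fit <- em_fit(hyp, tol = tol, max_iter = max_iter)
    post <- truncate_posterior(fit$posterior, cum = cum)
    n_flagged <- n_flagged + fit$n_flagged
    blocks[[step]] <- tibble::tibble(
      block = paste(loci_so_far, collapse = "~"),
      n_hypotheses = nrow(hyp),
      n_retained = nrow(post),
      iterations = fit$iterations,
      loglik = fit$loglik[fit$iterations],
      converged = fit$converged,
      n_flagged = fit$n_flagged
    )
    say("block ", blocks[[step]]$block, ": ", nrow(hyp), " hypotheses, ",
        fit$iterations, " EM iterations, loglik ",
        format(blocks[[step]]$loglik))
    if (step == 4L) break
    new_locus <- block_loci()[step + 2L]
    hyp <- extend_block(post, donors, new_locus)
    loci_so_far <- c(loci_so_far, new_locus)
  }
  freqs <- m_step(post)
  structure(
    list(posterior = post, freqs = freqs,
         blocks = dplyr::bind_rows(blocks),
         n_donors = length(unique(post$id)), n_flagged = n_flagged),
    class = "hla_pipeline"
  )
}
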
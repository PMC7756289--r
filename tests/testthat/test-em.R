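two_locus_donor <- function(a_txt, b_txt, tab = empty_table()) {
  list(A = parse_locus_genotype(a_txt, tab, "A"),
       B = parse_locus_genotype(b_txt, tab, "B"))
}

test_that("initial pair enumeration covers genotypes and phasings", {
  # double homozygote: one pair
  d <- two_locus_donor("A*01:01+A*01:01", "B*07:02+B*07:02")
  p <- enumerate_initial_pairs(d)
  expect_equal(nrow(p), 1L)
  expect_equal(p$h1, "A*01:01~B*07:02")
  expect_equal(p$h2, "A*01:01~B*07:02")

  # double heterozygote: the two classic phasings
  d2 <- two_locus_donor("A*01:01+A*02:01", "B*07:02+B*08:01")
  p2 <- enumerate_initial_pairs(d2)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$prob, c(0.5, 0.5))

  # allelic ambiguity at A, homozygous B
  tab <- empty_table()
  d3 <- list(A = structure(list(locus = "A",
                                candidates = rbind(c("A*01:01", "A*01:01"),
                                                   c("A*01:01", "A*02:01"))),
                           class = "hla_genotype"),
             B = parse_locus_genotype("B*07:02+B*07:02", tab, "B"))
  p3 <- enumerate_initial_pairs(d3)
  got <- sort(paste(p3$h1, p3$h2, sep = "|"))
  want <- enumerate_pairs_bruteforce(d3$A$candidates, d3$B$candidates)
  expect_equal(got, want)
  expect_equal(nrow(p3), 2L)

  expect_error(enumerate_initial_pairs(list(A = NULL, B = d$B)),
               "typed at HLA-A and HLA-B")
})

test_that("pair enumeration matches brute force on random ambiguous donors", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      alleles_a <- sprintf("A*%02d:01", 1:4)
      alleles_b <- sprintf("B*%02d:01", 1:4)
      rnd_cand <- function(pool) {
        k <- sample(1:3, 1)
        m <- t(replicate(k, sort(sample(pool, 2, replace = TRUE))))
        m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
      }
      d <- list(
        A = structure(list(locus = "A", candidates = rnd_cand(alleles_a)),
                      class = "hla_genotype"),
        B = structure(list(locus = "B", candidates = rnd_cand(alleles_b)),
                      class = "hla_genotype")
      )
      p <- enumerate_initial_pairs(d)
      expect_equal(sort(paste(p$h1, p$h2, sep = "|")),
                   enumerate_pairs_bruteforce(d$A$candidates,
                                              d$B$candidates))
    }
  })
})

test_that("E-step posteriors follow HWE arithmetic", {
  freqs <- tibble::tibble(haplotype = c("h1", "h2"),
                          frequency = c(0.5, 0.5))
  pairs <- tibble::tibble(id = c("d", "d"), h1 = c("h1", "h1"),
                          h2 = c("h1", "h2"))
  post <- e_step(pairs, freqs)
  # 0.25 vs 0.5 -> 1/3 and 2/3, heterozygous pair first after sorting
  expect_equal(post$prob, c(2 / 3, 1 / 3))
  expect_equal(post$h2, c("h2", "h1"))

  # a single hypothesis normalizes to probability 1 even when part of its
  # support is missing from the frequency table (re-seed path, flagged)
  single <- suppressWarnings(
    e_step(tibble::tibble(id = "d", h1 = "h1", h2 = "h2"),
           tibble::tibble(haplotype = "h1", frequency = 1))
  )
  expect_equal(single$prob, 1)

  # symmetric phasings under symmetric frequencies
  f4 <- tibble::tibble(haplotype = c("a1~b1", "a2~b2", "a1~b2", "a2~b1"),
                       frequency = rep(0.25, 4))
  ph <- e_step(tibble::tibble(id = c("d", "d"),
                              h1 = c("a1~b1", "a1~b2"),
                              h2 = c("a2~b2", "a2~b1")), f4)
  expect_equal(ph$prob, c(0.5, 0.5))

  # all-zero posterior flags the donor and re-seeds
  expect_warning(
    zz <- e_step(tibble::tibble(id = "d", h1 = "h1", h2 = "h2"),
                 tibble::tibble(haplotype = "h1", frequency = 0)),
    "all-zero"
  )
  expect_equal(sum(zz$prob), 1)
})

test_that("M-step counts haplotypes from posteriors", {
  p1 <- tibble::tibble(id = "d", h1 = "h1", h2 = "h2", prob = 1)
  expect_equal(sort(m_step(p1)$frequency), c(0.5, 0.5))

  p2 <- tibble::tibble(id = c("a", "b"), h1 = "h1", h2 = "h1", prob = 1)
  expect_equal(m_step(p2)$frequency, 1)

  p3 <- tibble::tibble(id = "d", h1 = c("h1", "h1"), h2 = c("h1", "h2"),
                       prob = c(0.4, 0.6))
  f3 <- m_step(p3)
  expect_equal(f3$frequency[f3$haplotype == "h1"], 0.7)
  expect_equal(f3$frequency[f3$haplotype == "h2"], 0.3)

  expect_error(m_step(p3[0, ]), "empty")
})

test_that("EM reaches the direct-counting fixed point on forced data", {
  # unambiguous, phase-forced donors (homozygous at A or B)
  hyp <- tibble::tibble(
    id = c("d1", "d2", "d3"),
    h1 = c("a1~b1", "a1~b1", "a2~b2"),
    h2 = c("a1~b2", "a2~b1", "a2~b2")
  )
  fit <- em_fit(hyp)
  counts <- table(c(hyp$h1, hyp$h2)) / 6
  expect_equal(fit$freqs$frequency,
               as.vector(counts[fit$freqs$haplotype]))
  expect_true(fit$converged)
})

test_that("EM matches the simplex-search MLE oracle on tiny instances", {
  # the classic 3-donor instance: A1A1xB1B2, A1A2xB1B1, A1A2xB1B2
  hyp <- tibble::tibble(
    id = c("d1", "d2", "d3", "d3"),
    h1 = c("A*01:01~B*01:01", "A*01:01~B*01:01",
           "A*01:01~B*01:01", "A*01:01~B*02:01"),
    h2 = c("A*01:01~B*02:01", "A*02:01~B*01:01",
           "A*02:01~B*02:01", "A*02:01~B*01:01")
  )
  fit <- em_fit(hyp, tol = 1e-12, max_iter = 5000)
  oracle <- hwe_mle_oracle(hyp)
  est <- stats::setNames(fit$freqs$frequency, fit$freqs$haplotype)
  for (h in names(oracle)) {
    got <- if (h %in% names(est)) est[[h]] else 0
    expect_lt(abs(got - oracle[[h]]), 1e-4)
  }

  # randomized small instances: <= 6 haplotypes, <= 20 donors
  withr::with_seed(23, {
    for (rep in 1:5) {
      haps <- c("A*01:01~B*01:01", "A*01:01~B*02:01", "A*02:01~B*01:01",
                "A*02:01~B*02:01", "A*03:01~B*01:01", "A*03:01~B*03:01")
      n <- sample(8:20, 1)
      rows <- lapply(seq_len(n), function(i) {
        k <- sample(1:3, 1)
        idx <- t(replicate(k, sort(sample(6, 2, replace = TRUE))))
        idx <- idx[!duplicated(paste(idx[, 1], idx[, 2])), , drop = FALSE]
        tibble::tibble(id = sprintf("d%02d", i),
                       h1 = haps[idx[, 1]], h2 = haps[idx[, 2]])
      })
      hyp_r <- dplyr::bind_rows(rows)
      fit_r <- em_fit(hyp_r, tol = 1e-12, max_iter = 5000)
      oracle_r <- hwe_mle_oracle(hyp_r, starts = 30)
      est_r <- stats::setNames(fit_r$freqs$frequency, fit_r$freqs$haplotype)
      for (h in names(oracle_r)) {
        got <- if (h %in% names(est_r)) est_r[[h]] else 0
        expect_lt(abs(got - oracle_r[[h]]), 1e-3)
      }
    }
  })
})

test_that("EM log-likelihood trace is non-decreasing and tables normalized", {
  sim <- simulate_registry(list(n_donors = 150, n_haplotypes = 10,
                                alleles_per_locus = 5), seed = 61)
  parsed <- parse_donors(sim$donors, sim$table)$donors
  hyp <- dplyr::bind_rows(lapply(seq_len(nrow(parsed)), function(i) {
    p <- enumerate_initial_pairs(parsed[i, ])
    tibble::tibble(id = parsed$id[i], h1 = p$h1, h2 = p$h2)
  }))
  fit <- em_fit(hyp)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_equal(sum(fit$freqs$frequency), 1, tolerance = 1e-9)
  per_donor <- rowsum(fit$posterior$prob, fit$posterior$id)
  expect_true(all(abs(per_donor - 1) < 1e-9))
})

test_that("posterior truncation keeps the shortest sufficient prefix", {
  post <- tibble::tibble(
    id = "d",
    h1 = sprintf("A*%02d:01~B*01:01", 1:5),
    h2 = sprintf("A*%02d:01~B*01:01", 1:5),
    prob = c(0.7, 0.2, 0.0999995, 4e-7, 1e-7)
  )
  tr <- truncate_posterior(post, cum = 0.999999)
  expect_equal(nrow(tr), 3L)
  expect_equal(sum(tr$prob), 1)
  expect_equal(tr$prob, c(0.7, 0.2, 0.0999995) / 0.9999995)

  one <- truncate_posterior(tibble::tibble(id = "d", h1 = "h", h2 = "h",
                                           prob = 1))
  expect_equal(one$prob, 1)

  top_only <- truncate_posterior(post, cum = 0)
  expect_equal(nrow(top_only), 1L)
  expect_equal(top_only$prob, 1)
  expect_equal(top_only$h1, "A*01:01~B*01:01")
})

test_that("block extension enumerates assignments and imputations", {
  tab <- empty_table()
  base <- tibble::tibble(id = "d", h1 = "A*01:01~B*01:01",
                         h2 = "A*02:01~B*02:01", prob = 1)

  # homozygous C: single extension
  don_hom <- tibble::tibble(id = "d", population = "P")
  don_hom$A <- list(parse_locus_genotype("A*01:01+A*02:01", tab, "A"))
  don_hom$B <- list(parse_locus_genotype("B*01:01+B*02:01", tab, "B"))
  don_hom$C <- list(parse_locus_genotype("C*01:01+C*01:01", tab, "C"))
  don_hom$DRB1 <- list(NULL)
  don_hom$DQB1 <- list(NULL)
  ext <- extend_block(base, don_hom, "C")
  expect_equal(nrow(ext), 1L)
  expect_equal(ext$h1, "A*01:01~B*01:01~C*01:01")
  expect_equal(ext$h2, "A*02:01~B*02:01~C*01:01")

  # heterozygous C: two assignments
  don_het <- don_hom
  don_het$C <- list(parse_locus_genotype("C*01:01+C*02:01", tab, "C"))
  ext2 <- extend_block(base, don_het, "C")
  expect_equal(nrow(ext2), 2L)
  expect_equal(sum(ext2$w), 1)

  # untyped donor, 3-allele imputation alphabet: ordered assignments
  # collapse to the brute-force set of unordered extended pairs
  don_un <- don_hom
  don_un$C <- list(NULL)
  alphabet <- c("C*01:01", "C*02:01", "C*03:01")
  ext3 <- extend_block(base, don_un, "C", alphabet = alphabet)
  expect_equal(sum(ext3$w), 1)
  # brute-force: unordered pairs of (h1 + a, h2 + b) over the alphabet;
  # with a heterozygous parent all 9 assignments are distinct diplotypes
  brute <- unique(vapply(seq_len(9), function(k) {
    a <- alphabet[(k - 1) %/% 3 + 1]
    b <- alphabet[(k - 1) %% 3 + 1]
    paste(sort(c(paste0("A*01:01~B*01:01~", a),
                 paste0("A*02:01~B*02:01~", b))), collapse = "|")
  }, ""))
  expect_setequal(paste(ext3$h1, ext3$h2, sep = "|"), brute)
  expect_equal(nrow(ext3), length(brute))

  # with a homozygous parent the swap collapses: 9 ordered -> 6 unordered
  base_hom <- tibble::tibble(id = "d", h1 = "A*01:01~B*01:01",
                             h2 = "A*01:01~B*01:01", prob = 1)
  ext4 <- extend_block(base_hom, don_un, "C", alphabet = alphabet)
  expect_equal(nrow(ext4), 6L)
  expect_equal(sum(ext4$w), 1)
})

test_that("pipeline equals phase-resolved counting on forced, complete data", {
  # two truth haplotypes differing only at HLA-A: every donor heterozygous
  # at most at A, so phase is forced everywhere
  h1 <- "A*01:01~B*01:01~C*01:01~DRB1*01:01~DQB1*02:01"
  h2 <- "A*02:01~B*01:01~C*01:01~DRB1*01:01~DQB1*02:01"
  pairs1 <- c(h1, h1, h2, h1, h2, h2, h1, h2)
  pairs2 <- c(h1, h2, h2, h1, h2, h2, h1, h1)
  donors <- donors_from_diplotypes(pairs1, pairs2)
  pipe <- run_block_pipeline(donors)
  counting <- table(c(pairs1, pairs2)) / 16
  est <- stats::setNames(pipe$freqs$frequency, pipe$freqs$haplotype)
  expect_equal(est[names(counting)], as.vector(counting) |>
                 stats::setNames(names(counting)))
  # posteriors are point masses on the true diplotypes
  expect_true(all(abs(pipe$posterior$prob - 1) < 1e-9))
})

test_that("truncation at the registry threshold barely moves estimates", {
  sim <- simulate_registry(list(n_donors = 120, n_haplotypes = 8,
                                alleles_per_locus = 4), seed = 71)
  parsed <- parse_donors(sim$donors, sim$table)$donors
  p1 <- run_block_pipeline(parsed, cum = 0.999999)
  p2 <- run_block_pipeline(parsed, cum = 1.0)
  expect_lt(tvd(p1$freqs, p2$freqs), 1e-6)
})

test_that("pipeline recovers truth frequencies on a clean mid-size draw", {
  truth <- generate_truth(12, 5, concentration = 0.8, seed = 81)
  donors <- sample_donors(truth, 800, seed = 82)
  parsed <- parse_donors(donors)$donors
  pipe <- run_block_pipeline(parsed)
  expect_lt(tvd(pipe$freqs, truth), 0.05)
  # every donor's truncated posterior still sums to 1
  per_donor <- rowsum(pipe$posterior$prob, pipe$posterior$id)
  expect_true(all(abs(per_donor - 1) < 1e-9))
})
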
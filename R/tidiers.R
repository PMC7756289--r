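#' Tidy an EM fit into its haplotype frequency table
#'
#' @param x An `hla_em` object from [em_fit()].
#' @param ... Unused.
#' @return Tibble with `haplotype`, `frequency`, descending.
#' @method tidy hla_em
#' @export
tidy.hla_em <- function(x, ...) {
  tibble::as_tibble(x$freqs)
}

#' One-row summary of an EM fit
#'
#' @inheritParams tidy.hla_em
#' @return Tibble with `logLik`, `iterations`, `converged`, `n_donors`,
#'   `n_haplotypes`, `n_flagged`.
#' @method glance hla_em
#' @export
glance.hla_em <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik[x$iterations],
    iterations = x$iterations,
    converged = x$converged,
    n_donors = x$n_donors,
    n_haplotypes = sum(x$freqs$frequency > 0),
    n_flagged = x$n_flagged
  )
}

#' Tidy a pipeline result into its five-locus frequency table
#'
#' @param x An `hla_pipeline` object from [run_block_pipeline()].
#' @param ... Unused.
#' @return Tibble with `haplotype`, `frequency`, descending.
#' @method tidy hla_pipeline
#' @export
tidy.hla_pipeline <- function(x, ...) {
  tibble::as_tibble(x$freqs)
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.hla_pipeline
#' @return Tibble with `n_donors`, `n_haplotypes`, `logLik` (final block),
#'   `n_blocks`, `n_flagged`.
#' @method glance hla_pipeline
#' @export
glance.hla_pipeline <- function(x, ...) {
  tibble::tibble(
    n_donors = x$n_donors,
    n_haplotypes = sum(x$freqs$frequency > 0),
    logLik = x$blocks$loglik[nrow(x$blocks)],
    n_blocks = nrow(x$blocks),
    n_flagged = x$n_flagged
  )
}

#' @export
print.hla_em <- function(x, ...) {
  cat("<hla_em> EM haplotype frequency fit\n")
  cat("  donors:     ", x$n_donors, "\n")
  cat("  haplotypes: ", nrow(x$freqs), "\n")
  cat("  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  cat("  logLik:     ", format(x$loglik[x$iterations]), "\n")
  invisible(x)
}

#' @export
print.hla_pipeline <- function(x, ...) {
  cat("<hla_pipeline> block-wise EM estimation\n")
  print(as.data.frame(x$blocks), row.names = FALSE)
  cat("donors:", x$n_donors, " five-locus haplotypes:", nrow(x$freqs), "\n")
  invisible(x)
}
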
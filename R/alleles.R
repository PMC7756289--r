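## Locus universe. hla_loci() is the display (genomic) order used in reports;
## block_loci() is the order in which the estimation blocks are grown.

#' HLA loci handled by the package
#'
#' `hla_loci()` returns the five classical loci in genomic display order;
#' `block_loci()` returns them in the order in which the estimation pipeline
#' grows its haplotype blocks: the (A, B) core first, then C, DRB1, DQB1.
#'
#' @return Character vector of locus names.
#' @export
#' @examples
#' hla_loci()
#' block_loci()
hla_loci <- function() c("A", "C", "B", "DRB1", "DQB1")

#' @rdname hla_loci
#' @export
block_loci <- function() c("A", "B", "C", "DRB1", "DQB1")

EXPRESSION_SUFFIXES <- c("N", "L", "S", "Q", "A")

ALLELE_RX <- "^(A|B|C|DRB1|DQB1)\\*([0-9]+):([0-9]+)(?::[0-9]+){0,2}([NLSQA])?$"

#' Parse HLA allele names to two-field (ARS) resolution
#'
#' Parses full allele names of the form `"LOCUS*f1:f2[:f3[:f4]][suffix]"` and
#' reduces them to the two-field antigen-recognition-site (ARS) name, keeping
#' any expression suffix (N/L/S/Q/A) as metadata. Legacy colon-less 4-digit
#' names (e.g. `"A*0101"`) and single-field tokens are rejected: those must go
#' through [expand_typing_token()] with an expansion table.
#'
#' @param text Character vector of allele name strings.
#' @return A tibble with one row per input: `allele` (rendered 2-field name,
#'   suffix included), `locus`, `field1`, `field2`, `suffix` (`NA` if none).
#' @export
#' @examples
#' parse_allele_name(c("A*01:01:01:01", "DQB1*06:02", "B*44:203Q"))
parse_allele_name <- function(text) {
  stopifnot(is.character(text))
  m <- regmatches(text, regexec(ALLELE_RX, text))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    stop("malformed allele name(s): ",
         paste(utils::head(text[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  parts <- do.call(rbind, m)
  locus <- parts[, 2L]
  f1 <- as.integer(parts[, 3L])
  f2 <- as.integer(parts[, 4L])
  suffix <- parts[, 5L]
  suffix[suffix == ""] <- NA_character_
  if (any(f1 < 1L) || any(f2 < 1L)) {
    stop("allele fields must be >= 1: ",
         paste(text[f1 < 1L | f2 < 1L], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    allele = render_allele(locus, f1, f2, suffix),
    locus = locus, field1 = f1, field2 = f2, suffix = suffix
  )
}

## Rendered 2-field form, zero-padded to at least two digits per field.
render_allele <- function(locus, f1, f2, suffix) {
  paste0(locus, "*",
         formatC(f1, width = 2, flag = "0"), ":",
         formatC(f2, width = 2, flag = "0"),
         ifelse(is.na(suffix), "", suffix))
}

## Sortable key implementing the allele total ordering
## (locus, field1, field2, suffix). Fields padded to 5 digits so multi-digit
## protein designations (e.g. B*44:203) order numerically. Computed over
## unique values: callers pass heavily repeated vectors.
allele_key <- function(allele) {
  ua <- unique(allele)
  p <- parse_allele_name(ua)
  rank <- match(p$locus, block_loci())
  k <- sprintf("%d|%05d|%05d|%s", rank, p$field1, p$field2,
               ifelse(is.na(p$suffix), "", p$suffix))
  k[match(allele, ua)]
}

## Key parseable allele names, pass other labels through unchanged so
## ordering helpers also work on arbitrary keys (e.g. in unit fixtures).
safe_allele_key <- function(al) {
  ok <- grepl(ALLELE_RX, al)
  k <- al
  if (any(ok)) k[ok] <- allele_key(al[ok])
  k
}

#' Read a code expansion table
#'
#' An expansion table maps low-resolution typing tokens (serological labels,
#' first-field-only tokens, multi-allele codes) to the set of two-field
#' alleles they denote. The file format is tab-delimited with columns
#' `code`, `locus`, `expansion` (slash-joined two-field allele names), after
#' an optional `# version: <string>` header line.
#'
#' @param path Path to the table file.
#' @return A tibble with columns `code`, `locus`, `alleles` (list column of
#'   character vectors), carrying a `"version"` attribute.
#' @export
read_expansion_table <- function(path) {
  lines <- readLines(path)
  version <- NA_character_
  if (length(lines) && grepl("^#", lines[1L])) {
    version <- sub("^#\\s*version:?\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  expansion_table(df$code, df$locus, strsplit(df$expansion, "/", fixed = TRUE),
                  version = version)
}

#' Construct an expansion table
#'
#' @param code Character vector of code tokens (e.g. `"A*01"`).
#' @param locus Locus of each code.
#' @param alleles List of character vectors: the two-field alleles each code
#'   expands to.
#' @param version Optional version string for provenance.
#' @return A tibble of class `hla_expansion` with columns `code`, `locus`,
#'   `alleles`.
#' @export
expansion_table <- function(code, locus, alleles, version = NA_character_) {
  stopifnot(length(code) == length(locus), length(code) == length(alleles))
  alleles <- lapply(alleles, as.character)
  if (any(lengths(alleles) == 0L)) {
    stop("expansion sets must be non-empty", call. = FALSE)
  }
  for (i in seq_along(code)) {
    p <- parse_allele_name(alleles[[i]])
    if (any(p$locus != locus[[i]])) {
      stop("expansion for code '", code[[i]], "' mixes loci", call. = FALSE)
    }
    alleles[[i]] <- p$allele
  }
  out <- tibble::tibble(code = as.character(code), locus = as.character(locus),
                        alleles = alleles)
  attr(out, "version") <- version
  class(out) <- c("hla_expansion", class(out))
  out
}

#' Write an expansion table
#'
#' @param table An `hla_expansion` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expansion_table <- function(table, path) {
  version <- attr(table, "version")
  lines <- c(
    paste0("# version: ", if (is.na(version)) "unversioned" else version),
    paste("code", "locus", "expansion", sep = "\t"),
    paste(table$code, table$locus,
          vapply(table$alleles, paste, "", collapse = "/"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

empty_expansion_table <- function() {
  expansion_table(character(), character(), list())
}

#' Expand a typing token to its two-field allele set
#'
#' A token may be a full allele name (passed through [parse_allele_name()]),
#' a slash-joined string (union of its parts), or a code present in the
#' expansion table. Null-expressed alleles (suffix `N`) are dropped from
#' table expansions by default because they present no ARS protein.
#'
#' @param token A single typing token string.
#' @param table An `hla_expansion` table (may be empty).
#' @param locus Locus the token belongs to.
#' @param drop_null Drop N-suffixed alleles from table expansions
#'   (default `TRUE`).
#' @return Character vector of distinct two-field allele names.
#' @export
#' @examples
#' tab <- expansion_table("A*01", "A", list(c("A*01:01", "A*01:02", "A*01:03")))
#' expand_typing_token("A*01:01/A*01:02", tab, "A")
#' expand_typing_token("A*01", tab, "A")
expand_typing_token <- function(token, table, locus, drop_null = TRUE) {
  stopifnot(length(token) == 1L, is.character(token))
  if (grepl("/", token, fixed = TRUE)) {
    parts <- strsplit(token, "/", fixed = TRUE)[[1L]]
    out <- unique(unlist(lapply(
      parts, expand_typing_token, table = table, locus = locus,
      drop_null = drop_null
    )))
  } else if (grepl(ALLELE_RX, token)) {
    p <- parse_allele_name(token)
    if (p$locus != locus) {
      stop("token '", token, "' is not at locus ", locus, call. = FALSE)
    }
    out <- p$allele
  } else {
    hit <- which(table$code == token & table$locus == locus)
    if (length(hit) == 0L) {
      stop("unresolvable typing token '", token, "' at locus ", locus,
           call. = FALSE)
    }
    out <- unique(unlist(table$alleles[hit]))
    if (drop_null) {
      out <- out[!endsWith(out, "N")]
    }
  }
  if (length(out) == 0L) {
    stop("token '", token, "' expands to an empty allele set at locus ",
         locus, call. = FALSE)
  }
  out
}

## Canonicalize a two-column matrix of allele pairs: within-row order by
## allele key, then deduplicate and order rows deterministically.
canonical_pairs <- function(a, b) {
  ka <- allele_key(a)
  kb <- allele_key(b)
  swap <- kb < ka
  a2 <- ifelse(swap, b, a)
  b2 <- ifelse(swap, a, b)
  k1 <- ifelse(swap, kb, ka)
  k2 <- ifelse(swap, ka, kb)
  keep <- !duplicated(paste(a2, b2, sep = "+"))
  ord <- order(k1[keep], k2[keep])
  cbind(a2[keep][ord], b2[keep][ord])
}

#' Parse an unphased locus genotype string
#'
#' Genotype strings have the form `"<tokenlist>+<tokenlist>"`, one token list
#' per chromosome, where a token list is a slash-joined set of typing tokens.
#' The candidate set is the cross product of the two expansions, as unordered
#' (canonically ordered, deduplicated) allele pairs.
#'
#' A bare token list without `"+"` is an error unless
#' `single_as_homozygous = TRUE`, in which case it is read as a homozygous
#' call — registry exports differ on this convention, so it is opt-in.
#'
#' @param text A single genotype string.
#' @inheritParams expand_typing_token
#' @param single_as_homozygous Interpret a single token list as homozygous.
#' @return A list of class `hla_genotype`: `locus` and `candidates`, a
#'   two-column character matrix with one row per candidate unordered pair.
#' @export
#' @examples
#' tab <- expansion_table(character(), character(), list())
#' parse_locus_genotype("A*01:01/A*01:02+A*02:01", tab, "A")$candidates
parse_locus_genotype <- function(text, table, locus, drop_null = TRUE,
                                 single_as_homozygous = FALSE) {
  stopifnot(length(text) == 1L, is.character(text))
  sides <- strsplit(text, "+", fixed = TRUE)[[1L]]
  sides <- sides[nzchar(sides)]
  if (length(sides) == 1L) {
    if (!single_as_homozygous) {
      stop("genotype '", text, "' at locus ", locus,
           " has a single token list; set single_as_homozygous = TRUE ",
           "to read it as a homozygous call", call. = FALSE)
    }
    sides <- c(sides, sides)
  }
  if (length(sides) != 2L) {
    stop("genotype '", text, "' at locus ", locus,
         " does not have two chromosome token lists", call. = FALSE)
  }
  e1 <- expand_typing_token(sides[[1L]], table, locus, drop_null)
  e2 <- expand_typing_token(sides[[2L]], table, locus, drop_null)
  grid <- expand.grid(a = e1, b = e2, stringsAsFactors = FALSE)
  cand <- canonical_pairs(grid$a, grid$b)
  if (nrow(cand) == 0L) {
    stop("genotype '", text, "' at locus ", locus,
         " yields no candidate pairs", call. = FALSE)
  }
  structure(list(locus = locus, candidates = cand), class = "hla_genotype")
}
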
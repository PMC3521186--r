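#' Read a fragment file
#'
#' Two plain-text dialects are supported. The `"hapcut"` dialect is the
#' whitespace-separated format used by fragment extractors in the HapCUT
#' family: each line is
#' `<num_pieces> <frag_id> <start_1> <alleles_1> ... <start_p> <alleles_p> [<quality_string>]`
#' with 1-based starts and pieces given left to right without overlap. A
#' trailing quality string (one character per called allele) is parsed and
#' retained in attribute `quals`, but the model is unweighted, so qualities
#' never enter scoring. The `"dense"` dialect is one fragment per line as a
#' string over `{0,1,-}`, all lines the same length.
#'
#' @param path file to read.
#' @param dialect `"hapcut"` or `"dense"`.
#' @param n number of SNP loci (columns). Required information for the
#'   hapcut dialect only when the matrix should be wider than the rightmost
#'   covered locus; by default the width is inferred from the data.
#' @return an `snp_matrix`.
#' @export
read_fragments <- function(path, dialect = c("dense", "hapcut"), n = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "dense") {
    m <- tryCatch(snp_matrix(lines), error = function(e) {
      stop("failed to parse dense fragment file '", path, "': ",
        conditionMessage(e), call. = FALSE)
    })
    if (!is.null(n) && ncol(m) != n && nrow(m) > 0) {
      stop("dense fragment file has ", ncol(m), " columns; expected ", n,
        call. = FALSE)
    }
    return(m)
  }
  parse_hapcut(lines, path, n)
}

parse_hapcut <- function(lines, path, n) {
  frags <- vector("list", length(lines))
  ids <- character(length(lines))
  quals <- rep(NA_character_, length(lines))
  max_end <- 0L
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    fail <- function(msg) {
      stop("malformed hapcut line ", ln, " in '", path, "': ", msg,
        call. = FALSE)
    }
    if (length(tok) < 4) fail("fewer than 4 fields")
    np <- suppressWarnings(as.integer(tok[1]))
    if (is.na(np) || np < 1) fail("bad piece count")
    n_tok <- length(tok)
    if (n_tok != 2 + 2 * np && n_tok != 3 + 2 * np) {
      fail(sprintf("expected %d or %d fields for %d piece(s), found %d",
        2 + 2 * np, 3 + 2 * np, np, n_tok))
    }
    ids[ln] <- tok[2]
    pieces <- vector("list", np)
    prev_end <- 0L
    n_alleles <- 0L
    for (p in seq_len(np)) {
      start <- suppressWarnings(as.integer(tok[1 + 2 * p]))
      alle <- tok[2 + 2 * p]
      if (is.na(start) || start < 1) fail("bad piece start")
      if (grepl("[^01-]", alle)) {
        fail(paste0("allele outside {0,1,-} in piece ", p))
      }
      if (start <= prev_end) fail("overlapping pieces within one fragment")
      prev_end <- start + nchar(alle) - 1L
      n_alleles <- n_alleles + nchar(alle)
      pieces[[p]] <- list(start = start, alleles = alle)
    }
    if (n_tok == 3 + 2 * np) {
      q <- tok[n_tok]
      if (nchar(q) != n_alleles) {
        fail(sprintf("quality string length %d does not match %d allele(s)",
          nchar(q), n_alleles))
      }
      quals[ln] <- q
    }
    max_end <- max(max_end, prev_end)
    frags[[ln]] <- pieces
  }
  width <- if (is.null(n)) max_end else as.integer(n)
  if (width < max_end) {
    stop("fragment extends to column ", max_end, " but n = ", width,
      call. = FALSE)
  }
  a <- matrix(NA_integer_, nrow = length(frags), ncol = width)
  for (i in seq_along(frags)) {
    for (pc in frags[[i]]) {
      v <- chars_to_alleles(strsplit(pc$alleles, "", fixed = TRUE)[[1]])
      a[i, pc$start + seq_along(v) - 1L] <- v
    }
  }
  if (all(is.na(quals))) quals <- NULL
  new_snp_matrix(a, row_ids = ids, quals = quals)
}

#' Write a fragment file
#'
#' Inverse of [read_fragments()]: round-trips bit-exactly under both
#' dialects (for `"hapcut"`, pass the matrix width back as `n` when reading
#' if trailing uncovered columns must be preserved).
#'
#' @param m an `snp_matrix`.
#' @param path file to write.
#' @param dialect `"hapcut"` or `"dense"`.
#' @export
write_fragments <- function(m, path, dialect = c("dense", "hapcut")) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    writeLines(fragment_strings(m), path)
    return(invisible(path))
  }
  ids <- row_ids(m)
  quals <- attr(m, "quals")
  lines <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    called <- which(!is.na(m[i, ]))
    if (!length(called)) {
      lines[i] <- paste(0, ids[i])
      next
    }
    breaks <- c(0L, which(diff(called) > 1L), length(called))
    fields <- character(0)
    for (p in seq_len(length(breaks) - 1L)) {
      seg <- called[(breaks[p] + 1L):breaks[p + 1L]]
      fields <- c(fields, seg[1],
        paste(m[i, seg], collapse = ""))
    }
    np <- length(breaks) - 1L
    q <- if (!is.null(quals) && !is.na(quals[i])) quals[i] else NULL
    lines[i] <- paste(c(np, ids[i], fields, q), collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a true haplotype pair
#'
#' Plain-text format: two lines, each a string over `{0,1}` of length `n`
#' (the two complementary haplotypes).
#'
#' @param path file path.
#' @return for `read_haplotypes`, a [haplotype_pair()].
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 2) {
    stop("haplotype file must contain exactly two lines", call. = FALSE)
  }
  h1 <- chars_to_alleles(strsplit(lines[1], "", fixed = TRUE)[[1]])
  h2 <- chars_to_alleles(strsplit(lines[2], "", fixed = TRUE)[[1]])
  if (anyNA(h1) || anyNA(h2)) {
    stop("haplotypes must be over {0,1}", call. = FALSE)
  }
  haplotype_pair(h1, h2)
}

#' @rdname read_haplotypes
#' @param h a [haplotype_pair()].
#' @export
write_haplotypes <- function(h, path) {
  writeLines(c(
    paste(h$h1, collapse = ""),
    paste(h$h2, collapse = "")
  ), path)
  invisible(path)
}

#' Read / write phased output
#'
#' Per-block plain-text phasing report: for each block a header line
#' `block <id> start <s> end <e>` followed by one line `<site> <h1> <h2>`
#' per phased site; unphased sites are omitted.
#'
#' @param fit an `hbop_blocks_fit` from [phase_blocks()].
#' @param path file path.
#' @export
write_phased <- function(fit, path) {
  h <- fit$haplotype
  lines <- character(0)
  bl <- fit$blocks
  for (b in seq_len(nrow(bl))) {
    sites <- bl$sites[[b]]
    phased <- sites[h$phased[sites]]
    if (!length(phased)) next
    lines <- c(lines,
      sprintf("block %d start %d end %d", bl$block[b], min(sites), max(sites)),
      sprintf("%d %d %d", phased, h$h1[phased], h$h2[phased]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phased
#' @param n total number of SNP sites (sites absent from the file are
#'   reported unphased).
#' @return for `read_phased`, a [haplotype_pair()] with `phased` flags, plus
#'   attribute `block` giving each phased site's block id.
#' @export
read_phased <- function(path, n) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  h1 <- integer(n); h2 <- 1L - h1
  phased <- logical(n)
  block_of <- rep(NA_integer_, n)
  cur <- NA_integer_
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "block") {
      cur <- as.integer(tok[2])
    } else {
      s <- as.integer(tok[1])
      h1[s] <- as.integer(tok[2]); h2[s] <- as.integer(tok[3])
      phased[s] <- TRUE
      block_of[s] <- cur
    }
  }
  out <- haplotype_pair(h1, h2, phased)
  attr(out, "block") <- block_of
  out
}
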
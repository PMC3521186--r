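#' Construct an SNP fragment matrix
#'
#' An `snp_matrix` encodes `m` aligned sequencing fragments over `n`
#' heterozygous SNP loci. Each entry is the allele called by a fragment at a
#' locus: `"0"` (major allele), `"1"` (minor allele) or `"-"` (not covered).
#' Internally alleles are stored as an integer matrix with `NA` for `-`;
#' all public interfaces use 1-based inclusive column indices.
#'
#' @param x a character vector of fragment strings over `{0,1,-}` (all the
#'   same length), or a matrix of `"0"`/`"1"`/`"-"` characters (or of
#'   integers 0/1 with `NA` gaps).
#' @param row_ids optional character vector of stable fragment identifiers;
#'   defaults to `f1, f2, ...`.
#'
#' @return an object of class `snp_matrix`.
#' @examples
#' m <- snp_matrix(c("01-", "-10"))
#' row_spans(m)
#' @export
snp_matrix <- function(x, row_ids = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (length(x) == 0) {
      a <- matrix(NA_integer_, nrow = 0, ncol = 0)
    } else {
      widths <- nchar(x)
      if (length(unique(widths)) > 1) {
        stop("all fragment strings must have the same length", call. = FALSE)
      }
      chars <- do.call(rbind, strsplit(x, "", fixed = TRUE))
      a <- matrix(chars_to_alleles(chars), nrow = length(x))
    }
  } else if (is.matrix(x)) {
    a <- if (is.character(x)) {
      matrix(chars_to_alleles(x), nrow = nrow(x))
    } else {
      storage.mode(x) <- "integer"
      if (any(!is.na(x) & x != 0L & x != 1L)) {
        stop("allele values must be 0, 1 or NA", call. = FALSE)
      }
      x
    }
  } else {
    stop("`x` must be a character vector or a matrix", call. = FALSE)
  }
  dimnames(a) <- NULL
  if (is.null(row_ids)) {
    row_ids <- if (nrow(a)) paste0("f", seq_len(nrow(a))) else character(0)
  }
  stopifnot(length(row_ids) == nrow(a))
  new_snp_matrix(a, row_ids = as.character(row_ids))
}

new_snp_matrix <- function(a, row_ids, quals = NULL, col_index = NULL) {
  structure(a,
    row_ids = row_ids, quals = quals, col_index = col_index,
    class = c("snp_matrix", "matrix", "array")
  )
}

chars_to_alleles <- function(chars) {
  bad <- !(chars %in% c("0", "1", "-"))
  if (any(bad)) {
    stop(
      "invalid allele symbol(s): ",
      paste(unique(chars[bad]), collapse = ", "),
      " (expected 0, 1 or -)",
      call. = FALSE
    )
  }
  out <- rep(NA_integer_, length(chars))
  out[chars == "0"] <- 0L
  out[chars == "1"] <- 1L
  out
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf(
    "<snp_matrix: %d fragment(s) x %d SNP locus/loci>\n", nrow(x), ncol(x)
  ))
  ids <- row_ids(x)
  strs <- fragment_strings(x)
  n_show <- min(nrow(x), 12L)
  for (i in seq_len(n_show)) cat(sprintf("  %-10s %s\n", ids[i], strs[i]))
  if (nrow(x) > n_show) cat(sprintf("  ... and %d more\n", nrow(x) - n_show))
  invisible(x)
}

#' @rdname snp_matrix
#' @param m an `snp_matrix`.
#' @export
row_ids <- function(m) attr(m, "row_ids")

#' Render fragments as strings over \{0,1,-\}
#' @param m an `snp_matrix`.
#' @return a character vector, one string per fragment.
#' @export
fragment_strings <- function(m) {
  if (nrow(m) == 0) return(character(0))
  apply(m, 1, function(row) {
    s <- ifelse(is.na(row), "-", as.character(row))
    paste(s, collapse = "")
  })
}

#' Per-fragment span bounds
#'
#' The span of a fragment is the interval from its first to its last called
#' (non-gap) locus; interior gaps are retained within the span. Fragments
#' with no called allele get `NA` bounds.
#'
#' @param m an `snp_matrix`.
#' @return a tibble with columns `row`, `id`, `l`, `r`, `n_called`.
#' @export
row_spans <- function(m) {
  sp <- spans_of(m)
  tibble::tibble(
    row = seq_len(nrow(m)),
    id = row_ids(m),
    l = sp$l, r = sp$r,
    n_called = sp$n_called
  )
}

## integer span bookkeeping shared by the solvers
spans_of <- function(m) {
  mm <- nrow(m)
  l <- integer(mm); r <- integer(mm); n_called <- integer(mm)
  for (i in seq_len(mm)) {
    idx <- which(!is.na(m[i, ]))
    n_called[i] <- length(idx)
    if (length(idx)) {
      l[i] <- idx[1L]; r[i] <- idx[length(idx)]
    } else {
      l[i] <- NA_integer_; r[i] <- NA_integer_
    }
  }
  list(l = l, r = r, n_called = n_called)
}

#' Preprocess a fragment matrix
#'
#' Drops fragments that cover fewer than two loci (such fragments carry no
#' linkage information) and, optionally, columns left with no coverage at
#' all. An index map from new to original column positions is recorded in
#' attribute `col_index` so coordinates remain recoverable after column
#' removal.
#'
#' @param m an `snp_matrix`.
#' @param drop_empty_cols drop columns with no remaining called allele
#'   (default `TRUE`).
#' @return a preprocessed `snp_matrix`; attribute `col_index` gives, for each
#'   retained column, its original index.
#' @export
preprocess_fragments <- function(m, drop_empty_cols = TRUE) {
  sp <- spans_of(m)
  keep_rows <- which(sp$n_called >= 2L)
  a <- unclass(m)[keep_rows, , drop = FALSE]
  ids <- row_ids(m)[keep_rows]
  quals <- attr(m, "quals")
  if (!is.null(quals)) quals <- quals[keep_rows]
  col_index <- seq_len(ncol(m))
  if (drop_empty_cols && nrow(a)) {
    covered <- colSums(!is.na(a)) > 0
    a <- a[, covered, drop = FALSE]
    col_index <- col_index[covered]
  } else if (drop_empty_cols && !nrow(a)) {
    a <- a[, integer(0), drop = FALSE]
    col_index <- integer(0)
  }
  attr(a, "row_ids") <- NULL
  new_snp_matrix(a, row_ids = ids, quals = quals, col_index = col_index)
}

#' Sort fragments by span
#'
#' Stable sort of fragments by `(l, r)`: fragment `i1` precedes `i2` when
#' `l(i1) < l(i2)`, or `l(i1) = l(i2)` and `r(i1) <= r(i2)`. Ties on both
#' bounds keep their input order, so the result is deterministic. The H-BOP
#' dynamic program requires this order.
#'
#' @param m an `snp_matrix` (fragments should cover >= 2 loci; see
#'   [preprocess_fragments()]).
#' @return the sorted `snp_matrix`; original identifiers travel with rows.
#' @export
sort_fragments <- function(m) {
  sp <- spans_of(m)
  ord <- order(sp$l, sp$r)  # radix sort: stable on ties
  a <- unclass(m)[ord, , drop = FALSE]
  attr(a, "row_ids") <- NULL
  quals <- attr(m, "quals")
  new_snp_matrix(a,
    row_ids = row_ids(m)[ord],
    quals = if (is.null(quals)) NULL else quals[ord],
    col_index = attr(m, "col_index")
  )
}

is_span_sorted <- function(l, r) {
  if (length(l) < 2) return(TRUE)
  dl <- diff(l)
  all(dl > 0 | (dl == 0 & diff(r) >= 0))
}

#' Active fragment set at a row
#'
#' For sorted fragments, the active set `R(i)` holds the fragments among the
#' first `i` whose span covers column `l(i)`, i.e.
#' `R(i) = { i' <= i : l(i') <= l(i) <= r(i') }`. It always contains `i`
#' itself and is the state over which the H-BOP dynamic program keeps
#' candidate partitions.
#'
#' @param m a sorted `snp_matrix`.
#' @param i row index in `1..m`.
#' @return an integer vector of row indices (ascending).
#' @export
active_set <- function(m, i) {
  mm <- nrow(m)
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > mm) {
    stop("`i` must be a row index in 1..", mm, call. = FALSE)
  }
  i <- as.integer(i)
  sp <- spans_of(m)
  if (!is_span_sorted(sp$l, sp$r)) {
    stop("fragments are not sorted; call sort_fragments() first", call. = FALSE)
  }
  cand <- seq_len(i)
  cand[sp$l[cand] <= sp$l[i] & sp$r[cand] >= sp$l[i]]
}

#' Haplotype blocks (connected components of the SNP-site graph)
#'
#' Two SNP sites are joined by an edge when at least one fragment calls an
#' allele at both; a haplotype block is a connected component of this graph.
#' Phase is only determinable within a block. Singleton components (sites
#' never linked to another site, including uncovered sites) cannot be phased.
#'
#' @param m an `snp_matrix`.
#' @return a tibble with one row per block, ordered by smallest site:
#'   `block` (id), `sites` (list column of ascending site indices),
#'   `rows` (list column of fragment indices whose called sites lie in the
#'   block), `n_sites`, `n_rows`, and `phaseable` (`n_sites >= 2`).
#' @export
snp_blocks <- function(m) {
  n <- ncol(m)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(m))) {
    idx <- which(!is.na(m[i, ]))
    if (length(idx) >= 2) {
      for (k in seq_along(idx)[-1]) {
        ra <- find(idx[k - 1L]); rb <- find(idx[k])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  site_groups <- split(seq_len(n), comp)
  first_site <- vapply(site_groups, min, integer(1))
  site_groups <- site_groups[order(first_site)]
  names(site_groups) <- NULL

  row_l <- spans_of(m)$l
  row_comp <- ifelse(is.na(row_l), NA_integer_, comp[row_l])
  block_comp <- vapply(site_groups, function(s) comp[s[1]], integer(1))
  rows <- lapply(block_comp, function(bc) which(!is.na(row_comp) & row_comp == bc))

  tibble::tibble(
    block = seq_along(site_groups),
    sites = site_groups,
    rows = rows,
    n_sites = lengths(site_groups),
    n_rows = lengths(rows),
    phaseable = lengths(site_groups) >= 2L
  )
}
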
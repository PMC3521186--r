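#' Incremental score updates for the H-BOP recurrence
#'
#' When the dynamic program extends partitions of the carried-over active
#' set `Rc(i, i+1) = R(i) intersect R(i+1)` with row `i + 1`, the two score
#' components change only over the new row's span. `delta_ec()` returns the
#' change in the errors-corrected measure: for each column `j` in
#' `[l(i+1), r(i+1)]` at which row `i + 1` calls an allele, the minority
#' count `min(N[1,1]+N[2,0], N[1,0]+N[2,1])` over the `Rc` rows covering `j`
#' is subtracted and re-added after including the new row's allele.
#' `delta_fc()` returns the change in the fragments-cut measure: each `Rc`
#' row in the other group with a called allele in the new row's span
#' contributes -1 if the alleles agree and +1 if they disagree.
#'
#' @param m a sorted `snp_matrix` (see [sort_fragments()]).
#' @param i the number of rows already processed; row `i + 1` is being added.
#' @param p integer vector of group labels (0/1) indexed by row, assigning at
#'   least every row of `Rc(i, i+1)` and row `i + 1` (other positions may be
#'   `NA`).
#' @return an integer score difference.
#' @export
delta_ec <- function(m, i, p) {
  info <- delta_prep(m, i, p)
  delta <- 0L
  for (j in info$cols) {
    v_new <- info$a[i + 1L, j]
    if (is.na(v_new)) next
    n <- c(`10` = 0L, `11` = 0L, `20` = 0L, `21` = 0L)
    for (l in info$rc) {
      v <- info$a[l, j]
      if (is.na(v)) next
      key <- paste0(info$p[l] + 1L, v)
      n[key] <- n[key] + 1L
    }
    delta <- delta - min(n[["11"]] + n[["20"]], n[["10"]] + n[["21"]])
    key <- paste0(info$p[i + 1L] + 1L, v_new)
    n[key] <- n[key] + 1L
    delta <- delta + min(n[["11"]] + n[["20"]], n[["10"]] + n[["21"]])
  }
  delta
}

#' @rdname delta_ec
#' @export
delta_fc <- function(m, i, p) {
  info <- delta_prep(m, i, p)
  g0 <- info$p[i + 1L]
  delta <- 0L
  for (j in info$cols) {
    v_new <- info$a[i + 1L, j]
    if (is.na(v_new)) next
    for (l in info$rc) {
      v <- info$a[l, j]
      if (is.na(v) || info$p[l] == g0) next
      delta <- delta + if (v == v_new) -1L else 1L
    }
  }
  delta
}

delta_prep <- function(m, i, p) {
  sp <- spans_of(m)
  if (!is_span_sorted(sp$l, sp$r)) {
    stop("fragments are not sorted; call sort_fragments() first", call. = FALSE)
  }
  if (i < 1 || i + 1 > nrow(m)) stop("row i + 1 out of range", call. = FALSE)
  rc <- which(seq_len(i) <= i & sp$r[seq_len(i)] >= sp$l[i + 1L])
  p <- as.integer(p)
  needed <- c(rc, i + 1L)
  if (length(p) < i + 1L || anyNA(p[needed])) {
    stop("`p` must assign every row of Rc(i, i+1) and row i + 1", call. = FALSE)
  }
  list(a = unclass(m), cols = sp$l[i + 1L]:sp$r[i + 1L], rc = rc, p = p)
}

#' Phase fragments with the H-BOP beam dynamic program
#'
#' Solves the Balanced Optimal Partition model heuristically: fragments are
#' sorted by span and added one at a time; the algorithm keeps, for the
#' active set `R(i)` (fragments among the first `i` spanning column `l(i)`),
#' at most `k` candidate partitions with the smallest running partition
#' scores. Scores are updated incrementally ([delta_ec()], [delta_fc()]),
#' partitions are stored in canonical form (smallest active fragment in
#' group 0) and candidates that project to the same partition of the
#' carried-over set are merged keeping the minimum score. With
#' `k >= 2^(q-1)` for every active-set size `q` the search is exhaustive and
#' the result exact. The run is deterministic given `(m, w, k)`; ties are
#' broken in favour of earlier-generated candidates.
#'
#' Time grows as `O(m * k * k1 * k2)` where `k1` is the maximum span length
#' and `k2` the maximum active-set size.
#'
#' @param m an `snp_matrix`; every fragment must cover at least two loci
#'   (see [preprocess_fragments()]). Sorting is performed internally.
#' @param w non-negative weight factor of the BOP objective (default 0.1).
#' @param k beam width, a positive integer (default 8).
#' @param ties how the induced haplotype treats majority-vote ties at a
#'   locus: `"unphase"` (default; the site is reported undetermined) or
#'   `"phase"` (the `<=` rule decides; see [haplotype_from_partition()]).
#' @param audit record, for every dynamic-programming step, every surviving
#'   candidate's full extension and running score components (for
#'   consistency checking; slows the run).
#' @return an object of class `hbop_fit`: a list with elements `partition`
#'   (canonical 0/1 labels in the input row order), `haplotype`
#'   (a [haplotype_pair()]), `score` (a `score_breakdown`), `w`, `k`, `ops`
#'   (count of elementary beam operations), and `audit` (list of per-step
#'   beam snapshots, or `NULL`).
#' @examples
#' m <- snp_matrix(c("0011", "0010", "1100", "1101"))
#' fit <- hbop_phase(m, w = 0.1, k = 8)
#' fit$score
#' @export
hbop_phase <- function(m, w = 0.1, k = 8, ties = c("unphase", "phase"),
                       audit = FALSE) {
  ties <- match.arg(ties)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("beam width `k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (!is.numeric(w) || length(w) != 1 || w < 0) {
    stop("`w` must be a single non-negative number", call. = FALSE)
  }
  mm <- nrow(m)
  if (mm == 0) {
    return(new_hbop_fit(
      partition = integer(0),
      haplotype = haplotype_pair(integer(ncol(m)), phased = rep(FALSE, ncol(m))),
      sc = 0L, sd = 0L, w = w, k = k, ops = 0L, audit = NULL,
      row_ids = character(0)
    ))
  }
  sp <- spans_of(m)
  if (any(sp$n_called < 2)) {
    stop("every fragment must cover >= 2 loci; run preprocess_fragments()",
      call. = FALSE)
  }
  ord <- order(sp$l, sp$r)
  ms <- sort_fragments(m)
  res <- hbop_dp(ms, w = w, k = k, audit = audit)
  p <- integer(mm)
  p[ord] <- res$ext
  p <- canonical_partition(p)
  new_hbop_fit(
    partition = p,
    haplotype = haplotype_from_partition(p, m, ties = ties),
    sc = res$sc, sd = res$sd, w = w, k = k, ops = res$ops,
    audit = res$audit, row_ids = row_ids(m)
  )
}

new_hbop_fit <- function(partition, haplotype, sc, sd, w, k, ops, audit,
                         row_ids) {
  structure(
    list(
      partition = partition,
      haplotype = haplotype,
      score = structure(
        list(
          errors_corrected = as.integer(sc),
          fragments_cut = as.integer(sd),
          partition_score = sc - w * sd,
          w = w
        ),
        class = "score_breakdown"
      ),
      w = w, k = k, ops = ops, audit = audit, row_ids = row_ids
    ),
    class = "hbop_fit"
  )
}

#' @export
print.hbop_fit <- function(x, ...) {
  cat(sprintf(
    "<hbop_fit: %d fragment(s), k = %d, w = %g>\n", length(x$partition),
    x$k, x$w
  ))
  print(x$score)
  cat(sprintf("  phased sites: %d of %d\n", sum(x$haplotype$phased),
    length(x$haplotype$h1)))
  invisible(x)
}

## The beam DP over a sorted matrix. Beam entries are lists
## (act, ext, sc, sd): `act` the canonical partition of the current active
## rows, `ext` the full group assignment of rows 1..i, `sc`/`sd` the integer
## score components of `ext` on M[1..i, ].
hbop_dp <- function(ms, w, k, audit = FALSE) {
  a <- unclass(ms)
  mm <- nrow(a)
  sp <- spans_of(ms)
  l <- sp$l; r <- sp$r
  ratio <- w_as_ratio(w)
  rowcols <- lapply(seq_len(mm), function(i) which(!is.na(a[i, ])))

  beam <- list(list(act = 0L, ext = 0L, sc = 0L, sd = 0L))
  act_rows <- 1L
  ops <- 0L
  snapshots <- if (audit) list(beam_snapshot(1L, beam)) else NULL

  for (i in seq_len(mm - 1L)) {
    lnext <- l[i + 1L]
    keep <- which(r[act_rows] >= lnext)
    rc_rows <- act_rows[keep]

    ## project onto Rc(i, i+1), canonicalize, merge duplicates keeping the
    ## minimum score (ties: earlier candidate wins)
    proj <- list()
    proj_keys <- character(0)
    for (entry in beam) {
      pa <- entry$act[keep]
      ext <- entry$ext
      if (length(pa) && pa[1] == 1L) {
        pa <- 1L - pa
        ext <- 1L - ext
      }
      key <- paste(pa, collapse = "")
      hit <- match(key, proj_keys)
      if (is.na(hit)) {
        proj[[length(proj) + 1L]] <- list(act = pa, ext = ext,
          sc = entry$sc, sd = entry$sd)
        proj_keys <- c(proj_keys, key)
      } else {
        old <- proj[[hit]]
        if (score_key(entry$sc, entry$sd, ratio, w) <
            score_key(old$sc, old$sd, ratio, w)) {
          proj[[hit]] <- list(act = pa, ext = ext,
            sc = entry$sc, sd = entry$sd)
        }
      }
    }

    ## per-column coverage of the new row's called loci by Rc rows
    cols <- rowcols[[i + 1L]]
    cover <- lapply(cols, function(j) {
      pos <- which(!is.na(a[rc_rows, j, drop = TRUE]))
      list(pos = pos, v = a[rc_rows[pos], j])
    })
    vals_new <- a[i + 1L, cols]

    children <- vector("list", 2L * length(proj))
    nch <- 0L
    for (entry in proj) {
      dec <- c(0L, 0L)  # delta errors-corrected for child group 0 / 1
      dfc <- c(0L, 0L)  # delta fragments-cut
      for (t in seq_along(cols)) {
        pos <- cover[[t]]$pos
        v <- cover[[t]]$v
        g <- entry$act[pos]
        n10 <- sum(v == 0L & g == 0L); n11 <- sum(v == 1L & g == 0L)
        n20 <- sum(v == 0L & g == 1L); n21 <- sum(v == 1L & g == 1L)
        base <- min(n11 + n20, n10 + n21)
        vn <- vals_new[t]
        ## child joining group 0
        m0 <- if (vn == 0L) min(n11 + n20, n10 + 1L + n21) else
          min(n11 + 1L + n20, n10 + n21)
        ## child joining group 1
        m1 <- if (vn == 0L) min(n11 + n20 + 1L, n10 + n21) else
          min(n11 + n20, n10 + n21 + 1L)
        dec[1L] <- dec[1L] + (m0 - base)
        dec[2L] <- dec[2L] + (m1 - base)
        eq0 <- sum(g == 0L & v == vn); cr0 <- sum(g == 0L)
        eq1 <- sum(g == 1L & v == vn); cr1 <- sum(g == 1L)
        dfc[1L] <- dfc[1L] + (cr1 - eq1) - eq1  # cross rows are group 1
        dfc[2L] <- dfc[2L] + (cr0 - eq0) - eq0
        ops <- ops + length(pos) + 1L
      }
      groups <- if (length(rc_rows)) 0:1 else 0L  # canonical when Rc empty
      for (g_new in groups) {
        nch <- nch + 1L
        children[[nch]] <- list(
          act = c(entry$act, g_new),
          ext = c(entry$ext, g_new),
          sc = entry$sc + dec[g_new + 1L],
          sd = entry$sd + dfc[g_new + 1L]
        )
      }
    }
    children <- children[seq_len(nch)]

    ## beam selection: keep the k smallest scores; stable order makes the
    ## earlier-inserted candidate win ties (heap replace-if-strictly-smaller)
    if (length(children) > k) {
      keys <- vapply(children, function(e) {
        as.numeric(score_key(e$sc, e$sd, ratio, w))
      }, numeric(1))
      children <- children[sort.list(keys, method = "radix")[seq_len(k)]]
    }
    beam <- children
    act_rows <- c(rc_rows, i + 1L)
    if (audit) snapshots[[length(snapshots) + 1L]] <- beam_snapshot(i + 1L, beam)
  }

  keys <- vapply(beam, function(e) {
    as.numeric(score_key(e$sc, e$sd, ratio, w))
  }, numeric(1))
  best <- beam[[which.min(keys)]]
  list(ext = best$ext, sc = best$sc, sd = best$sd, ops = ops,
    audit = snapshots)
}

beam_snapshot <- function(i, beam) {
  list(i = i, entries = lapply(beam, function(e) {
    list(ext = e$ext, sc = e$sc, sd = e$sd)
  }))
}

## subset an snp_matrix keeping attributes aligned
submatrix <- function(m, rows, cols) {
  a <- unclass(m)[rows, cols, drop = FALSE]
  attr(a, "row_ids") <- NULL
  quals <- attr(m, "quals")
  new_snp_matrix(a,
    row_ids = row_ids(m)[rows],
    quals = if (is.null(quals)) NULL else quals[rows]
  )
}

#' Phase every haplotype block independently
#'
#' Decomposes the input into haplotype blocks (connected components of the
#' SNP-site graph, [snp_blocks()]), runs [hbop_phase()] on each phaseable
#' block's submatrix, and assembles a genome-wide haplotype pair. Because
#' fragments never link sites across blocks, the block decomposition is an
#' exact decomposition of the BOP objective: per-block optima compose into
#' a whole-matrix optimum and per-block scores add up. Singleton blocks
#' (sites never linked to a second site) are reported unphased. Fragments
#' covering fewer than two loci are removed first, as in
#' [preprocess_fragments()].
#'
#' @inheritParams hbop_phase
#' @return an object of class `hbop_blocks_fit`: a list with elements
#'   `blocks` (a tibble with one row per block: `block`, `n_sites`,
#'   `n_rows`, `phaseable`, `sc`, `sd`, `sp`, `n_phased`, `sites`),
#'   `haplotype` (genome-wide [haplotype_pair()]; unphased outside
#'   phaseable blocks), `partition` (per-fragment group labels in input
#'   order, `NA` for removed fragments; labels are canonical within each
#'   block), `score` (summed `score_breakdown`), `w`, `k`, `kept_rows`.
#' @examples
#' sim <- simulate_fragments(n = 30, m = 40, l = 3, e = 0.01, g = 0.1, seed = 1)
#' fit <- phase_blocks(sim$matrix)
#' glance(fit)
#' @export
phase_blocks <- function(m, w = 0.1, k = 8, ties = c("unphase", "phase")) {
  ties <- match.arg(ties)
  n <- ncol(m)
  sp <- spans_of(m)
  kept_rows <- which(sp$n_called >= 2L)
  mk <- submatrix(m, kept_rows, seq_len(n))
  bl <- snp_blocks(mk)

  h1 <- integer(n); phased <- logical(n)
  partition <- rep(NA_integer_, nrow(m))
  sc_b <- integer(nrow(bl)); sd_b <- integer(nrow(bl))
  nph_b <- integer(nrow(bl))

  for (b in seq_len(nrow(bl))) {
    if (!bl$phaseable[b] || bl$n_rows[b] == 0) next
    sub <- submatrix(mk, bl$rows[[b]], bl$sites[[b]])
    fit <- hbop_phase(sub, w = w, k = k, ties = ties)
    sites <- bl$sites[[b]]
    h1[sites] <- fit$haplotype$h1
    phased[sites] <- fit$haplotype$phased
    partition[kept_rows[bl$rows[[b]]]] <- fit$partition
    sc_b[b] <- fit$score$errors_corrected
    sd_b[b] <- fit$score$fragments_cut
    nph_b[b] <- sum(fit$haplotype$phased)
  }

  blocks <- tibble::tibble(
    block = bl$block,
    n_sites = bl$n_sites,
    n_rows = bl$n_rows,
    phaseable = bl$phaseable,
    sc = sc_b, sd = sd_b, sp = sc_b - w * sd_b,
    n_phased = nph_b,
    sites = bl$sites
  )
  sc <- sum(sc_b); sd <- sum(sd_b)
  structure(
    list(
      blocks = blocks,
      haplotype = haplotype_pair(h1, 1L - h1, phased),
      partition = partition,
      score = structure(
        list(
          errors_corrected = as.integer(sc),
          fragments_cut = as.integer(sd),
          partition_score = sc - w * sd,
          w = w
        ),
        class = "score_breakdown"
      ),
      w = w, k = k, kept_rows = kept_rows, row_ids = row_ids(m)
    ),
    class = "hbop_blocks_fit"
  )
}

#' @export
print.hbop_blocks_fit <- function(x, ...) {
  cat(sprintf(
    "<hbop_blocks_fit: %d block(s), %d phaseable, k = %d, w = %g>\n",
    nrow(x$blocks), sum(x$blocks$phaseable), x$k, x$w
  ))
  print(x$score)
  cat(sprintf("  phased sites: %d of %d\n", sum(x$haplotype$phased),
    length(x$haplotype$h1)))
  invisible(x)
}
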
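#' Construct a haplotype pair
#'
#' A pair of complementary length-`n` haplotypes over `{0,1}`. All loci are
#' assumed heterozygous, so `h2` is the site-wise complement of `h1` at every
#' phased site. The `phased` flag marks sites at which the pair actually
#' determines the alleles; metrics such as phased length and switch errors
#' only look at phased sites.
#'
#' @param h1,h2 integer (or character `"0"`/`"1"`) vectors of equal length;
#'   `h2` defaults to the complement of `h1`.
#' @param phased logical vector of per-site determination flags (default all
#'   `TRUE`).
#' @return an object of class `haplotype_pair` (a list with elements `h1`,
#'   `h2`, `phased`).
#' @export
haplotype_pair <- function(h1, h2 = 1L - h1, phased = rep(TRUE, length(h1))) {
  if (is.character(h1)) h1 <- chars_to_alleles(strsplit(paste(h1, collapse = ""), "", fixed = TRUE)[[1]])
  if (is.character(h2)) h2 <- chars_to_alleles(strsplit(paste(h2, collapse = ""), "", fixed = TRUE)[[1]])
  h1 <- as.integer(h1); h2 <- as.integer(h2)
  stopifnot(length(h1) == length(h2), length(phased) == length(h1))
  if (any(h1[phased] + h2[phased] != 1L)) {
    stop("h1 and h2 must be complementary at phased sites (heterozygous loci)",
      call. = FALSE)
  }
  structure(list(h1 = h1, h2 = h2, phased = as.logical(phased)),
    class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  n <- length(x$h1)
  cat(sprintf("<haplotype_pair: %d site(s), %d phased>\n", n, sum(x$phased)))
  if (n <= 80) {
    show <- function(h) paste(ifelse(x$phased, as.character(h), "."), collapse = "")
    cat("  H1: ", show(x$h1), "\n  H2: ", show(x$h2), "\n", sep = "")
  }
  invisible(x)
}

as_allele <- function(a) {
  if (is.character(a)) chars_to_alleles(a) else as.integer(a)
}

#' Allele conflict indicator
#'
#' `allele_conflict(a, b)` is 1 when both alleles are called and disagree,
#' else 0; a gap never conflicts. `allele_pair_weight(a, b)` is the signed
#' agreement weight used by the fragments-cut measure: -1 when both are
#' called and equal, +1 when both are called and unequal, 0 when either is a
#' gap.
#'
#' @param a,b alleles as `"0"`/`"1"`/`"-"` or integer 0/1/`NA` (vectorized).
#' @return an integer vector.
#' @export
allele_conflict <- function(a, b) {
  a <- as_allele(a); b <- as_allele(b)
  as.integer(!is.na(a) & !is.na(b) & a != b)
}

#' @rdname allele_conflict
#' @export
allele_pair_weight <- function(a, b) {
  a <- as_allele(a); b <- as_allele(b)
  out <- rep(0L, max(length(a), length(b)))
  both <- !is.na(a) & !is.na(b)
  out[both & a == b] <- -1L
  out[both & a != b] <- 1L
  out
}

#' Pairwise fragment weight
#'
#' The edge weight between two fragments in the weighted conflict graph:
#' the sum over loci of [allele_pair_weight()]. Negative weights mean the
#' fragments mostly agree (likely same chromosome), positive weights mean
#' they mostly disagree.
#'
#' @param f1,f2 two fragments of equal length (allele vectors or strings).
#' @return an integer.
#' @export
fragment_weight <- function(f1, f2) {
  if (is.character(f1) && length(f1) == 1) f1 <- strsplit(f1, "", fixed = TRUE)[[1]]
  if (is.character(f2) && length(f2) == 1) f2 <- strsplit(f2, "", fixed = TRUE)[[1]]
  f1 <- as_allele(f1); f2 <- as_allele(f2)
  if (length(f1) != length(f2)) stop("fragments differ in length", call. = FALSE)
  sum(allele_pair_weight(f1, f2))
}

#' Errors-corrected measure of a haplotype pair
#'
#' The MEC objective: each fragment is matched against whichever haplotype
#' fits it better, and the per-fragment minimum conflict counts are summed.
#' This lower-bounds the number of sequencing errors under the assumption
#' that the pair is the truth.
#'
#' @param h a [haplotype_pair()] covering all columns of `m`.
#' @param m an `snp_matrix`.
#' @return a non-negative integer.
#' @export
errors_corrected <- function(h, m) {
  if (length(h$h1) != ncol(m)) {
    stop("haplotype length ", length(h$h1), " does not match matrix width ",
      ncol(m), call. = FALSE)
  }
  if (nrow(m) == 0) return(0L)
  a <- unclass(m)
  conf1 <- sweep(a, 2, h$h1, function(x, y) !is.na(x) & x != y)
  conf2 <- sweep(a, 2, h$h2, function(x, y) !is.na(x) & x != y)
  sum(pmin(rowSums(conf1), rowSums(conf2)))
}

check_partition <- function(p, m) {
  p <- as.integer(p)
  if (length(p) != nrow(m) || anyNA(p) || any(p != 0L & p != 1L)) {
    stop("partition must assign 0 or 1 to every fragment of the matrix",
      call. = FALSE)
  }
  p
}

#' Canonical form of a fragment partition
#'
#' A bipartition and its complement describe the same phasing; the canonical
#' representative assigns group 0 to the smallest-indexed fragment.
#'
#' @param p integer vector of 0/1 group labels.
#' @return the canonical 0/1 vector.
#' @export
canonical_partition <- function(p) {
  p <- as.integer(p)
  if (length(p) && p[1] == 1L) 1L - p else p
}

#' Fragments-cut measure of a partition
#'
#' The MFC objective: the total [fragment_weight()] over all unordered
#' cross-group fragment pairs, i.e. the cut value of the partition in the
#' weighted conflict graph. May be negative.
#'
#' @param p integer vector assigning each fragment of `m` to group 0 or 1.
#' @param m an `snp_matrix`.
#' @return an integer.
#' @export
cut_score <- function(p, m) {
  p <- check_partition(p, m)
  if (nrow(m) < 2) return(0L)
  ## +/-1 encoding: column-wise product is -allele_pair_weight
  b <- unclass(m)
  b <- ifelse(is.na(b), 0, ifelse(b == 0L, 1, -1))
  w <- -tcrossprod(b)
  cross <- outer(p, p, "!=")
  as.integer(sum(w[cross]) / 2)
}

## per-column group/allele counts for a partition (group 1 = label 0)
column_counts <- function(p, m) {
  a <- unclass(m)
  g0 <- p == 0L
  list(
    n10 = colSums(!is.na(a) & a == 0L & g0),
    n11 = colSums(!is.na(a) & a == 1L & g0),
    n20 = colSums(!is.na(a) & a == 0L & !g0),
    n21 = colSums(!is.na(a) & a == 1L & !g0)
  )
}

#' Majority-vote haplotype induced by a partition
#'
#' For each locus `j`, count `N[g,v]`, the fragments of group `g` calling
#' allele `v`. The induced pair sets `H1[j] = 0` when
#' `N[1,1] + N[2,0] <= N[1,0] + N[2,1]` and `H1[j] = 1` otherwise; `H2` is
#' the complement. Loci with no called allele are always flagged unphased
#' (their alleles fall out of the `<=` rule on zero counts but carry no
#' information). A locus where the two sides of the rule tie is ambiguous:
#' with `ties = "phase"` it is kept phased (the `<=` branch wins, a
#' deterministic convention), with `ties = "unphase"` it is flagged
#' undetermined, which is how the solver pipeline reports phased length.
#'
#' @param p integer vector of 0/1 group labels over the fragments of `m`.
#' @param m an `snp_matrix`.
#' @param ties `"phase"` or `"unphase"` (see above).
#' @return a [haplotype_pair()] with per-site `phased` flags.
#' @export
haplotype_from_partition <- function(p, m, ties = c("phase", "unphase")) {
  ties <- match.arg(ties)
  p <- check_partition(p, m)
  cc <- column_counts(p, m)
  lhs <- cc$n11 + cc$n20
  rhs <- cc$n10 + cc$n21
  h1 <- as.integer(lhs > rhs)
  covered <- (lhs + rhs) > 0
  phased <- covered
  if (ties == "unphase") phased <- phased & (lhs != rhs)
  haplotype_pair(h1, 1L - h1, phased)
}

#' Partition induced by a haplotype pair
#'
#' Each fragment goes to group 0 (the `H1` side) when it conflicts strictly
#' less with `H1` than with `H2`; ties and the reverse go to group 1. The
#' result is canonicalized.
#'
#' @param h a [haplotype_pair()] defined on all columns of `m`.
#' @param m an `snp_matrix`.
#' @return an integer 0/1 vector, one label per fragment.
#' @export
partition_from_haplotype <- function(h, m) {
  a <- unclass(m)
  conf1 <- rowSums(sweep(a, 2, h$h1, function(x, y) !is.na(x) & x != y))
  conf2 <- rowSums(sweep(a, 2, h$h2, function(x, y) !is.na(x) & x != y))
  canonical_partition(as.integer(!(conf1 < conf2)))
}

## columnwise errors-corrected measure of a partition: each fragment is
## charged against its own group's majority haplotype. This is the quantity
## the H-BOP recurrences accumulate; it can exceed errors_corrected() of the
## induced pair when a fragment happens to fit the other group better.
partition_ec <- function(p, m) {
  cc <- column_counts(p, m)
  as.integer(sum(pmin(cc$n11 + cc$n20, cc$n10 + cc$n21)))
}

#' Balanced partition score
#'
#' The BOP objective `sp = sc - w * sd` of a fragment bipartition: `sc` is
#' the errors-corrected measure of the partition (the summed conflicts
#' between each fragment and the majority haplotype of its own group, equal
#' to `sum_j min(N[1,1]+N[2,0], N[1,0]+N[2,1])`), `sd` is the fragments-cut
#' measure ([cut_score()]), and `w >= 0` trades the two off. `w = 0` reduces
#' BOP to MEC; large `w` emphasizes the max-cut objective. Smaller `sp` is
#' better.
#'
#' Note `sc` charges every fragment to its own group; it can exceed
#' [errors_corrected()] of the induced pair when a fragment sits in the
#' "wrong" group, because the MEC measure lets each fragment defect to the
#' better-fitting haplotype.
#'
#' @param p integer vector of 0/1 group labels over the fragments of `m`.
#' @param m an `snp_matrix`.
#' @param w non-negative weight factor (default 0.1).
#' @return a list of class `score_breakdown` with integer fields
#'   `errors_corrected` (`sc`), `fragments_cut` (`sd`) and real
#'   `partition_score` (`sp = sc - w * sd`), plus `w`.
#' @export
partition_score <- function(p, m, w = 0.1) {
  if (!is.numeric(w) || length(w) != 1 || w < 0) {
    stop("`w` must be a single non-negative number", call. = FALSE)
  }
  p <- check_partition(p, m)
  sc <- partition_ec(p, m)
  sd <- cut_score(p, m)
  structure(
    list(
      errors_corrected = sc,
      fragments_cut = sd,
      partition_score = sc - w * sd,
      w = w
    ),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "<score_breakdown: sc = %d, sd = %d, sp = sc - %g*sd = %g>\n",
    x$errors_corrected, x$fragments_cut, x$w, x$partition_score
  ))
  invisible(x)
}

## Exact score comparison. For rational w = p/q (q <= 1e6), scores are
## compared as the integer q*sc - p*sd, avoiding float ties; otherwise fall
## back to the float value sc - w*sd.
w_as_ratio <- function(w) {
  for (q in c(1L, 10L, 100L, 1000L, 10000L, 100000L, 1000000L)) {
    p <- w * q
    if (abs(p - round(p)) < 1e-9) return(c(p = round(p), q = q))
  }
  NULL
}

score_key <- function(sc, sd, ratio, w) {
  if (!is.null(ratio)) ratio[["q"]] * sc - ratio[["p"]] * sd else sc - w * sd
}
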
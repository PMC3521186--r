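#' Exact BOP solver by exhaustive partition enumeration
#'
#' Enumerates all `2^(m-1)` canonical bipartitions of the fragments and
#' returns one minimizing the partition score `sp = sc - w * sd`
#' ([partition_score()]). Deliberately simple and slow; intended as a
#' correctness oracle and for tiny instances. Ties are broken towards the
#' smallest binary encoding of the partition (row 2 is the least significant
#' bit).
#'
#' @param m an `snp_matrix` with at most `cap` fragments.
#' @param w non-negative weight factor (default 0.1).
#' @param cap refuse instances with more fragments than this (default 20).
#' @return a list with elements `partition` (canonical 0/1 labels) and
#'   `score` (a `score_breakdown`).
#' @export
exact_bop <- function(m, w = 0.1, cap = 20) {
  mm <- nrow(m)
  if (mm > cap) {
    stop("exact_bop enumerates 2^(m-1) partitions; m = ", mm,
      " exceeds cap = ", cap, call. = FALSE)
  }
  if (mm == 0) {
    return(list(partition = integer(0),
      score = partition_score(integer(0), m, w)))
  }
  ratio <- w_as_ratio(w)
  best_p <- NULL
  best_key <- Inf
  for (code in 0:(2^(mm - 1L) - 1L)) {
    bits <- as.integer(bitwAnd(code %/% 2^(seq_len(mm - 1L) - 1L), 1L))
    p <- c(0L, bits)
    sc <- partition_ec(p, m)
    sd <- cut_score(p, m)
    key <- score_key(sc, sd, ratio, w)
    if (key < best_key) {
      best_key <- key
      best_p <- p
    }
  }
  list(partition = best_p, score = partition_score(best_p, m, w))
}

#' Exact MEC solver by exhaustive haplotype enumeration
#'
#' Enumerates all `2^(n-1)` haplotype pairs (fixing `H1[1] = 0` by
#' complement symmetry) and returns a pair minimizing the errors-corrected
#' measure ([errors_corrected()]). Oracle / tiny-instance use only.
#'
#' @param m an `snp_matrix` with at most `cap` SNP loci.
#' @param cap refuse instances with more loci than this (default 20).
#' @return a list with elements `haplotype` (a [haplotype_pair()]) and
#'   `errors_corrected` (the optimum, an integer).
#' @export
exact_mec <- function(m, cap = 20) {
  n <- ncol(m)
  if (n > cap) {
    stop("exact_mec enumerates 2^(n-1) haplotype pairs; n = ", n,
      " exceeds cap = ", cap, call. = FALSE)
  }
  if (n == 0) {
    return(list(haplotype = haplotype_pair(integer(0)), errors_corrected = 0L))
  }
  best_h <- NULL
  best_sc <- Inf
  for (code in 0:(2^(n - 1L) - 1L)) {
    h1 <- c(0L, as.integer(bitwAnd(code %/% 2^(seq_len(n - 1L) - 1L), 1L)))
    h <- haplotype_pair(h1)
    sc <- errors_corrected(h, m)
    if (sc < best_sc) {
      best_sc <- sc
      best_h <- h
    }
  }
  list(haplotype = best_h, errors_corrected = as.integer(best_sc))
}
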
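#' Simulate sequencing fragments from a random haplotype pair
#'
#' Emulates the standard single-individual-haplotyping simulation protocol.
#' A haplotype `h1` of `n` heterozygous SNPs is drawn uniformly at random
#' and `h2` is its complement. Half of the `m` fragments are sampled from
#' each haplotype (for odd `m`, the extra fragment comes from `h1`):
#' each fragment's length is a normal draw with mean `l` and
#' variance 1, rounded to the nearest integer and clamped to
#' `[2, min(4 * l, n)]`; its start is uniform over the positions at which it
#' fits. Each allele is then flipped with probability `e` (sequencing
#' error), and each allele except the fragment's first and last is deleted
#' (set to `-`) with probability `g` (gap). Because the end alleles are
#' never deleted, every fragment keeps at least two called alleles.
#'
#' The order of random draws is fixed: haplotype first, then per fragment
#' (first the `m/2` fragments from `h1`, then those from `h2`): length,
#' start, flips left to right, deletions left to right. Given `seed` the
#' dataset is bit-reproducible, and the caller's RNG state is left
#' untouched.
#'
#' @param n haplotype length (number of SNPs), at least 2.
#' @param m number of fragments, an even number, at least 2.
#' @param l mean fragment length, in `[2, n]`.
#' @param e per-allele flip probability in `[0, 1]`.
#' @param g per-interior-allele deletion probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return an object of class `sih_sim`: a list with elements `truth`
#'   (a [haplotype_pair()]), `matrix` (an `snp_matrix` whose rows record
#'   their source haplotype in `row_ids`), `call_coverage` (total called
#'   alleles divided by `n`), and `params`.
#' @examples
#' sim <- simulate_fragments(n = 50, m = 70, l = 3, e = 0.01, g = 0.1, seed = 1)
#' sim$call_coverage
#' @export
simulate_fragments <- function(n, m, l, e, g, seed = NULL) {
  stopifnot(n >= 2, m >= 2, l >= 2, e >= 0, e <= 1, g >= 0, g <= 1)
  if (l > n) stop("mean fragment length l exceeds haplotype length n",
    call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  h1 <- sample(0:1, n, replace = TRUE)
  truth <- haplotype_pair(h1)
  max_len <- min(4L * ceiling(l), n)

  a <- matrix(NA_integer_, nrow = m, ncol = n)
  src <- rep(1:2, times = c(ceiling(m / 2), floor(m / 2)))
  for (i in seq_len(m)) {
    len <- as.integer(round(stats::rnorm(1, mean = l, sd = 1)))
    len <- max(2L, min(max_len, len))
    start <- sample.int(n - len + 1L, 1L)
    hap <- if (src[i] == 1L) truth$h1 else truth$h2
    frag <- hap[start:(start + len - 1L)]
    flip <- stats::runif(len) < e
    frag <- ifelse(flip, 1L - frag, frag)
    if (len > 2L) {
      interior <- 2L:(len - 1L)
      del <- stats::runif(length(interior)) < g
      frag[interior[del]] <- NA_integer_
    }
    a[i, start + seq_len(len) - 1L] <- frag
  }
  mat <- new_snp_matrix(a, row_ids = paste0("h", src, "_f", seq_len(m)))
  structure(
    list(
      truth = truth,
      matrix = mat,
      call_coverage = coverage(mat, n),
      params = list(n = n, m = m, l = l, e = e, g = g, seed = seed)
    ),
    class = "sih_sim"
  )
}

#' @export
print.sih_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<sih_sim: n = %d, m = %d, l = %g, e = %g, g = %g; call coverage %.2f>\n",
    p$n, p$m, p$l, p$e, p$g, x$call_coverage
  ))
  invisible(x)
}

#' Average call coverage
#'
#' Total number of called (non-gap) alleles across all fragments divided by
#' the haplotype length.
#'
#' @param m an `snp_matrix`.
#' @param n haplotype length; defaults to `ncol(m)`.
#' @return a double.
#' @export
coverage <- function(m, n = ncol(m)) {
  if (n == 0) stop("haplotype length is zero", call. = FALSE)
  sum(!is.na(unclass(m))) / n
}
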
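resolve_blocks <- function(blocks) {
  if (inherits(blocks, "snp_matrix")) return(snp_blocks(blocks))
  if (inherits(blocks, "hbop_blocks_fit")) return(blocks$blocks)
  if (is.data.frame(blocks) && all(c("block", "sites") %in% names(blocks))) {
    return(blocks)
  }
  stop("`blocks` must be an snp_matrix, an hbop_blocks_fit, or a block tibble",
    call. = FALSE)
}

## per-block agreement bits over phased sites; phase is relative, so only
## flips of agreement between consecutive phased sites count
block_agreements <- function(truth, rec, sites) {
  phased <- sites[rec$phased[sites]]
  list(sites = phased, agree = rec$h1[phased] == truth$h1[phased])
}

#' Count switch errors against a true haplotype pair
#'
#' A switch error is a flip, between two consecutive phased sites of a
#' block, of the agreement between the reconstructed and the true
#' haplotype orientation. Orientation is relative within a block, so a
#' globally complemented reconstruction has no switch errors and blocks are
#' never compared across their boundary.
#'
#' @param truth the true [haplotype_pair()].
#' @param rec the reconstructed [haplotype_pair()] with `phased` flags.
#' @param blocks the block decomposition: an `snp_matrix`, an
#'   `hbop_blocks_fit`, or the tibble from [snp_blocks()].
#' @return a tibble with one row per block: `block`, `n_phased`,
#'   `switch_errors`.
#' @export
count_switch_errors <- function(truth, rec, blocks) {
  bl <- resolve_blocks(blocks)
  if (length(truth$h1) != length(rec$h1)) {
    stop("truth and reconstruction differ in length", call. = FALSE)
  }
  per <- purrr::map(bl$sites, function(sites) {
    if (length(sites) < 2) {
      return(list(n_phased = 0L, sw = 0L))
    }
    ag <- block_agreements(truth, rec, sort(sites))
    a <- ag$agree
    sw <- if (length(a) >= 2) sum(a[-1] != a[-length(a)]) else 0L
    list(n_phased = length(a), sw = as.integer(sw))
  })
  tibble::tibble(
    block = bl$block,
    n_phased = purrr::map_int(per, "n_phased"),
    switch_errors = purrr::map_int(per, "sw")
  )
}

#' Phased haplotype length
#'
#' The number of SNP sites at which the reconstruction determines the
#' alleles: phased sites lying in blocks of two or more sites (singleton
#' blocks cannot be phased by any fragment-based method).
#'
#' @inheritParams count_switch_errors
#' @return an integer.
#' @export
phased_length <- function(rec, blocks) {
  bl <- resolve_blocks(blocks)
  sum(purrr::map_int(bl$sites, function(sites) {
    if (length(sites) < 2) 0L else sum(rec$phased[sites])
  }))
}

#' Quality-adjusted N50 of switch-error-free segments
#'
#' Measures completeness and accuracy jointly: (1) each block is broken at
#' its switch errors into the longest segments containing none; (2) each
#' segment's span runs from its first to its last phased SNP in reference
#' coordinates (inclusive, so a one-SNP segment has span 1); (3) the span
#' is adjusted by the fraction of phased SNPs among all SNPs whose
#' coordinate falls within the segment's extent; (4) segments are sorted by
#' decreasing adjusted span; (5) walking down the list and accumulating
#' phased-SNP counts, the adjusted span of the segment at which the count
#' first exceeds half of the total number of SNPs is the QAN50 (0 if the
#' count never gets there).
#'
#' @inheritParams count_switch_errors
#' @param coords optional monotone map from site index to reference
#'   coordinate (numeric vector of length `n`); defaults to the site index
#'   itself, appropriate for simulated data.
#' @return a double.
#' @export
qan50 <- function(truth, rec, blocks, coords = NULL) {
  bl <- resolve_blocks(blocks)
  n <- length(truth$h1)
  if (is.null(coords)) coords <- seq_len(n)
  if (length(coords) != n) stop("`coords` must have one entry per site",
    call. = FALSE)
  if (any(diff(coords) <= 0)) stop("`coords` must be strictly increasing",
    call. = FALSE)

  segs <- list()
  for (b in seq_len(nrow(bl))) {
    sites <- sort(bl$sites[[b]])
    if (length(sites) < 2) next
    ag <- block_agreements(truth, rec, sites)
    if (!length(ag$sites)) next
    run_id <- cumsum(c(1L, as.integer(ag$agree[-1] != ag$agree[-length(ag$agree)])))
    for (seg_sites in split(ag$sites, run_id)) {
      lo <- coords[seg_sites[1]]
      hi <- coords[seg_sites[length(seg_sites)]]
      total_in_extent <- sum(coords >= lo & coords <= hi)
      span <- hi - lo + 1
      segs[[length(segs) + 1L]] <- list(
        span = span,
        adjusted = span * length(seg_sites) / total_in_extent,
        n_phased = length(seg_sites)
      )
    }
  }
  if (!length(segs)) return(0)
  adj <- vapply(segs, `[[`, numeric(1), "adjusted")
  nph <- vapply(segs, `[[`, numeric(1), "n_phased")
  ord <- order(-adj)
  cum <- cumsum(nph[ord])
  hit <- which(cum > n / 2)
  if (!length(hit)) return(0)
  adj[ord][hit[1]]
}

#' Evaluate a phasing against the truth
#'
#' Bundles the accuracy metrics: total switch errors, phased haplotype
#' length, switch error rate (switch errors / phased length) and QAN50.
#'
#' @inheritParams qan50
#' @return a one-row tibble with columns `switch_errors`, `phased_length`,
#'   `switch_error_rate`, `qan50`, `n_blocks`.
#' @examples
#' sim <- simulate_fragments(n = 40, m = 60, l = 3, e = 0.02, g = 0.1, seed = 7)
#' fit <- phase_blocks(sim$matrix)
#' evaluate_phasing(sim$truth, fit$haplotype, fit)
#' @export
evaluate_phasing <- function(truth, rec, blocks, coords = NULL) {
  bl <- resolve_blocks(blocks)
  per <- count_switch_errors(truth, rec, bl)
  sw <- sum(per$switch_errors)
  pl <- phased_length(rec, bl)
  tibble::tibble(
    switch_errors = sw,
    phased_length = pl,
    switch_error_rate = if (pl > 0) sw / pl else NA_real_,
    qan50 = qan50(truth, rec, bl, coords),
    n_blocks = nrow(bl)
  )
}
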
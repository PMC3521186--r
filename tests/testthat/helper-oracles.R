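## Independent brute-force oracles and random-instance generators.
## Deliberately naive, loop-based re-implementations: they share nothing
## with the package's vectorized/incremental code paths beyond the data
## containers.

allele_at <- function(m, i, j) unclass(m)[i, j]

## per-fragment min-conflict count, explicit loops
oracle_errors_corrected <- function(h, m) {
  total <- 0L
  for (i in seq_len(nrow(m))) {
    c1 <- 0L; c2 <- 0L
    for (j in seq_len(ncol(m))) {
      a <- allele_at(m, i, j)
      if (is.na(a)) next
      if (a != h$h1[j]) c1 <- c1 + 1L
      if (a != h$h2[j]) c2 <- c2 + 1L
    }
    total <- total + min(c1, c2)
  }
  total
}

## cut value by explicit unordered-pair loop with term-by-term d(a, b)
oracle_cut_score <- function(p, m) {
  total <- 0L
  for (i1 in seq_len(nrow(m))) {
    for (i2 in seq_len(nrow(m))) {
      if (i2 <= i1 || p[i1] == p[i2]) next
      for (j in seq_len(ncol(m))) {
        a <- allele_at(m, i1, j); b <- allele_at(m, i2, j)
        if (is.na(a) || is.na(b)) next
        total <- total + if (a == b) -1L else 1L
      }
    }
  }
  total
}

## columnwise own-group errors-corrected measure, explicit count loop
oracle_partition_ec <- function(p, m) {
  total <- 0L
  for (j in seq_len(ncol(m))) {
    n <- matrix(0L, 2, 2)  # n[g, v+1]
    for (i in seq_len(nrow(m))) {
      a <- allele_at(m, i, j)
      if (is.na(a)) next
      g <- p[i] + 1L
      n[g, a + 1L] <- n[g, a + 1L] + 1L
    }
    total <- total + min(n[1, 2] + n[2, 1], n[1, 1] + n[2, 2])
  }
  total
}

oracle_partition_sp <- function(p, m, w) {
  oracle_partition_ec(p, m) - w * oracle_cut_score(p, m)
}

## error-injected random instance in the study's style: fragments sampled
## from a random haplotype pair with flip rate `err` and gap rate `gap`
random_instance <- function(seed, n = 10, m = 6, l = 3, err = 0.1,
                            gap = 0.2) {
  simulate_fragments(n = n, m = m, l = l, e = err, g = gap, seed = seed)
}

## unconstrained random matrix (rows may cover < 2 loci); for scoring ops
random_raw_matrix <- function(seed, m = 6, n = 8, gap = 0.3) {
  withr::local_seed(seed)
  a <- matrix(sample(c(0L, 1L, NA_integer_), m * n, replace = TRUE,
    prob = c((1 - gap) / 2, (1 - gap) / 2, gap)), nrow = m)
  snp_matrix(a)
}

random_haplotype <- function(seed, n) {
  withr::local_seed(seed)
  haplotype_pair(sample(0:1, n, replace = TRUE))
}
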
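test_that("delta functions match their hand-computable cases", {
  # adding a row identical to the only overlapping row, same group: no new
  # conflict, and the cut is untouched
  m <- snp_matrix(c("011", "011"))
  p <- c(0L, 0L)
  expect_equal(delta_ec(m, 1, p), 0L)
  expect_equal(delta_fc(m, 1, p), 0L)

  # a disagreeing same-group row grows the minority by one at that column
  m2 <- snp_matrix(c("0-1", "1-1"))
  expect_equal(delta_ec(m2, 1, c(0L, 0L)), 1L)

  # one equal cross-group overlap lowers the cut measure by one per column
  m3 <- snp_matrix(c("01", "01"))
  expect_equal(delta_fc(m3, 1, c(0L, 1L)), -2L)
  # no cross-group overlap: zero
  expect_equal(delta_fc(m3, 1, c(0L, 0L)), 0L)

  expect_error(delta_ec(snp_matrix(c("-11", "11-")), 1, c(0L, 0L)),
    "not sorted")
})

test_that("delta updates equal full score recomputation on random instances", {
  for (seed in 1:15) {
    ms <- sort_fragments(random_instance(seed, n = 10, m = 7)$matrix)
    p <- withr::with_seed(seed + 100, sample(0:1, nrow(ms), replace = TRUE))
    for (i in seq_len(nrow(ms) - 1)) {
      sub_before <- snp_matrix(unclass(ms)[seq_len(i), , drop = FALSE])
      sub_after <- snp_matrix(unclass(ms)[seq_len(i + 1), , drop = FALSE])
      dec <- delta_ec(ms, i, p)
      dfc <- delta_fc(ms, i, p)
      sb_before <- partition_score(p[seq_len(i)], sub_before, 0.1)
      sb_after <- partition_score(p[seq_len(i + 1)], sub_after, 0.1)
      expect_equal(dec,
        sb_after$errors_corrected - sb_before$errors_corrected)
      expect_equal(dfc, sb_after$fragments_cut - sb_before$fragments_cut)
      expect_equal(sb_after$partition_score - sb_before$partition_score,
        dec - 0.1 * dfc)
    }
  }
})

test_that("every row covering a column at or past l(i+1) is in the carried-over set", {
  # localization soundness: the delta functions see all relevant rows
  for (seed in 1:10) {
    ms <- sort_fragments(random_instance(seed, n = 15, m = 12)$matrix)
    sp <- row_spans(ms)
    for (i in seq_len(nrow(ms) - 1)) {
      rc <- intersect(active_set(ms, i), active_set(ms, i + 1))
      for (i2 in seq_len(i)) {
        covered <- which(!is.na(unclass(ms)[i2, ]))
        if (any(covered >= sp$l[i + 1])) expect_true(i2 %in% rc)
      }
    }
  }
})

test_that("a wide-enough beam reproduces the exact optimum", {
  for (seed in 1:10) {
    m <- random_instance(seed, n = 8, m = 6)$matrix
    fit <- hbop_phase(m, w = 0.1, k = 2^(nrow(m) - 1))
    ex <- exact_bop(m, w = 0.1)
    expect_equal(fit$score$partition_score, ex$score$partition_score)
  }
})

test_that("beam entries carry scores equal to from-scratch recomputation", {
  for (seed in 1:5) {
    m <- random_instance(seed, n = 10, m = 8)$matrix
    fit <- hbop_phase(m, w = 0.1, k = 4, audit = TRUE)
    ms <- sort_fragments(m)
    for (snap in fit$audit) {
      sub <- snp_matrix(unclass(ms)[seq_len(snap$i), , drop = FALSE])
      for (entry in snap$entries) {
        sb <- partition_score(canonical_partition(entry$ext), sub, 0.1)
        expect_equal(entry$sc, sb$errors_corrected)
        expect_equal(entry$sd, sb$fragments_cut)
      }
    }
  }
})

test_that("noise-free data is phased without error correction", {
  sim <- simulate_fragments(n = 30, m = 50, l = 4, e = 0, g = 0.1, seed = 3)
  fit <- hbop_phase(sim$matrix, w = 0.1, k = 8)
  expect_equal(fit$score$errors_corrected, 0L)
  expect_equal(errors_corrected(fit$haplotype, sim$matrix), 0L)
})

test_that("the solver is deterministic and validates its configuration", {
  m <- random_instance(9, n = 10, m = 8)$matrix
  f1 <- hbop_phase(m, w = 0.1, k = 8)
  f2 <- hbop_phase(m, w = 0.1, k = 8)
  expect_identical(f1$partition, f2$partition)
  expect_identical(f1$score, f2$score)

  expect_error(hbop_phase(m, k = 0), "positive")
  expect_error(hbop_phase(m, w = -0.5), "non-negative")
  expect_error(hbop_phase(snp_matrix(c("0--", "011")), k = 1),
    "preprocess")

  empty <- hbop_phase(snp_matrix(character(0)), k = 1)
  expect_equal(length(empty$partition), 0L)
  expect_equal(empty$score$partition_score, 0)
})

test_that("k = 1 is a greedy pass and wider beams never score worse", {
  for (seed in 1:20) {
    m <- random_instance(seed, n = 12, m = 8)$matrix
    sp1 <- hbop_phase(m, w = 0.1, k = 1)$score$partition_score
    sp8 <- hbop_phase(m, w = 0.1, k = 8)$score$partition_score
    sp16 <- hbop_phase(m, w = 0.1, k = 16)$score$partition_score
    expect_lte(sp8, sp1)
    expect_lte(sp16, sp8)
  }
})

test_that("disconnected blocks phase independently and scores add up", {
  # two components glued side by side
  left <- simulate_fragments(n = 6, m = 6, l = 3, e = 0.1, g = 0, seed = 21)
  right <- simulate_fragments(n = 6, m = 6, l = 3, e = 0.1, g = 0, seed = 22)
  a <- matrix(NA_integer_, 12, 12)
  a[1:6, 1:6] <- unclass(left$matrix)[, ]
  a[7:12, 7:12] <- unclass(right$matrix)[, ]
  m <- snp_matrix(a)

  whole <- hbop_phase(m, w = 0.1, k = 64)
  per <- phase_blocks(m, w = 0.1, k = 64)
  expect_gte(nrow(per$blocks), 2L)
  expect_equal(per$score$partition_score, whole$score$partition_score)
  expect_equal(sum(per$blocks$sp), whole$score$partition_score)
})

test_that("per-block phasing flags singletons and mirrors the block table", {
  m <- snp_matrix(c("11--0", "-11-0"))  # site 4 never covered
  fit <- phase_blocks(m, w = 0.1, k = 8)
  bl <- snp_blocks(m)
  expect_equal(fit$blocks$block, bl$block)
  expect_equal(fit$blocks$sites, bl$sites)
  expect_false(fit$haplotype$phased[4])

  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  gl <- glance(fit)
  expect_equal(gl$n_blocks, nrow(bl))
})

test_that("beam work grows with the beam width", {
  m <- simulate_fragments(n = 40, m = 120, l = 5, e = 0.02, g = 0.1,
    seed = 17)$matrix
  ops <- vapply(c(1, 2, 4, 8), function(k) {
    hbop_phase(m, w = 0.1, k = k)$ops
  }, numeric(1))
  expect_true(all(diff(ops) > 0))
})
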
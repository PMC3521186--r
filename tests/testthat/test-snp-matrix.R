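test_that("dense fragment files parse into matrices with correct spans", {
  path <- withr::local_tempfile(lines = c("01-", "-10"))
  m <- read_fragments(path, dialect = "dense")
  expect_equal(dim(m), c(2L, 3L))
  sp <- row_spans(m)
  expect_equal(sp$l, c(1L, 2L))
  expect_equal(sp$r, c(2L, 3L))

  # interior gaps stay inside the span
  m2 <- snp_matrix("1-1")
  sp2 <- row_spans(m2)
  expect_equal(c(sp2$l, sp2$r), c(1L, 3L))
})

test_that("hapcut dialect places 1-based pieces and retains qualities", {
  path <- withr::local_tempfile(lines = "1 f1 2 01")
  m <- read_fragments(path, dialect = "hapcut", n = 3)
  expect_equal(fragment_strings(m), "-01")
  expect_equal(row_ids(m), "f1")

  # multi-piece fragment with quality string
  path2 <- withr::local_tempfile(lines = "2 frag7 1 01 4 1 ABC")
  m2 <- read_fragments(path2, dialect = "hapcut")
  expect_equal(fragment_strings(m2), "01-1")
  expect_equal(attr(m2, "quals"), "ABC")
})

test_that("malformed fragment lines fail with the offending line number", {
  bad_allele <- withr::local_tempfile(lines = c("1 a 1 01", "1 b 1 0x"))
  expect_error(read_fragments(bad_allele, dialect = "hapcut"), "line 2")
  overlap <- withr::local_tempfile(lines = "2 a 1 011 3 10")
  expect_error(read_fragments(overlap, dialect = "hapcut"), "overlap")
  short <- withr::local_tempfile(lines = "1 a 1")
  expect_error(read_fragments(short, dialect = "hapcut"), "line 1")
  expect_error(snp_matrix(c("012")), "invalid allele")
})

test_that("write/read round-trips bit-exactly in both dialects", {
  # degenerate: empty matrix
  p0 <- withr::local_tempfile()
  write_fragments(snp_matrix(character(0)), p0, dialect = "dense")
  expect_equal(nrow(read_fragments(p0, dialect = "dense")), 0L)

  # property: 1000-fragment simulated matrix survives both dialects
  sim <- simulate_fragments(n = 60, m = 1000, l = 4, e = 0.05, g = 0.2,
    seed = 11)
  m <- sim$matrix
  pd <- withr::local_tempfile()
  write_fragments(m, pd, dialect = "dense")
  md <- read_fragments(pd, dialect = "dense")
  expect_identical(unclass(md)[, ], unclass(m)[, ])

  ph <- withr::local_tempfile()
  write_fragments(m, ph, dialect = "hapcut")
  mh <- read_fragments(ph, dialect = "hapcut", n = ncol(m))
  expect_identical(unclass(mh)[, ], unclass(m)[, ])
  expect_identical(row_ids(mh), row_ids(m))
})

test_that("preprocessing removes uninformative rows and empty columns", {
  m <- snp_matrix(c("0--", "011"))
  pp <- preprocess_fragments(m)
  expect_equal(nrow(pp), 1L)
  expect_equal(fragment_strings(pp), "011")

  # matrix already clean: identity
  m2 <- snp_matrix(c("011", "110"))
  expect_identical(unclass(preprocess_fragments(m2))[, ], unclass(m2)[, ])

  # a column losing all coverage is dropped and the index map records it
  m3 <- snp_matrix(c("-1-", "0-1"))  # row 1 covers only locus 2
  pp3 <- preprocess_fragments(m3)
  expect_equal(fragment_strings(pp3), "01")
  expect_equal(attr(pp3, "col_index"), c(1L, 3L))
})

test_that("fragments sort stably by (l, r)", {
  m <- snp_matrix(c("-1111", "11---", "11000"), row_ids = c("a", "b", "c"))
  s <- sort_fragments(m)  # spans (2,5), (1,2), (1,5)
  expect_equal(row_ids(s), c("b", "c", "a"))

  # ties on (l, r) keep input order
  m2 <- snp_matrix(c("110", "010", "100"), row_ids = c("x", "y", "z"))
  expect_equal(row_ids(sort_fragments(m2)), c("x", "y", "z"))

  # property: sortedness invariant on random fixtures
  for (seed in 1:5) {
    s <- sort_fragments(random_instance(seed, n = 20, m = 15)$matrix)
    sp <- row_spans(s)
    expect_true(all(diff(sp$l) > 0 |
      (diff(sp$l) == 0 & diff(sp$r) >= 0)))
  }
})

test_that("active sets follow the span definition", {
  # sorted spans (1,3), (2,4), (4,5): row 1 ends before l(3) = 4
  m <- snp_matrix(c("111--", "-111-", "---11"))
  expect_equal(active_set(m, 1), 1L)
  expect_equal(active_set(m, 2), c(1L, 2L))
  expect_equal(active_set(m, 3), c(2L, 3L))
  expect_error(active_set(m, 4), "row index")
  expect_error(active_set(snp_matrix(c("-11", "11-")), 1), "not sorted")
})

test_that("active sets are interval-consistent on sorted random fixtures", {
  for (seed in 1:5) {
    m <- sort_fragments(random_instance(seed, n = 15, m = 12)$matrix)
    for (i in seq_len(nrow(m) - 1)) {
      r_i <- active_set(m, i)
      r_next <- active_set(m, i + 1)
      expect_true(all(setdiff(r_next, i + 1) %in% r_i))
    }
  }
})

test_that("blocks are the connected components of the site graph", {
  # chained coverage joins all three sites
  b1 <- snp_blocks(snp_matrix(c("11-", "-11")))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$sites[[1]], 1:3)

  # disconnected coverage yields two blocks
  b2 <- snp_blocks(snp_matrix(c("11--", "--11")))
  expect_equal(b2$sites, list(1:2, 3:4))

  # a never-covered column is a singleton, unphaseable block
  b3 <- snp_blocks(snp_matrix(c("1-1")))
  expect_equal(b3$sites, list(c(1L, 3L), 2L))
  expect_equal(b3$phaseable, c(TRUE, FALSE))
})

test_that("block decomposition partitions columns and no edge crosses blocks", {
  for (seed in 1:5) {
    m <- random_instance(seed, n = 25, m = 12, l = 3)$matrix
    bl <- snp_blocks(m)
    sites <- sort(unlist(bl$sites))
    expect_equal(sites, seq_len(ncol(m)))
    # re-scan rows: every fragment's called sites stay inside one block
    block_of <- integer(ncol(m))
    for (b in seq_len(nrow(bl))) block_of[bl$sites[[b]]] <- b
    for (i in seq_len(nrow(m))) {
      called <- which(!is.na(unclass(m)[i, ]))
      expect_length(unique(block_of[called]), min(1L, length(called)))
    }
  }
})
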
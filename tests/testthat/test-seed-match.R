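test_that("the k-mer index maps every N-free window to its positions", {
  idx <- build_match_index("AAAA", b = 4)
  expect_identical(idx$env[["AAAA"]], 0L)

  idx <- build_match_index("ACGUACGU", b = 4)
  expect_identical(idx$env[["ACGU"]], c(0L, 4L))
  keys <- setdiff(ls(idx$env, all.names = TRUE), ".target_chars")
  expect_length(keys, 4)                     # 5 windows, 4 distinct k-mers
  expect_identical(sort(keys), c("ACGU", "CGUA", "GUAC", "UACG"))

  # windows containing N are never keyed
  idx <- build_match_index("ACGNUACG", b = 4)
  keys <- setdiff(ls(idx$env, all.names = TRUE), ".target_chars")
  expect_false(any(grepl("N", keys)))
  expect_identical(keys, "UACG")

  expect_error(build_match_index("ACGUA", b = 3), "b must be")
  expect_error(build_match_index("ACG", b = 4), "shorter than")
})

test_that("a perfectly complementary non-periodic miRNA yields one full-length match", {
  mirna <- "UUACCGAGUUGACGAAUCCGAU"           # 22 nt, no internal periodicity
  target <- reverse_complement(mirna)
  hits <- find_seed_matches(mirna, target, b = 7)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$length, 22L)
  expect_identical(hits$target_start, 0L)
  expect_identical(hits$target_end, 22L)
  expect_identical(hits$mirna_start, 0L)
  expect_identical(hits$mirna_end, 22L)
  # and the naive oracle agrees there is exactly one
  expect_identical(as.matrix(hits), as.matrix(naive_seed_scan(mirna, target, 7)))
})

test_that("identical bases never seed (A does not pair A)", {
  hits <- find_seed_matches(strrep("A", 22), strrep("A", 100), b = 7)
  expect_identical(nrow(hits), 0L)
})

test_that("G over U does not extend a Watson-Crick seed run", {
  # miRNA AAAAAA G AAAAA over poly-U: the G could only wobble-pair, so the
  # maximal WC runs are 6 and 5 -- visible at b=4, absent at b=7
  mirna <- "AAAAAAGAAAAA"
  target <- strrep("U", 30)
  hits4 <- find_seed_matches(mirna, target, b = 4)
  expect_gt(nrow(hits4), 0L)
  expect_true(all(hits4$length <= 6L))
  # no run crosses the G at miRNA position 6
  expect_true(all(hits4$mirna_end <= 6L | hits4$mirna_start >= 7L))
  expect_identical(nrow(find_seed_matches(mirna, target, b = 7)), 0L)
})

test_that("the exact scan equals the naive diagonal oracle on random instances", {
  set.seed(101)
  for (i in 1:40) {
    mirna <- rand_rna(sample(15:25, 1))
    target <- rand_rna(sample(40:120, 1), gc = runif(1, 0.3, 0.7))
    for (b in c(4L, 7L)) {
      got <- find_seed_matches(mirna, target, b = b)
      want <- naive_seed_scan(mirna, target, b)
      expect_identical(as.matrix(got), as.matrix(want),
                       info = sprintf("instance %d b=%d", i, b))
    }
  }
})

test_that("matches at b+1 are a subset of matches at b (maximal runs)", {
  set.seed(202)
  for (i in 1:20) {
    mirna <- rand_rna(22)
    target <- rand_rna(150)
    at_b <- find_seed_matches(mirna, target, b = 4)
    at_b1 <- find_seed_matches(mirna, target, b = 5)
    key <- function(df) paste(df$target_start, df$mirna_start, df$length)
    expect_true(all(key(at_b1) %in% key(at_b)))
    expect_identical(key(at_b1), key(at_b[at_b$length >= 5, , drop = FALSE]))
  }
})

test_that("no two reported matches share a diagonal and extent, and a shared index reproduces per-call scans", {
  set.seed(303)
  target <- rand_rna(400)
  idx <- build_match_index(target, b = 4)
  for (i in 1:10) {
    mirna <- rand_rna(20)
    got <- find_seed_matches(mirna, b = 4, index = idx)
    expect_identical(as.matrix(got),
                     as.matrix(find_seed_matches(mirna, target, b = 4)))
    # antiparallel runs live on anti-diagonals: target_start + mirna_end const
    diag_key <- paste(got$target_start + got$mirna_end, got$target_start)
    expect_identical(anyDuplicated(diag_key), 0L)
  }
  expect_error(find_seed_matches("ACGUACGU", b = 7, index = idx),
               "built with b")
})
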
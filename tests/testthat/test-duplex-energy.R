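model <- load_energy_model()

test_that("score_duplex decomposes structures exactly as specified", {
  # empty duplex is +Inf by convention
  expect_identical(score_duplex(matrix(integer(), 0, 2), "ACGU", "ACGU", model),
                   Inf)
  # single pair: initiation plus a terminal penalty at each end, no stacks
  one_au <- score_duplex(cbind(0L, 0L), "A", "U", model)
  expect_equal(one_au, model$duplex_init + 2 * model$terminal_au)
  one_gc <- score_duplex(cbind(0L, 0L), "G", "C", model)
  expect_equal(one_gc, model$duplex_init)
  # an 8-bp contiguous CG helix: init + 7 stack terms, no AU ends
  mirna <- strrep("C", 8)
  site <- strrep("G", 8)
  pairs <- cbind(0:7, 7:0)
  hand_sum <- model$duplex_init + 7 * model$stack["CG", "GC"]
  expect_equal(score_duplex(pairs, mirna, site, model), hand_sum)
  # geometric violations are errors
  expect_error(score_duplex(rbind(c(0, 0), c(1, 1)), "CC", "GG", model),
               "antiparallel")
  expect_error(score_duplex(cbind(0L, 0L), "A", "G", model), "disallowed")
})

test_that("hybridize finds the MFE duplex and re-scores consistently", {
  # no admissible pair at all
  d <- hybridize("AAAAAA", "AAAAAA")
  expect_identical(d$mfe, Inf)
  expect_identical(nrow(d$pairs), 0L)

  # perfect complement: every position paired, mfe equals the helix hand-sum
  mirna <- "CCGGCCGGCC"
  site <- reverse_complement(mirna)
  d <- hybridize(mirna, site, model = model)
  expect_identical(nrow(d$pairs), 10L)
  expect_equal(d$mfe, score_duplex(d$pairs, mirna, site, model),
               tolerance = 1e-9)

  # random instances: traceback re-scores to the reported mfe
  set.seed(42)
  for (i in 1:30) {
    m <- rand_rna(sample(8:20, 1))
    w <- rand_rna(sample(10:40, 1))
    d <- hybridize(m, w, model = model)
    if (is.finite(d$mfe)) {
      expect_equal(score_duplex(d$pairs, m, w, model), d$mfe,
                   tolerance = 1e-6)
      # footprint bookkeeping
      expect_identical(d$site_start, min(d$pairs[, 2]))
      expect_identical(d$site_end, max(d$pairs[, 2]) + 1L)
      # alignment strings render every paired and looped column
      expect_identical(nchar(d$mirna_aln), nchar(d$pair_aln))
      expect_identical(nchar(d$target_aln), nchar(d$pair_aln))
    }
  }
})

test_that("DP equals brute-force enumeration on small instances", {
  # exhaustive hand-picked set covering stacks, bulges, wobble, no-pair
  cases <- list(
    c("ACG", "CGU"), c("GGG", "CCC"), c("AAA", "GGG"),
    c("GCGC", "GCGC"), c("AUGC", "GCAU"), c("GGAAU", "AUUCC"),
    c("GGXAU", "AUCC"), c("UUUU", "GGGG"))
  for (cs in cases) {
    m <- gsub("X", "N", cs[1]); w <- cs[2]
    expect_equal(hybridize(m, w, model = model)$mfe,
                 brute_duplex_mfe(m, w, model),
                 tolerance = 1e-6, info = paste(cs, collapse = " vs "))
  }
  set.seed(7)
  for (i in 1:25) {
    m <- rand_rna(sample(4:9, 1))
    w <- rand_rna(sample(4:9, 1))
    expect_equal(hybridize(m, w, model = model)$mfe,
                 brute_duplex_mfe(m, w, model),
                 tolerance = 1e-6, info = paste(m, w))
  }
})

test_that("extending a terminal helix changes mfe by exactly one stack term", {
  # all-GC helices so no terminal-AU bookkeeping changes
  for (n in 4:9) {
    m1 <- strrep("C", n); m2 <- strrep("C", n + 1)
    e1 <- hybridize(m1, reverse_complement(m1), model = model)$mfe
    e2 <- hybridize(m2, reverse_complement(m2), model = model)$mfe
    expect_equal(e2 - e1, model$stack["CG", "GC"], tolerance = 1e-9)
  }
  # appending an AU pair to a GC helix: stack term plus the new AU end
  m <- paste0(strrep("C", 6), "A")
  e_gc <- hybridize(strrep("C", 6), strrep("G", 6), model = model)$mfe
  e_au <- hybridize(m, reverse_complement(m), model = model)$mfe
  expect_equal(e_au - e_gc, model$stack["CG", "UA"] + model$terminal_au,
               tolerance = 1e-9)
})

test_that("the duplex model is symmetric in which strand is called miRNA", {
  set.seed(99)
  for (i in 1:20) {
    a <- rand_rna(sample(5:12, 1))
    b <- rand_rna(sample(5:12, 1))
    expect_equal(hybridize(a, b, model = model)$mfe,
                 hybridize(b, a, model = model)$mfe, tolerance = 1e-9)
  }
})

test_that("the energy cutoff is inclusive and Inf never passes", {
  expect_true(passes_energy_cutoff(-25.0, e = -25))
  expect_false(passes_energy_cutoff(-24.9, e = -25))
  expect_false(passes_energy_cutoff(Inf, e = -25))
  expect_false(passes_energy_cutoff(Inf, e = 0))
  # relaxing e never shrinks the passing set
  mfes <- c(-40, -25, -24.9, -10, Inf)
  strict <- passes_energy_cutoff(mfes, e = -25)
  relaxed <- passes_energy_cutoff(mfes, e = -20)
  expect_true(all(relaxed[strict]))
})

test_that("window preconditions guard the quadratic engine", {
  t <- rand_rna(300)
  expect_error(hybridize("ACGUACGU", t, c(0, 250)), "200")
  expect_error(hybridize("ACGUACGU", t, c(-1, 50)), "interval")
  expect_error(hybridize("ACGUACGU", t, c(50, 50)), "interval")
})
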
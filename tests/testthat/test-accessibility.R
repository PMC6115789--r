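model <- load_energy_model()

test_that("unpairable windows fold to zero with an empty pair map", {
  f <- fold_local(strrep("A", 60), c(10, 30), flank = 10)
  expect_identical(f$fold_mfe, 0)
  expect_identical(nrow(f$pair_map), 0L)
  rep <- site_accessibility_report(f)
  expect_identical(rep$unpaired_fraction, 1)
})

test_that("a GC hairpin folds to its hand-summed stem energy", {
  # 10-bp GC stem closing a 4-nt loop
  s <- paste0(strrep("G", 10), "AAAA", strrep("C", 10))
  f <- fold_local(s, c(0, 24), flank = 0)
  hand_sum <- 9 * model$stack["GC", "CG"] + model$hairpin[4]
  expect_equal(f$fold_mfe, hand_sum, tolerance = 1e-9)
  expect_identical(nrow(f$pair_map), 10L)
  expect_equal(score_structure(f$pair_map, s, model), f$fold_mfe,
               tolerance = 1e-9)
  # the whole site is the stem + loop: 20 of 24 positions paired
  rep <- site_accessibility_report(f)
  expect_equal(rep$unpaired_fraction, 4 / 24)
  # a fully paired sub-interval reports zero accessibility
  expect_equal(site_accessibility_report(f, c(0, 10))$unpaired_fraction, 0)
  # a half-paired interval counts positions: 8,9,14,15 paired, 10-13 loop
  expect_equal(site_accessibility_report(f, c(8, 16))$unpaired_fraction, 0.5)
})

test_that("fold DP equals brute-force enumeration on small windows", {
  set.seed(13)
  for (i in 1:25) {
    s <- rand_rna(sample(10:18, 1), gc = runif(1, 0.3, 0.7))
    f <- fold_local(s, c(0, nchar(s)), flank = 0)
    expect_equal(f$fold_mfe, brute_fold_mfe(s, model), tolerance = 1e-6,
                 info = s)
    expect_equal(score_structure(f$pair_map, s, model), f$fold_mfe,
                 tolerance = 1e-6, info = s)
  }
})

test_that("folding energy never exceeds zero and is monotone in window size", {
  set.seed(23)
  for (i in 1:15) {
    s <- rand_rna(120)
    prev <- 0
    for (flank in c(0L, 10L, 25L, 45L)) {
      f <- fold_local(s, c(50, 70), flank = flank)
      expect_lte(f$fold_mfe, 0)
      expect_lte(f$fold_mfe, prev + 1e-9)   # larger window admits the smaller's MFE
      prev <- f$fold_mfe
      # traceback (which hits multibranch cases at these window sizes)
      # re-scores to the DP optimum
      win <- substr(s, f$window_start + 1, f$window_end)
      expect_equal(score_structure(f$pair_map - f$window_start, win, model),
                   f$fold_mfe, tolerance = 1e-6)
    }
  }
})

test_that("multibranch loops are scored by the linear model", {
  # closing 5-bp GC stem enclosing two 5-bp GC hairpins: an explicit
  # three-branch multiloop whose energy is summed by hand from the model
  s <- paste0("GGGGG", "AA",
              "GGGGG", "AAAA", "CCCCC", "AA",
              "GGGGG", "AAAA", "CCCCC", "AA",
              "CCCCC")
  outer <- cbind(0:4, 43:39)
  h1 <- cbind(7:11, 20:16)
  h2 <- cbind(23:27, 36:32)
  pairs <- rbind(outer, h1, h2)
  hairpin_arm <- 4 * model$stack["GC", "CG"] + model$hairpin[4]
  hand <- 4 * model$stack["GC", "CG"] +                     # closing stem
    2 * hairpin_arm +
    model$ml_close + 3 * model$ml_branch +                  # closing + 2 arms
    6 * model$ml_unpaired                                   # AA spacers
  expect_equal(score_structure(pairs, s, model), unname(hand),
               tolerance = 1e-9)
  # the DP admits multibranch structures: its optimum is at least this good
  # and its traceback re-scores exactly
  f <- fold_local(s, c(0, nchar(s)), flank = 0)
  expect_lte(f$fold_mfe, score_structure(pairs, s, model) + 1e-9)
  expect_equal(score_structure(f$pair_map, s, model), f$fold_mfe,
               tolerance = 1e-6)
})

test_that("fold window preconditions are enforced", {
  s <- rand_rna(800)
  expect_error(fold_local(s, c(100, 500), flank = 0), "300")
  expect_error(fold_local(s, c(100, 120), flank = 200), "300")
  expect_error(fold_local(s, c(-5, 20), flank = 0), "interval")
  expect_error(fold_local(s, c(10, 20), flank = -1), "flank")
})
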
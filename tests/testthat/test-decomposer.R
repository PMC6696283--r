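# Formula decomposition within ppm tolerance under element bounds.

small_bounds <- element_bounds(C = c(0, 12), H = c(0, 24), N = c(0, 2),
                               O = c(0, 6), Na = c(0, 1))

test_that("known sodiated species are recovered at 3 ppm", {
  c1 <- decompose_mz(693.4184, adducts = "+Na")
  expect_true("C36H62O11" %in% c1$formula)
  expect_lte(abs(c1$ppm[c1$formula == "C36H62O11"]), 0.1)
  c2 <- decompose_mz(619.3817, adducts = "+Na")
  expect_true("C33H56O9" %in% c2$formula)
})

test_that("a sparse mass region decomposes uniquely", {
  # protonated water: the only composition in the default lattice
  res <- decompose_mz(19.0178, adducts = "+H")
  expect_identical(res$formula, "H2O")
})

test_that("decomposition equals the naive lattice oracle below 200 Da", {
  set.seed(7)
  masses <- stats::runif(50, 50, 200)
  for (mz in masses) {
    for (a in c("+H", "+Na")) {
      got <- decompose_mz(mz, adducts = a, tol_ppm = 3,
                          bounds = small_bounds, rdbe_filter = FALSE)
      want <- oracle_decompose(mz, a, 3, small_bounds)
      expect_setequal(got$formula, want)
    }
  }
})

test_that("widening tolerance or bounds never removes a candidate", {
  for (mz in c(693.4184, 150.0528, 301.1410)) {
    narrow <- decompose_mz(mz, tol_ppm = 1)
    wide <- decompose_mz(mz, tol_ppm = 3)
    expect_true(all(paste(narrow$formula, narrow$adduct) %in%
                      paste(wide$formula, wide$adduct)))
    small <- decompose_mz(mz, tol_ppm = 3, bounds = small_bounds)
    expect_true(all(paste(small$formula, small$adduct) %in%
                      paste(wide$formula, wide$adduct)))
  }
})

test_that("every candidate round-trips to within tolerance", {
  res <- decompose_mz(693.4205, tol_ppm = 3)
  expect_gt(nrow(res), 0)
  for (i in seq_len(nrow(res))) {
    expect_equal(adduct_mz(res$formula[i], res$adduct[i]), res$mz_calc[i],
                 tolerance = 1e-12)
    expect_lte(abs(ppm_error(693.4205, res$mz_calc[i])), 3)
  }
  expect_false(is.unsorted(abs(res$ppm)))
})

test_that("absurd bounds trip the resource guard; empty results are fine", {
  expect_error(decompose_mz(500, bounds = list(C = c(0, 5000), H = c(0, 10),
                                               N = c(0, 2), O = c(0, 5000),
                                               Na = c(0, 1))),
               "lattice")
  none <- decompose_mz(18.5, adducts = "+H", tol_ppm = 1)
  expect_identical(nrow(none), 0L)
})

test_that("isotope-fit ranking puts the true formula first", {
  cands <- decompose_mz(693.4205, adducts = c("+Na", "+NH4"), tol_ppm = 3)
  expect_gt(nrow(cands), 1)
  observed <- theoretical_pattern("C36H62O11", "+Na")
  ranked <- rank_candidates(cands, observed)
  expect_identical(ranked$formula[1], "C36H62O11")
  expect_identical(ranked$adduct[1], "+Na")
  expect_equal(ranked$sigma[1], 0, tolerance = 1e-9)
  expect_false(is.unsorted(ranked$rank))
  # single candidate stays rank 1; missing pattern falls back with warning
  expect_warning(one <- rank_candidates(decompose_mz(19.0178, adducts = "+H")),
                 "ppm")
  expect_identical(one$rank, 1L)
})

test_that("subformula search is restricted to precursor subsets", {
  pre <- "C36H62O11"
  pre_mz <- adduct_mz(pre, "+Na")
  self <- subformula_candidates(pre_mz, pre)
  expect_true(pre %in% self$formula)
  loss <- subformula_candidates(pre_mz - 18.010565, pre)
  expect_true("C36H60O10" %in% loss$formula)
  f <- as_formula(pre)
  for (i in seq_len(nrow(loss))) {
    sub <- as_formula(loss$formula[i])
    expect_true(all(sub <= f[names(sub)]))
  }
  expect_identical(nrow(subformula_candidates(0.5, pre)), 0L)
})
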
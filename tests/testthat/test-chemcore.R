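# Formula arithmetic, monoisotopic masses and adduct m/z computation.

test_that("formula parsing handles both text dialects and rejects junk", {
  expect_identical(parse_formula("C36H62O11"),
                   c(C = 36L, H = 62L, O = 11L))
  expect_identical(parse_formula("C_36_H_62_O_11_Na"),
                   c(C = 36L, H = 62L, Na = 1L, O = 11L))
  expect_identical(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_length(parse_formula(""), 0L)
  expect_identical(format_formula(c(O = 1L, H = 2L)), "H2O")
  expect_identical(parse_formula(format_formula(c(C = 3L, H = 1L, Na = 1L))),
                   c(C = 3L, H = 1L, Na = 1L))
  expect_error(parse_formula("C2Xe5"), "alphabet")
  expect_error(as_formula(c(C = -1)), "non-negative")
})

test_that("monoisotopic masses match hand sums and are additive", {
  expect_identical(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5 / 18)
  expect_equal(monoisotopic_mass("C36H62O11"), 670.42921,
               tolerance = 1e-4 / 670)
  # additivity over random formulas
  set.seed(42)
  for (i in 1:50) {
    f1 <- c(C = sample(0:40, 1), H = sample(0:80, 1), N = sample(0:2, 1),
            O = sample(0:15, 1), Na = sample(0:1, 1))
    f2 <- c(C = sample(0:40, 1), H = sample(0:80, 1), N = sample(0:2, 1),
            O = sample(0:15, 1), Na = sample(0:1, 1))
    expect_equal(monoisotopic_mass(f1 + f2),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9 / 1000)
  }
})

test_that("adduct m/z uses the electron-corrected cation convention", {
  expect_equal(adduct_mz("C36H62O11", "+Na"), 693.4184, tolerance = 5e-4 / 693)
  expect_equal(adduct_mz("C35H60O11", "+Na"), 679.4028, tolerance = 5e-4 / 679)
  expect_equal(adduct_mz("C36H62O11", "+NH4"), 688.4630, tolerance = 5e-4 / 688)
  # bracketed spellings and bare names are accepted
  expect_identical(adduct_mz("C36H62O11", "[M+Na]+"),
                   adduct_mz("C36H62O11", "Na"))
  expect_error(adduct_mz("C36H62O11", "+K"), "unsupported adduct")
  expect_error(adduct_mz("C36H62O11", "+Na", charge = 2), "singly charged")
})

test_that("adduct pair spacing is formula-independent", {
  expect_equal(adduct_pair_delta("+Na", "+NH4"), 4.9554, tolerance = 1e-3 / 5)
  expect_identical(adduct_pair_delta("+Na", "+Na"), 0)
  expect_equal(adduct_pair_delta("+NH4", "+H"), 17.0265, tolerance = 1e-3 / 17)
  set.seed(7)
  for (i in 1:20) {
    f <- c(C = sample(1:40, 1), H = sample(1:80, 1), O = sample(0:15, 1))
    expect_equal(adduct_mz(f, "+Na") - adduct_mz(f, "+NH4"),
                 adduct_pair_delta("+Na", "+NH4"), tolerance = 1e-12)
  }
})

test_that("ppm error is signed and guards its domain", {
  expect_identical(ppm_error(693.4184, 693.4184), 0)
  expect_equal(ppm_error(693.4205, 693.4184), 3.03, tolerance = 0.01 / 3)
  expect_equal(ppm_error(619.3817, 619.3836), -3.07, tolerance = 0.01 / 3)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("formula differences are element-wise and antisymmetric", {
  expect_identical(formula_diff("C36H62O11", "C35H60O9"),
                   c(C = -1L, H = -2L, O = -2L))
  expect_identical(formula_diff("C35H60O11", "C33H56O9"),
                   c(C = -2L, H = -4L, O = -2L))
  expect_length(formula_diff("C36H62O11", "C36H62O11"), 0L)
  set.seed(11)
  for (i in 1:20) {
    a <- c(C = sample(0:30, 1), H = sample(0:60, 1), O = sample(0:10, 1))
    b <- c(C = sample(0:30, 1), H = sample(0:60, 1), O = sample(0:10, 1))
    expect_identical(formula_diff(a, b), -formula_diff(b, a))
  }
})

test_that("sodiated formula strings split into neutral plus +Na", {
  s <- split_adduct_formula("C_36_H_62_O_11_Na")
  expect_identical(s$neutral, c(C = 36L, H = 62L, O = 11L))
  expect_identical(s$adduct, "+Na")
  expect_equal(adduct_mz(s$neutral, s$adduct), 693.4184,
               tolerance = 5e-4 / 693)
  s2 <- split_adduct_formula("C36H62O11")
  expect_identical(s2$adduct, NA_character_)
})

test_that("isotope table satisfies its invariants", {
  el <- element_table()
  expect_setequal(unique(el$symbol), c("C", "H", "N", "O", "Na"))
  for (s in unique(el$symbol)) {
    sub <- el[el$symbol == s, ]
    expect_equal(sum(sub$abundance), 1, tolerance = 1e-6)
    expect_true(all(diff(sub$mass) > 0))
  }
})

test_that("RDBE follows C - H/2 + N/2 + 1 on the neutral formula", {
  expect_identical(rdbe("H2O"), 0)
  expect_identical(rdbe("C36H62O11"), 6)
  expect_identical(rdbe("C5H5N"), 4)   # pyridine
  expect_identical(rdbe("C3H7"), 0.5)  # half-integer compositions allowed
})
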
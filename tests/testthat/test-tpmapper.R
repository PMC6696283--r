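# Transformation path enumeration, suspect lists and structural classes.

MON_A <- "C36H62O11"
MON_B <- "C35H60O11"

test_that("minimal paths reproduce the canonical transformations", {
  p4 <- enumerate_paths(MON_A, "C35H60O9")
  expect_identical(p4[[1]]$steps, c("DECARBOXYLATION", "DEHYDROGENATION"))
  p12 <- enumerate_paths(MON_A, "C36H60O10")
  expect_identical(p12[[1]]$steps, "DEHYDRATION")
  p5 <- enumerate_paths(MON_A, "C36H64O10")
  expect_identical(p5[[1]]$steps, c("DECARBOXYLATION", "DEHYDROGENATION",
                                    "METHANOL_ADDITION"))
})

test_that("identical formulas yield exactly the isomerization path", {
  pid <- enumerate_paths(MON_A, MON_A, max_steps = 3)
  expect_length(pid, 1L)
  expect_identical(pid[[1]]$label, "ISOMERIZATION")
})

test_that("unexplainable deltas give an empty path list", {
  # a lone nitrogen gain is outside the reaction alphabet
  expect_length(enumerate_paths("C10H20O5", "C10H20N1O5"), 0L)
  expect_error(enumerate_paths(MON_A, MON_B, max_steps = 9), "max_steps")
})

test_that("raising max_steps only adds paths, and all paths are sound", {
  pairs <- list(c(MON_A, "C34H58O9"), c(MON_B, "C33H56O9"),
                c(MON_A, "C35H62O10"))
  for (pr in pairs) {
    for (k in 1:3) {
      pk <- enumerate_paths(pr[1], pr[2], max_steps = k)
      if (k > 1) {
        prev <- enumerate_paths(pr[1], pr[2], max_steps = k - 1)
        expect_true(all(vapply(prev, `[[`, character(1), "label") %in%
                          vapply(pk, `[[`, character(1), "label")))
      }
      steps <- reaction_steps()
      for (p in pk) {
        prod <- as_formula(pr[1])
        for (s in p$steps) {
          d <- steps[[s]]
          if (length(d)) prod <- tpscreen:::apply_delta(prod, d)
        }
        expect_identical(format_formula(prod), format_formula(pr[2]))
      }
    }
  }
})

test_that("suspect lists contain the expected products and no negatives", {
  dehyd <- suspect_list(MON_A, steps = reaction_steps()["DEHYDRATION"],
                        max_steps = 1, adducts = "+Na")
  hit <- dehyd[dehyd$formula == "C36H60O10", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$mz_calc, 675.4079, tolerance = 5e-4 / 675)
  expect_identical(hit$path_label, "DEHYDRATION")

  zero <- suspect_list(c(MON_A, MON_B), max_steps = 0)
  expect_setequal(zero$formula, c(MON_A, MON_B))
  expect_true(all(zero$path_label == "ISOMERIZATION"))

  full <- suspect_list(c(MON_A, MON_B), max_steps = 3)
  printed <- unique(tp_rows$neutral_formula)
  expect_true(all(printed %in% full$formula))
  for (f in full$formula) expect_true(all(as_formula(f) >= 0))
})

test_that("suspects deduplicate to the shortest path and round-trip", {
  full <- suspect_list(c(MON_A, MON_B), max_steps = 3)
  expect_false(any(duplicated(paste(full$formula, full$adduct))))
  # demethylated MON A coincides with the MON B parent entry
  monb <- full[full$formula == MON_B & full$adduct == "+Na", ]
  expect_identical(monb$n_steps, 0L)
  sub <- full[full$adduct == "+Na", ][1:20, ]
  for (i in seq_len(nrow(sub))) {
    rec <- decompose_mz(sub$mz_calc[i], adducts = "+Na", tol_ppm = 3)
    expect_true(sub$formula[i] %in% rec$formula)
  }
})

test_that("structural classing collapses stereoisomers but not chemistry", {
  cls <- structural_classes(data.frame(
    id = tp_rows$id, formula = tp_rows$neutral_formula,
    parent = tp_rows$parent_formula,
    isomer_annotation = tp_rows$isomer_annotation))
  expect_identical(cls$n_classes, 9L)
  # demethylation of either parent is one class
  expect_identical(cls$classes$class[cls$classes$id == "TP 8"],
                   cls$classes$class[cls$classes$id == "TP 9"])
  # the two formula-neutral hydrolysis isomers stay distinct
  expect_false(cls$classes$class[cls$classes$id == "TP 10"] ==
                 cls$classes$class[cls$classes$id == "TP 11"])

  single <- structural_classes(data.frame(formula = "C36H60O10",
                                          parent = MON_A))
  expect_identical(single$n_classes, 1L)

  stereo <- structural_classes(data.frame(
    formula = c("C36H64O10", "C36H64O10"), parent = c(MON_A, MON_A),
    isomer_annotation = c("stereoisomer", "stereoisomer"),
    retention = c(133, 144)))
  expect_identical(stereo$n_classes, 1L)

  expect_error(structural_classes(data.frame(formula = "C36H60O10",
                                             parent = NA_character_)),
               "parent")
})
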
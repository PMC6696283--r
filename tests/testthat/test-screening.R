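# Feature extraction, trend classification, suspect matching, occurrence.

test_that("scan series validates its inputs", {
  expect_error(scan_series(data.frame(axis_value = 1, mz = 100)),
               "columns")
  expect_error(scan_series(data.frame(axis_value = 1, mz = 100,
                                      intensity = -5)), "non-negative")
})

test_that("a stable peak links into exactly one full-length feature", {
  axis <- seq(0, 2, by = 0.5)
  ser <- make_series(693.4184, list(rep(1e5, 5)), axis)
  fs <- extract_features(ser, min_scans = 3)
  expect_identical(nrow(fs$features), 1L)
  expect_identical(fs$features$n_scans, 5L)
  expect_equal(fs$features$mz, 693.4184, tolerance = 1e-9)
  expect_identical(unname(fs$trace[1, ]), rep(1e5, 5))
})

test_that("a Na/NH4 adduct pair is never merged at 10 ppm", {
  axis <- seq(0, 2, by = 0.5)
  ser <- make_series(c(693.4184, 688.4630),
                     list(rep(1e5, 5), rep(3e5, 5)), axis)
  fs <- extract_features(ser, mz_tol_ppm = 10, min_scans = 3)
  expect_identical(nrow(fs$features), 2L)
})

test_that("trend classification follows the Spearman rule", {
  axis <- seq(0, 2.5, length.out = 11)
  up <- classify_trend(seq(1, 11), axis)
  expect_identical(up$class, "product")
  expect_identical(up$rho, 1)
  down <- classify_trend(seq(11, 1), axis)
  expect_identical(down$class, "precursor")
  expect_identical(down$rho, -1)
  flat <- classify_trend(rep(5, 11), axis)
  expect_identical(flat$class, "flat")
  expect_identical(flat$rho, 0)
  expect_error(classify_trend(1:3, 1:3), "4 scans")
})

test_that("noisy sigmoid rises classify as product in >= 95 of 100 runs", {
  set.seed(7)
  axis <- seq(0, 2.5, by = 0.1)
  truth <- stats::plogis((axis - 1.2) / 0.25)
  hits <- sum(vapply(1:100, function(i) {
    noisy <- truth * exp(stats::rnorm(length(axis), 0, 0.05))
    classify_trend(noisy, axis)$class == "product"
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("intensity classes use half-open lower-inclusive bins", {
  expect_identical(intensity_class(c(65, 60, 30, 10, 5), 100),
                   c("s", "s", "ms", "w", "vw"))
  expect_error(intensity_class(10, 0), "positive")
})

test_that("screening a synthetic voltammogram recovers the seeded TPs", {
  run <- generate_voltammogram(seed = 1)
  res <- screen_ec(run$series)
  seeded <- run$manifest$species
  tps <- seeded$formula[seeded$curve == "rise"]
  expect_setequal(res$records$formula, tps)
  expect_true(all(res$records$adduct_pair))
  # feature count: every species contributes its two adduct features
  expect_identical(nrow(res$features$features), 2L * nrow(seeded))
  # parents decay, so they never show up as product records
  expect_false(any(c("C36H62O11", "C35H60O11") %in% res$records$formula))
  # formula-level suspects credit the shortest path: C34H58O9 is two steps
  # from the MON B homologue (the study resolves MON A parentage by MS/MS)
  tp3 <- res$records[res$records$formula == "C34H58O9", ]
  expect_identical(tp3$path_label, "DECARBOXYLATION + DEHYDROGENATION")
  expect_identical(tp3$parent, "C35H60O11")
  expect_true(tp3$intensity_class %in% c("s", "ms"))
})

test_that("a parent-only run yields no product features", {
  parents_only <- ec_default_species()[1:2]
  run <- generate_voltammogram(species = parents_only, seed = 5)
  fs <- classify_features(extract_features(run$series))
  expect_false(any(fs$features$trend == "product"))
})

test_that("identical seeds give byte-identical reports end-to-end", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  for (f in c(f1, f2)) {
    run <- generate_voltammogram(seed = 23)
    write_tp_report(screen_ec(run$series), f)
  }
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("occurrence tables track presence against the day-1 parent", {
  run <- generate_hydrolysis_series(seed = 3)
  sus <- suspect_list("C36H62O11", max_steps = 1)
  occ <- occurrence_table(run$series, sus)
  man <- run$manifest$species
  # helper: first present day for the species nearest a manifest retention
  first_day <- function(ph, role) {
    rt <- man$rt[man$role == role]
    f <- man$formula[man$role == role]
    sub <- occ[occ$ph == ph & occ$formula == f & abs(occ$rt - rt) < 3, ]
    expect_gt(nrow(sub), 0)
    d <- sub$day[which(sub$present)]
    if (length(d)) min(d) else Inf
  }
  for (ph in c("3", "4", "5")) {
    # parent present on every sampled day
    expect_identical(first_day(ph, "parent"), 1)
    pres <- occ[occ$ph == ph & abs(occ$rt - man$rt[man$role == "parent"]) < 3 &
                  occ$formula == "C36H62O11", "present"]
    expect_true(all(pres))
    # appearance order: diastereomer <= ring-opened < dehydrated
    fd <- vapply(c("diastereomer", "ring_opened", "dehydrated"),
                 function(r) first_day(ph, r), numeric(1))
    expect_lte(fd[["diastereomer"]], fd[["ring_opened"]])
    expect_lt(fd[["ring_opened"]], fd[["dehydrated"]])
    # once present, always present (monotone kinetics)
    for (sp in unique(occ$species[occ$ph == ph])) {
      v <- occ$present[occ$ph == ph & occ$species == sp]
      v <- v[!is.na(v)]
      expect_true(all(diff(cummax(as.integer(v))) >= 0))
      expect_identical(as.logical(cummax(as.integer(v))), v)
    }
  }
  # a threshold above everything blanks the table
  occ_hi <- occurrence_table(run$series, sus, detect_threshold = 1e6)
  expect_false(any(occ_hi$present, na.rm = TRUE))
})
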
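# Screening pipeline: scan series -> features -> trend classes -> suspect
# matching -> TP report / occurrence tables.

#' Construct a scan series
#'
#' A scan series is the raw measurement container: centroided peak lists
#' over a strictly increasing scan axis that is either applied potential
#' (mass voltammograms from an electrochemical ramp) or storage time in
#' days (hydrolysis experiments). Peaks may optionally carry a retention
#' time (`rt`, seconds) when each scan is an LC/HRMS run; retention is what
#' separates formula-neutral isomers.
#'
#' @param peaks A data.frame with columns `axis_value`, `mz`, `intensity`
#'   (>= 0) and optionally `rt`. A `scan_id` column is accepted and ignored
#'   in favour of `axis_value`.
#' @param axis_kind `"potential"` (V) or `"time"` (days).
#' @param ph Solution pH, for hydrolysis series.
#' @param ramp_rate Potential ramp rate in V/s, for EC series.
#' @return An object of class `scan_series`: list with `peaks` (with a
#'   `scan` index column), `axis`, `axis_kind`, `ph`, `ramp_rate`.
#' @export
scan_series <- function(peaks, axis_kind = c("potential", "time"),
                        ph = NA_real_, ramp_rate = NA_real_) {
  axis_kind <- match.arg(axis_kind)
  need <- c("axis_value", "mz", "intensity")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop("peaks must have columns axis_value, mz, intensity")
  if (!nrow(peaks)) stop("empty peak list")
  if (any(peaks$intensity < 0)) stop("intensities must be non-negative")
  axis <- sort(unique(peaks$axis_value))
  if (any(diff(axis) <= 0)) stop("scan axis must be strictly increasing")
  peaks$scan <- match(peaks$axis_value, axis)
  keep <- intersect(c("scan", "axis_value", "mz", "intensity", "rt"),
                    names(peaks))
  structure(list(peaks = peaks[order(peaks$scan, peaks$mz), keep,
                               drop = FALSE],
                 axis = axis, axis_kind = axis_kind,
                 ph = ph, ramp_rate = ramp_rate),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat("scan_series:", length(x$axis), "scans over", x$axis_kind,
      sprintf("[%g, %g],", min(x$axis), max(x$axis)),
      nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' Read / write peak lists in the pipeline's CSV dialect
#'
#' Columns `scan_id`, `axis_value`, `mz`, `intensity` and optionally `rt`.
#'
#' @param path CSV file path.
#' @param ... Passed to [scan_series()] (`axis_kind`, `ph`, `ramp_rate`).
#' @return `read_peaklist` returns a `scan_series`; `write_peaklist`
#'   returns `path` invisibly.
#' @export
read_peaklist <- function(path, ...) {
  scan_series(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @rdname read_peaklist
#' @param series A `scan_series`.
#' @export
write_peaklist <- function(series, path) {
  pk <- series$peaks
  out <- data.frame(scan_id = pk$scan, axis_value = pk$axis_value,
                    mz = round(pk$mz, 6), intensity = round(pk$intensity, 3))
  if ("rt" %in% names(pk)) out$rt <- round(pk$rt, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Link peaks across scans into features
#'
#' Greedy nearest-m/z linking in scan order: each peak joins the nearest
#' existing feature within `mz_tol_ppm` of the feature's running
#' intensity-weighted mean m/z (and within `rt_tol` seconds when retention
#' times are present), at most one peak per feature per scan; otherwise it
#' founds a new feature. Scans where a feature has no peak are filled with
#' intensity zero. Features detected in fewer than `min_scans` scans are
#' dropped, which suppresses sporadic baseline peaks.
#'
#' @param series A [scan_series()].
#' @param mz_tol_ppm Linking tolerance in ppm (default twice the ~2 ppm
#'   mass accuracy of the targeted instruments).
#' @param min_scans Minimum number of scans a feature must appear in.
#' @param rt_tol Retention-time tolerance in seconds (used only when peaks
#'   carry `rt`).
#' @return An object of class `feature_set`: list with `features` (id, mz,
#'   rt, n_scans, max_intensity), `trace` (features x scans intensity
#'   matrix), `axis`, `axis_kind`, `ph`.
#' @export
extract_features <- function(series, mz_tol_ppm = 4, min_scans = 3L,
                             rt_tol = 5) {
  if (!inherits(series, "scan_series")) stop("series must be a scan_series")
  pk <- series$peaks
  nscan <- length(series$axis)
  has_rt <- "rt" %in% names(pk)
  f_mz <- numeric(0); f_w <- numeric(0)
  f_rt <- numeric(0); f_n <- integer(0)
  traces <- list()
  for (si in seq_len(nscan)) {
    rows <- pk[pk$scan == si, , drop = FALSE]
    if (!nrow(rows)) next
    rows <- rows[order(-rows$intensity), , drop = FALSE]
    taken <- rep(FALSE, length(f_mz))
    for (ri in seq_len(nrow(rows))) {
      mz <- rows$mz[ri]; int <- rows$intensity[ri]
      rt <- if (has_rt) rows$rt[ri] else NA_real_
      j <- 0L
      if (length(f_mz)) {
        d <- abs(f_mz - mz)
        ok <- !taken & d <= mz_tol_ppm * 1e-6 * f_mz
        if (has_rt) ok <- ok & abs(f_rt - rt) <= rt_tol
        if (any(ok)) {
          cand <- which(ok)
          j <- cand[which.min(d[cand])]
        }
      }
      if (j == 0L) {
        f_mz <- c(f_mz, mz); f_w <- c(f_w, 0)
        f_rt <- c(f_rt, if (has_rt) rt else NA_real_)
        f_n <- c(f_n, 0L)
        traces[[length(traces) + 1L]] <- numeric(nscan)
        taken <- c(taken, FALSE)
        j <- length(f_mz)
      }
      w <- max(int, .Machine$double.eps)
      f_mz[j] <- (f_mz[j] * f_w[j] + mz * w) / (f_w[j] + w)
      if (has_rt) f_rt[j] <- (f_rt[j] * f_w[j] + rt * w) / (f_w[j] + w)
      f_w[j] <- f_w[j] + w
      traces[[j]][si] <- traces[[j]][si] + int
      f_n[j] <- f_n[j] + 1L
      taken[j] <- TRUE
    }
  }
  keep <- f_n >= min_scans
  trace <- if (any(keep)) do.call(rbind, traces[keep]) else
    matrix(numeric(0), nrow = 0, ncol = nscan)
  features <- data.frame(
    feature_id = seq_len(sum(keep)),
    mz = f_mz[keep],
    rt = f_rt[keep],
    n_scans = f_n[keep],
    max_intensity = if (any(keep)) apply(trace, 1, max) else numeric(0))
  structure(list(features = features, trace = trace, axis = series$axis,
                 axis_kind = series$axis_kind, ph = series$ph),
            class = "feature_set")
}

#' Classify the potential / time trend of an intensity trace
#'
#' Spearman rank correlation of intensity against the scan axis: rising
#' traces (rho >= threshold) are products, falling traces
#' (rho <= -threshold) precursors, anything else flat. Rank correlation is
#' robust to the sigmoidal shape of mass-voltammogram traces. Constant
#' traces are flat with statistic 0.
#'
#' @param intensity Numeric intensity trace (>= 4 scans).
#' @param axis Scan axis values, same length.
#' @param threshold Correlation threshold in (0, 1]; default 0.6.
#' @return List with `class` (`"precursor"`, `"product"` or `"flat"`) and
#'   `rho`.
#' @export
classify_trend <- function(intensity, axis, threshold = 0.6) {
  if (length(intensity) != length(axis)) stop("length mismatch")
  if (length(axis) < 4L) stop("trend classification needs >= 4 scans")
  rho <- suppressWarnings(stats::cor(intensity, axis, method = "spearman"))
  if (is.na(rho)) rho <- 0
  cls <- if (rho >= threshold) "product" else
    if (rho <= -threshold) "precursor" else "flat"
  list(class = cls, rho = rho)
}

#' Classify every feature in a feature set
#'
#' @param fs A `feature_set`.
#' @param threshold Passed to [classify_trend()].
#' @return The feature set with `trend` and `rho` columns added to
#'   `$features`.
#' @export
classify_features <- function(fs, threshold = 0.6) {
  if (!nrow(fs$features)) {
    fs$features$trend <- character(0)
    fs$features$rho <- numeric(0)
    return(fs)
  }
  res <- lapply(seq_len(nrow(fs$features)), function(i)
    classify_trend(fs$trace[i, ], fs$axis, threshold))
  fs$features$trend <- vapply(res, `[[`, character(1), "class")
  fs$features$rho <- vapply(res, `[[`, numeric(1), "rho")
  fs
}

#' Relative-intensity class of a TP
#'
#' Bins the TP/parent intensity ratio into the conventional reporting
#' classes: strong (s) for >= 60 %, moderately strong (ms) for 30-60 %,
#' weak (w) for 10-30 %, very weak (vw) below 10 %. Bins are half-open,
#' lower-inclusive.
#'
#' @param tp_intensity,parent_intensity Intensities (counts);
#'   `parent_intensity` must be positive. Vectorized over `tp_intensity`.
#' @return Character vector of classes.
#' @export
#' @examples
#' intensity_class(c(65, 30, 5), 100)
intensity_class <- function(tp_intensity, parent_intensity) {
  if (any(parent_intensity <= 0))
    stop("parent intensity must be positive to define a class")
  r <- tp_intensity / parent_intensity
  cut(r, breaks = c(-Inf, 0.10, 0.30, 0.60, Inf),
      labels = c("vw", "w", "ms", "s"), right = FALSE) |> as.character()
}

#' Match product features against a suspect list
#'
#' Each product-classified feature is matched to the nearest suspect m/z
#' within `tol_ppm`; when two suspects fall inside the window the lower
#' |ppm| wins and both are reported in a message. Matches are merged per
#' neutral formula across adducts; a Na/NH4 pair is declared when both
#' adduct features exist and their observed spacing equals the theoretical
#' 4.9554 Da within the tolerance window. Product features with no suspect
#' within tolerance are returned separately as unknowns.
#'
#' @param fs A classified `feature_set` (see [classify_features()]).
#' @param suspects A suspect list from [suspect_list()].
#' @param tol_ppm Match tolerance in ppm.
#' @param parents Parent neutral formulas; the reference intensity for
#'   classing is the maximum intensity of any feature matching the first
#'   parent's adduct m/z values (the dominant standard), irrespective of
#'   trend class.
#' @return A list of class `tp_screen` with `records` (one row per matched
#'   formula: formula, parent, path_label, n_steps, mz, ppm, adducts,
#'   adduct_pair, max_intensity, rel_intensity, intensity_class, rho) and
#'   `unknowns` (unmatched product features).
#' @export
match_suspects <- function(fs, suspects, tol_ppm = 3,
                           parents = c("C36H62O11", "C35H60O11")) {
  if (!nrow(suspects)) stop("suspect list is empty")
  feats <- fs$features
  prods <- feats[feats$trend == "product", , drop = FALSE]
  # reference intensity: the first parent's features, any trend class
  ref_mzs <- vapply(unique(suspects$adduct), function(a)
    adduct_mz(parents[[1]], a), numeric(1))
  ref_hit <- vapply(feats$mz, function(m)
    any(abs(ppm_error(m, ref_mzs)) <= tol_ppm), logical(1))
  parent_ref <- if (any(ref_hit)) max(feats$max_intensity[ref_hit]) else NA_real_
  matches <- list(); unknown <- list()
  for (i in seq_len(nrow(prods))) {
    pe <- ppm_error(prods$mz[i], suspects$mz_calc)
    inside <- which(abs(pe) <= tol_ppm)
    if (!length(inside)) {
      unknown[[length(unknown) + 1L]] <- prods[i, , drop = FALSE]
      next
    }
    if (length(unique(suspects$formula[inside])) > 1L)
      message("ambiguous match at m/z ", round(prods$mz[i], 4), ": ",
              paste(unique(suspects$formula[inside]), collapse = ", "),
              "; keeping lowest |ppm|")
    best <- inside[which.min(abs(pe[inside]))]
    row <- cbind(prods[i, , drop = FALSE],
                 suspects[best, c("formula", "parent", "path_label",
                                  "n_steps", "adduct", "mz_calc")],
                 ppm = pe[best])
    matches[[length(matches) + 1L]] <- row
  }
  records <- data.frame()
  if (length(matches)) {
    m <- do.call(rbind, matches)
    na_delta <- adduct_pair_delta("+Na", "+NH4")
    records <- do.call(rbind, lapply(split(m, m$formula), function(g) {
      g <- g[order(-g$max_intensity), , drop = FALSE]
      pair <- FALSE
      if (all(c("+Na", "+NH4") %in% g$adduct)) {
        mz_na <- g$mz[match("+Na", g$adduct)]
        mz_nh4 <- g$mz[match("+NH4", g$adduct)]
        pair <- abs((mz_na - mz_nh4) - na_delta) <= 2 * tol_ppm * 1e-6 * mz_na
      }
      data.frame(formula = g$formula[1], parent = g$parent[1],
                 path_label = g$path_label[1], n_steps = g$n_steps[1],
                 mz = g$mz[1], ppm = g$ppm[1],
                 adducts = paste(sort(unique(g$adduct)), collapse = ";"),
                 adduct_pair = pair,
                 max_intensity = max(g$max_intensity),
                 rho = g$rho[1], stringsAsFactors = FALSE)
    }))
    records$rel_intensity <- if (is.na(parent_ref)) NA_real_ else
      records$max_intensity / parent_ref
    records$intensity_class <- if (is.na(parent_ref)) NA_character_ else
      intensity_class(records$max_intensity, parent_ref)
    records <- records[order(records$mz), , drop = FALSE]
    rownames(records) <- NULL
  }
  unknowns <- if (length(unknown)) do.call(rbind, unknown) else
    prods[0, , drop = FALSE]
  structure(list(records = records, unknowns = unknowns,
                 parent_ref = parent_ref),
            class = "tp_screen")
}

#' End-to-end screening of an EC mass voltammogram
#'
#' Feature extraction, trend classification, suspect generation from the
#' parents and suspect matching, in one call.
#'
#' @param series A `scan_series` over potential.
#' @param parents Parent neutral formulas (most abundant first).
#' @param config A configuration list, see [default_config()].
#' @return A `tp_screen` list with `records`, `unknowns`, `features`,
#'   `suspects`.
#' @export
screen_ec <- function(series, parents = c("C36H62O11", "C35H60O11"),
                      config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  fs <- extract_features(series, mz_tol_ppm = cfg$mz_tol_ppm,
                         min_scans = cfg$min_scans, rt_tol = cfg$rt_tol)
  fs <- classify_features(fs, threshold = cfg$trend_threshold)
  sus <- suspect_list(parents, max_steps = cfg$max_steps,
                      adducts = cfg$adducts)
  res <- match_suspects(fs, sus, tol_ppm = cfg$tol_ppm, parents = parents)
  res$features <- fs
  res$suspects <- sus
  res
}

#' Occurrence of suspects across storage days and pH
#'
#' For each pH series, features are extracted (any trend), matched to the
#' suspect list by m/z, grouped into species (same formula, same retention
#' cluster; the Na and NH4 adduct features of one species merge), and
#' declared present on a sampling day when any member feature's intensity
#' reaches `detect_threshold` times the parent intensity on the first
#' sampled day. Days missing from a series are `NA` (not measured), which
#' is distinct from absent.
#'
#' @param series_list Named list of `scan_series` over time, one per pH
#'   (names like `"3"`; unnamed lists fall back to each series' `ph`).
#' @param suspects Suspect list ([suspect_list()]).
#' @param tol_ppm Match tolerance in ppm.
#' @param detect_threshold Fraction of the day-1 parent intensity.
#' @param parent Parent neutral formula used for the reference intensity.
#' @param mz_tol_ppm,rt_tol,min_scans Feature-extraction settings.
#' @return A long data.frame with columns `ph`, `species`, `formula`, `rt`,
#'   `day`, `present` (logical, `NA` = not measured). See
#'   [format_occurrence()] for the wide day-by-day layout.
#' @export
occurrence_table <- function(series_list, suspects, tol_ppm = 3,
                             detect_threshold = 0.01,
                             parent = "C36H62O11", mz_tol_ppm = 4,
                             rt_tol = 5, min_scans = 1L) {
  if (!length(series_list)) stop("no series supplied")
  phs <- names(series_list)
  if (is.null(phs) || any(!nzchar(phs)))
    phs <- vapply(series_list, function(s) as.character(s$ph), character(1))
  all_days <- sort(unique(unlist(lapply(series_list, `[[`, "axis"))))
  out <- list()
  for (si in seq_along(series_list)) {
    ser <- series_list[[si]]
    fs <- extract_features(ser, mz_tol_ppm = mz_tol_ppm,
                           min_scans = min_scans, rt_tol = rt_tol)
    feats <- fs$features
    if (!nrow(feats)) next
    # nearest suspect per feature
    hit <- lapply(feats$mz, function(m) {
      pe <- ppm_error(m, suspects$mz_calc)
      j <- which.min(abs(pe))
      if (abs(pe[j]) <= tol_ppm) j else NA_integer_
    })
    feats$suspect <- unlist(hit)
    matched <- which(!is.na(feats$suspect))
    if (!length(matched)) next
    feats$formula <- NA_character_
    feats$formula[matched] <- suspects$formula[feats$suspect[matched]]
    # parent reference: day-1 intensity of the most intense parent feature
    pref <- matched[feats$formula[matched] == format_formula(parent)]
    if (!length(pref))
      stop("parent formula not detected in series; cannot set threshold")
    day1 <- max(fs$trace[pref, 1, drop = TRUE])
    thr <- detect_threshold * day1
    # cluster matched features into species: same formula, retention gap <= rt_tol
    mf <- feats[matched, , drop = FALSE]
    mf$row <- matched
    for (f in unique(mf$formula)) {
      grp <- mf[mf$formula == f, , drop = FALSE]
      grp <- grp[order(grp$rt, grp$mz), , drop = FALSE]
      cl <- if (all(is.na(grp$rt))) rep(1L, nrow(grp)) else
        cumsum(c(1L, as.integer(diff(grp$rt) > rt_tol)))
      for (ci in unique(cl)) {
        g <- grp[cl == ci, , drop = FALSE]
        tr <- fs$trace[g$row, , drop = FALSE]
        present_here <- apply(tr, 2, max) >= thr
        rt_rep <- g$rt[which.max(g$max_intensity)]
        species <- if (is.na(rt_rep)) f else sprintf("%s@%.0fs", f, rt_rep)
        pres <- rep(NA, length(all_days))
        pres[match(fs$axis, all_days)] <- present_here
        out[[length(out) + 1L]] <- data.frame(
          ph = phs[si], species = species, formula = f, rt = rt_rep,
          day = all_days, present = pres, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wide day-by-day occurrence layout
#'
#' Pivots the long occurrence table into one row per (pH, species) with a
#' column per sampling day: `"x"` present, `""` absent, `"."` not measured.
#'
#' @param occ Output of [occurrence_table()].
#' @return A data.frame in the wide layout.
#' @export
format_occurrence <- function(occ) {
  days <- sort(unique(occ$day))
  keys <- unique(occ[, c("ph", "species")])
  wide <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- occ[occ$ph == keys$ph[i] & occ$species == keys$species[i], ]
    cells <- vapply(days, function(d) {
      p <- sub$present[match(d, sub$day)]
      if (is.na(p)) "." else if (p) "x" else ""
    }, character(1))
    stats::setNames(data.frame(keys$ph[i], keys$species[i],
                               t(cells), stringsAsFactors = FALSE),
                    c("ph", "species", paste0("day", days)))
  }))
  rownames(wide) <- NULL
  wide
}

#' Screening configuration defaults
#'
#' All tunable tolerances and thresholds of the pipeline in one list:
#' `tol_ppm` (suspect match window, 3), `mz_tol_ppm` (feature linking, 4),
#' `min_scans` (3), `rt_tol` (5 s), `trend_threshold` (Spearman rho, 0.6),
#' `detect_threshold` (fraction of day-1 parent, 0.01), `adducts`,
#' `max_steps` (3), `seed` (1).
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(tol_ppm = 3, mz_tol_ppm = 4, min_scans = 3L, rt_tol = 5,
       trend_threshold = 0.6, detect_threshold = 0.01,
       adducts = c("+Na", "+NH4"), max_steps = 3L, seed = 1L)
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defs <- default_config()
  bad <- setdiff(names(user), names(defs))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defs, user)
}

#' Write a TP report CSV
#'
#' Serializes screening records in a fixed column order with fixed rounding
#' so that identical inputs, configuration and seed produce byte-identical
#' reports.
#'
#' @param result A `tp_screen` object or its `records` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tp_report <- function(result, path) {
  rec <- if (inherits(result, "tp_screen")) result$records else result
  out <- data.frame(
    formula = rec$formula, parent = rec$parent,
    transformation = rec$path_label, n_steps = rec$n_steps,
    mz = sprintf("%.4f", rec$mz), ppm = sprintf("%.2f", rec$ppm),
    adducts = rec$adducts, adduct_pair = rec$adduct_pair,
    intensity_class = rec$intensity_class,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
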
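# Element-bounded molecular formula decomposition within a ppm tolerance.
#
# The enumeration loops over the bounded C/N/O/Na lattice and solves the
# hydrogen count by mass closure, which makes it exhaustive and fast at the
# default bounds (a few thousand lattice points).  The ppm tolerance is
# applied on the adduct m/z, not on the neutral mass.

#' Element count bounds for formula decomposition
#'
#' Defaults are wide enough to cover a C36 polyether scaffold and its
#' plausible transformation products: C 0-60, H 0-120, N 0-2, O 0-20,
#' Na 0-1. N and Na are admitted mainly to account for adduct chemistry.
#'
#' @param C,H,N,O,Na Length-2 integer vectors `c(min, max)`.
#' @return A named list of `c(min, max)` bounds, class `element_bounds`.
#' @export
element_bounds <- function(C = c(0, 60), H = c(0, 120), N = c(0, 2),
                           O = c(0, 20), Na = c(0, 1)) {
  b <- list(C = C, H = H, N = N, O = O, Na = Na)
  for (s in names(b)) {
    v <- as.integer(b[[s]])
    if (length(v) != 2L || v[1] < 0L || v[1] > v[2])
      stop("bounds for ", s, " must satisfy 0 <= min <= max")
    b[[s]] <- v
  }
  structure(b, class = "element_bounds")
}

#' Decompose an observed m/z into candidate molecular formulas
#'
#' Enumerates every neutral formula within the element bounds whose adduct
#' m/z lies within `tol_ppm` of the observation, for each requested adduct
#' species. The search is exhaustive over the bounded lattice; hydrogen is
#' solved by mass closure. Candidates failing the RDBE plausibility filter
#' (when enabled) are dropped.
#'
#' @param mz Observed m/z (single positive number).
#' @param adducts Character vector of adduct species to consider.
#' @param tol_ppm Mass tolerance in ppm, applied on the adduct m/z.
#' @param bounds An [element_bounds()] object.
#' @param rdbe_filter Keep only candidates with RDBE inside `rdbe_range`
#'   (computed on the neutral formula; Na excluded by construction).
#' @param rdbe_range Allowed RDBE interval.
#' @return A data.frame of class `candidate_set` with columns `formula`,
#'   `adduct`, `mz_calc`, `ppm`, `rdbe` and `sigma` (NA until ranked),
#'   sorted by `abs(ppm)`. Zero rows is a legitimate outcome.
#' @export
#' @examples
#' decompose_mz(693.4184, adducts = "+Na")
decompose_mz <- function(mz, adducts = c("+Na", "+NH4"), tol_ppm = 3,
                         bounds = element_bounds(), rdbe_filter = TRUE,
                         rdbe_range = c(0, 40)) {
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0)
    stop("mz must be a single positive number")
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (!inherits(bounds, "element_bounds")) bounds <- do.call(element_bounds, bounds)
  lattice <- prod(vapply(bounds[c("C", "N", "O", "Na")],
                         function(v) v[2] - v[1] + 1, numeric(1)))
  if (lattice > 1e8)
    stop("element bounds admit more than 1e8 lattice points; ",
         "tighten the bounds")
  adducts <- vapply(adducts, normalize_adduct, character(1), USE.NAMES = FALSE)
  mono <- monoisotopic_masses()
  win <- tol_ppm * 1e-6 * mz
  grid <- expand.grid(C = seq(bounds$C[1], bounds$C[2]),
                      N = seq(bounds$N[1], bounds$N[2]),
                      O = seq(bounds$O[1], bounds$O[2]),
                      Na = seq(bounds$Na[1], bounds$Na[2]),
                      KEEP.OUT.ATTRS = FALSE)
  partial <- grid$C * mono[["C"]] + grid$N * mono[["N"]] +
    grid$O * mono[["O"]] + grid$Na * mono[["Na"]]
  out <- list()
  for (a in adducts) {
    target <- mz - adduct_atom_mass(a) + ELECTRON_MASS  # neutral-mass center
    h0 <- round((target - partial) / mono[["H"]])
    for (dh in -1L:1L) {
      h <- h0 + dh
      ok <- h >= bounds$H[1] & h <= bounds$H[2]
      if (!any(ok)) next
      neutral <- partial[ok] + h[ok] * mono[["H"]]
      mz_calc <- neutral + adduct_atom_mass(a) - ELECTRON_MASS
      hit <- abs(mz_calc - mz) <= win
      if (!any(hit)) next
      g <- grid[ok, , drop = FALSE][hit, , drop = FALSE]
      g$H <- h[ok][hit]
      out[[length(out) + 1L]] <- data.frame(
        C = g$C, H = g$H, N = g$N, O = g$O, Na = g$Na,
        adduct = a, mz_calc = mz_calc[hit],
        ppm = ppm_error(mz, mz_calc[hit]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(C = integer(0), H = integer(0), N = integer(0),
               O = integer(0), Na = integer(0), adduct = character(0),
               mz_calc = numeric(0), ppm = numeric(0))
  res$rdbe <- res$C - res$H / 2 + res$N / 2 + 1
  if (rdbe_filter && nrow(res))
    res <- res[res$rdbe >= rdbe_range[1] & res$rdbe <= rdbe_range[2], ,
               drop = FALSE]
  res$formula <- vapply(seq_len(nrow(res)), function(i)
    format_formula(c(C = res$C[i], H = res$H[i], N = res$N[i],
                     O = res$O[i], Na = res$Na[i])), character(1))
  res <- res[!duplicated(paste(res$formula, res$adduct)), , drop = FALSE]
  res <- res[order(abs(res$ppm), res$formula), , drop = FALSE]
  res$sigma <- rep(NA_real_, nrow(res))
  rownames(res) <- NULL
  structure(res[, c("formula", "adduct", "mz_calc", "ppm", "rdbe", "sigma")],
            class = c("candidate_set", "data.frame"))
}

#' Rank candidate formulas by isotope-pattern fit
#'
#' Computes the sigma fit score of each candidate's theoretical isotope
#' pattern against the observed pattern and sorts by
#' (sigma, |ppm|, formula text) -- a fully specified, deterministic key.
#' Without an observed pattern the candidates are ranked by |ppm| alone and
#' a warning is raised.
#'
#' @param candidates A `candidate_set` from [decompose_mz()] (all candidates
#'   should explain the same observed m/z).
#' @param observed_pattern An observed isotope pattern (data.frame with
#'   `mass` and `abundance`/`intensity`), or `NULL`.
#' @param prune,max_peaks Passed to [theoretical_pattern()].
#' @return The candidate set with `sigma` filled in, a `rank` column added
#'   and rows sorted by rank.
#' @export
rank_candidates <- function(candidates, observed_pattern = NULL,
                            prune = 1e-4, max_peaks = 6L) {
  res <- as.data.frame(candidates)
  if (!nrow(res)) {
    res$rank <- integer(0)
    return(structure(res, class = c("candidate_set", "data.frame")))
  }
  if (is.null(observed_pattern)) {
    warning("no observed isotope pattern; ranking by |ppm| only")
    ord <- order(abs(res$ppm), res$formula)
  } else {
    res$sigma <- vapply(seq_len(nrow(res)), function(i) {
      th <- theoretical_pattern(res$formula[i], res$adduct[i],
                                prune = prune, max_peaks = max_peaks)
      tryCatch(sigma_score(th, observed_pattern, prune = prune),
               error = function(e) Inf)
    }, numeric(1))
    ord <- order(res$sigma, abs(res$ppm), res$formula)
  }
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, class = c("candidate_set", "data.frame"))
}

#' Subformula candidates for a fragment ion
#'
#' Decomposes a fragment m/z while restricting the search to element-wise
#' subsets of a fixed precursor formula, the generic support used when
#' assigning MS/MS fragments of an identified precursor.
#'
#' @param fragment_mz Observed fragment m/z; must not exceed the precursor
#'   adduct m/z beyond tolerance.
#' @param precursor Neutral precursor formula (string or named counts).
#' @param tol_ppm Mass tolerance in ppm.
#' @param adducts Adduct species considered for the fragment (sodiated
#'   polyether fragments typically retain Na).
#' @param rdbe_filter Off by default: odd-electron fragment compositions are
#'   legitimate.
#' @return A `candidate_set` (possibly empty).
#' @export
subformula_candidates <- function(fragment_mz, precursor, tol_ppm = 3,
                                  adducts = c("+H", "+Na"),
                                  rdbe_filter = FALSE) {
  p <- as_formula(precursor)
  cnt <- function(s) if (s %in% names(p)) p[[s]] else 0L
  b <- element_bounds(C = c(0, cnt("C")), H = c(0, cnt("H")),
                      N = c(0, cnt("N")), O = c(0, cnt("O")),
                      Na = c(0, cnt("Na")))
  decompose_mz(fragment_mz, adducts = adducts, tol_ppm = tol_ppm,
               bounds = b, rdbe_filter = rdbe_filter)
}
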
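# Theoretical isotope patterns and the sigma-style fit score.
#
# Patterns are aggregated by nominal mass (integer Da offsets from the
# monoisotopic peak): the time-of-flight resolution this pipeline targets
# does not resolve fine isotopic structure, so e.g. 13C and 17O
# contributions to M+1 fall into one centroid whose mass is the
# abundance-weighted mean.

# single-atom distribution of one element over nominal-mass offsets
single_atom_dist <- function(symbol, kmax) {
  el <- element_table()
  iso <- el[el$symbol == symbol, , drop = FALSE]
  k <- iso$nominal - iso$nominal[1]
  ab <- numeric(kmax + 1L)
  m <- numeric(kmax + 1L)
  keep <- k <= kmax
  ab[k[keep] + 1L] <- iso$abundance[keep]
  m[k[keep] + 1L] <- iso$mass[keep]
  # renormalize in case a heavy isotope fell outside the window
  list(ab = ab / sum(ab), m = m)
}

# convolution of two offset distributions, tracking weighted mean masses
dist_conv <- function(a, b, kmax) {
  ab <- numeric(kmax + 1L)
  mm <- numeric(kmax + 1L)
  for (i in seq_along(a$ab)) {
    if (a$ab[i] == 0) next
    jmax <- min(length(b$ab), kmax + 2L - i)
    for (j in seq_len(jmax)) {
      if (b$ab[j] == 0) next
      k <- i + j - 1L
      w <- a$ab[i] * b$ab[j]
      ab[k] <- ab[k] + w
      mm[k] <- mm[k] + w * (a$m[i] + b$m[j])
    }
  }
  list(ab = ab, m = ifelse(ab > 0, mm / ab, 0))
}

# n-fold self-convolution by binary exponentiation
dist_power <- function(d, n, kmax) {
  unit <- list(ab = c(1, numeric(kmax)), m = numeric(kmax + 1L))
  acc <- unit
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- dist_conv(acc, base, kmax)
    n <- n %/% 2L
    if (n > 0L) base <- dist_conv(base, base, kmax)
  }
  acc
}

#' Theoretical isotope pattern of a molecule or adduct ion
#'
#' Convolves the per-element isotope distributions of the formula (plus the
#' adduct atoms, when an adduct is given), aggregates by nominal-mass bin,
#' normalizes to the base peak and prunes minor peaks.
#'
#' @param neutral Neutral formula (string or named counts).
#' @param adduct Optional adduct species (`"+H"`, `"+Na"`, `"+NH4"`). When
#'   given, the pattern is that of the singly charged cation: the adduct
#'   atoms are convolved in and the electron mass subtracted from every
#'   centroid.
#' @param prune Drop peaks below this fraction of the base peak; must lie in
#'   (0, 0.1].
#' @param max_peaks Keep at most this many peaks (>= 2), counted from the
#'   lightest.
#' @return An object of class `isotope_pattern`: a data.frame with columns
#'   `mass` (centroid, Da) and `abundance` (fraction of base peak, exactly
#'   one equal to 1).
#' @export
#' @examples
#' theoretical_pattern("C36H62O11", "+Na")
theoretical_pattern <- function(neutral, adduct = NULL, prune = 1e-4,
                                max_peaks = 6L) {
  if (!(prune > 0 && prune <= 0.1))
    stop("prune must lie in (0, 0.1]")
  if (max_peaks < 2L)
    stop("max_peaks must be at least 2")
  atoms <- as_formula(neutral)
  charged <- !is.null(adduct)
  if (charged)
    atoms <- canonical_formula(apply_delta(atoms, .adduct_atoms[[normalize_adduct(adduct)]]))
  if (!length(atoms))
    stop("cannot compute an isotope pattern for the empty formula")
  kmax <- max_peaks + 3L  # head-room before final truncation
  acc <- NULL
  for (s in names(atoms)) {
    d <- dist_power(single_atom_dist(s, kmax), atoms[[s]], kmax)
    acc <- if (is.null(acc)) d else dist_conv(acc, d, kmax)
  }
  mass <- acc$m - if (charged) ELECTRON_MASS else 0
  ab <- acc$ab / max(acc$ab)
  keep <- ab >= prune
  mass <- mass[keep]
  ab <- ab[keep]
  ord <- order(mass)
  mass <- mass[ord][seq_len(min(max_peaks, length(mass)))]
  ab <- ab[ord][seq_len(min(max_peaks, length(ab)))]
  structure(data.frame(mass = mass, abundance = ab),
            class = c("isotope_pattern", "data.frame"))
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("isotope pattern (", nrow(x), " peaks)\n", sep = "")
  print(data.frame(mass = round(x$mass, 4),
                   abundance = signif(x$abundance, 4)))
  invisible(x)
}

#' Sigma-style isotope pattern fit score
#'
#' Root-mean-square deviation between two base-peak-normalized isotope
#' patterns after matching peaks by nearest nominal-mass bin (integer Da
#' offsets from the theoretical monoisotopic peak). Bins present in only one
#' pattern contribute their full abundance as deviation, so a missing
#' theoretical peak is penalized exactly like a spurious observed one.
#' Zero means a perfect fit; the score is scale-invariant and, for patterns
#' covering the same bins, symmetric in its arguments.
#'
#' @param theoretical,observed `isotope_pattern` objects or data.frames with
#'   `mass` and `abundance` (or `intensity`) columns. Absolute intensity
#'   scales are irrelevant; both are renormalized.
#' @param prune Theoretical bins below this fraction of base peak are
#'   ignored rather than counted as missing.
#' @return Non-negative dimensionless score (lower is better).
#' @export
#' @examples
#' p <- theoretical_pattern("C36H62O11", "+Na")
#' sigma_score(p, p)
sigma_score <- function(theoretical, observed, prune = 1e-4) {
  norm_pat <- function(p) {
    if (!is.data.frame(p) || !"mass" %in% names(p))
      stop("patterns must be data.frames with a 'mass' column")
    ab <- if ("abundance" %in% names(p)) p$abundance else p$intensity
    if (is.null(ab) || !nrow(p))
      stop("patterns must be non-empty with abundances")
    data.frame(mass = p$mass, ab = ab / max(ab))
  }
  th <- norm_pat(theoretical)
  ob <- norm_pat(observed)
  ref <- min(th$mass)  # lightest theoretical centroid
  kt <- round(th$mass - ref)
  ko <- round(ob$mass - ref)
  th_ab <- vapply(split(th$ab, kt), sum, numeric(1))
  ob_ab <- vapply(split(ob$ab, ko), sum, numeric(1))
  th_ab <- th_ab[th_ab >= prune]
  if (!length(intersect(names(th_ab), names(ob_ab))))
    stop("patterns share no nominal-mass bins; cannot be compared")
  bins <- union(names(th_ab), names(ob_ab))
  t_v <- ifelse(bins %in% names(th_ab), th_ab[bins], 0)
  o_v <- ifelse(bins %in% names(ob_ab), ob_ab[bins], 0)
  sqrt(mean((t_v - o_v)^2))
}
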
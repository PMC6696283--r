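# Atomic constants and molecular formula arithmetic.
#
# Formulas are named integer vectors over the alphabet {C, H, N, O, Na},
# stored in Hill order with zero counts dropped.  All masses are
# monoisotopic (lightest isotope) and come from the isotope table shipped
# in inst/extdata/isotopes.csv.  Na is ordinarily adduct chemistry, but a
# neutral formula may carry Na so that sodiated formula strings such as
# "C36H62O11Na" can be represented verbatim; split_adduct_formula() turns
# them into (neutral, "+Na") form.

.tp <- new.env(parent = emptyenv())

#' Rest mass of the electron in Da
#'
#' Subtracted once from the mass of every singly charged cation, so that
#' computed adduct m/z values refer to the ion, not the neutral species.
#'
#' @export
ELECTRON_MASS <- 0.000548579909

#' Isotope table of the supported elements
#'
#' One row per stable isotope of C, H, N, O and Na: the nominal mass number,
#' the exact mass in Da and the relative isotopic abundance. Within each
#' element the abundances sum to one and the exact masses increase strictly;
#' these invariants are what the isotope-pattern simulator relies on.
#'
#' @return A data.frame with columns `symbol`, `nominal`, `mass` and
#'   `abundance`, ordered by element symbol and mass.
#' @export
#' @examples
#' element_table()
element_table <- function() {
  if (is.null(.tp$elements)) {
    path <- system.file("extdata", "isotopes.csv", package = "tpscreen",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab <- tab[order(tab$symbol, tab$mass), , drop = FALSE]
    rownames(tab) <- NULL
    .tp$elements <- tab
  }
  .tp$elements
}

element_alphabet <- function() unique(element_table()$symbol)

# named vector of monoisotopic (lightest isotope) masses
monoisotopic_masses <- function() {
  if (is.null(.tp$mono)) {
    el <- element_table()
    .tp$mono <- vapply(split(el$mass, el$symbol), min, numeric(1))
  }
  .tp$mono
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill notation (`"C36H62O11"`) as well as the
#' underscore-subscript dialect used in printed TP tables
#' (`"C_36_H_62_O_11_Na"`). Repeated element tokens are summed.
#'
#' @param x A formula string, or an already-parsed named count vector
#'   (returned unchanged after validation). The empty string is the empty
#'   formula (mass zero).
#' @return A named integer vector of element counts in Hill order
#'   (C, H, then alphabetically), zero counts dropped.
#' @export
#' @examples
#' parse_formula("C36H62O11")
#' parse_formula("C_36_H_62_O_11_Na")
parse_formula <- function(x) {
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single formula string")
  s <- gsub("_", "", trimws(x))
  counts <- stats::setNames(integer(0), character(0))
  if (nzchar(s)) {
    tokens <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
    if (paste(tokens, collapse = "") != s)
      stop("cannot parse formula: ", sQuote(x))
    sym <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Za-z]+", "", tokens)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    bad <- setdiff(sym, element_alphabet())
    if (length(bad))
      stop("element(s) outside the supported alphabet: ",
           paste(bad, collapse = ", "))
    counts <- vapply(split(n, sym), sum, integer(1))
  }
  canonical_formula(counts)
}

# sort counts into Hill order and drop zeros
canonical_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (!length(counts)) return(stats::setNames(integer(0), character(0)))
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  out <- as.integer(counts[ord])
  names(out) <- ord
  out
}

#' Coerce to a formula count vector
#'
#' @param x A formula string or a named non-negative integer vector.
#' @return Validated named integer counts in Hill order.
#' @export
as_formula <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (is.null(names(x)) && length(x))
    stop("numeric formulas must be named by element symbol")
  bad <- setdiff(names(x), element_alphabet())
  if (length(bad))
    stop("element(s) outside the supported alphabet: ",
         paste(bad, collapse = ", "))
  if (any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers")
  counts <- as.integer(round(x))
  names(counts) <- names(x)
  canonical_formula(tapply(counts, names(counts), sum))
}

#' Format a formula count vector as text
#'
#' @param f Formula (string or named counts).
#' @param style `"hill"` for plain text (`"C36H62O11Na"`) or `"table"` for
#'   the underscore-subscript dialect (`"C_36_H_62_O_11_Na"`).
#' @return A single string; the empty formula formats as `""`.
#' @export
format_formula <- function(f, style = c("hill", "table")) {
  style <- match.arg(style)
  f <- as_formula(f)
  if (!length(f)) return("")
  piece <- ifelse(f == 1L, names(f),
                  if (style == "hill") paste0(names(f), f)
                  else paste0(names(f), "_", f, "_"))
  out <- paste(piece, collapse = "")
  sub("_$", "", out)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the exact mass of the lightest isotope.
#'
#' @param f Formula (string or named counts).
#' @return Mass in Da; `0` for the empty formula.
#' @export
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C36H62O11")
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return(0)
  sum(f * monoisotopic_masses()[names(f)])
}

#' Element-wise difference between two formulas
#'
#' Returns `product - parent` per element; entries may be negative. Used to
#' express a transformation (e.g. a decarboxylation with dehydrogenation is
#' `c(C = -1, H = -2, O = -2)`).
#'
#' @param parent,product Formulas (strings or named counts).
#' @return A named integer vector of the non-zero per-element changes, in
#'   Hill order; a zero-length vector when the formulas are identical.
#' @export
#' @examples
#' formula_diff("C36H62O11", "C35H60O9")
formula_diff <- function(parent, product) {
  a <- as_formula(parent)
  b <- as_formula(product)
  syms <- union(names(a), names(b))
  d <- stats::setNames(integer(length(syms)), syms)
  d[names(b)] <- d[names(b)] + b
  d[names(a)] <- d[names(a)] - a
  canonical_formula(d)
}

# add a signed delta to a formula; may produce negative counts (caller checks)
apply_delta <- function(f, delta) {
  f <- as_formula(f)
  syms <- union(names(f), names(delta))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(f)] <- out[names(f)] + f
  out[names(delta)] <- out[names(delta)] + as.integer(delta)
  out
}

#' Split a sodiated formula string into neutral formula and adduct
#'
#' Printed TP tables often report the sodium adduct as part of the formula
#' ("C36H62O11Na"). This helper removes one Na and returns the neutral
#' molecule together with the `"+Na"` adduct species, so the text can be fed
#' into [adduct_mz()] directly.
#'
#' @param f Formula (string or named counts) containing at least one Na.
#'   A formula without Na is returned unchanged with adduct `NA`.
#' @return A list with elements `neutral` (named counts) and `adduct`
#'   (`"+Na"` or `NA_character_`).
#' @export
#' @examples
#' split_adduct_formula("C_36_H_62_O_11_Na")
split_adduct_formula <- function(f) {
  f <- as_formula(f)
  if (!"Na" %in% names(f))
    return(list(neutral = f, adduct = NA_character_))
  list(neutral = canonical_formula(apply_delta(f, c(Na = -1L))),
       adduct = "+Na")
}

#' Rings plus double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1, computed on the neutral formula; O and Na do
#' not contribute. Half-integer values are legitimate for even-electron
#' cation compositions.
#'
#' @param f Formula (string or named counts).
#' @return A (half-)integer RDBE value.
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  cnt <- function(s) if (s %in% names(f)) f[[s]] else 0L
  cnt("C") - cnt("H") / 2 + cnt("N") / 2 + 1
}
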
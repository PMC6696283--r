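# Adduct ion arithmetic for singly charged cations.

# supported adduct species: atoms attached to the neutral molecule
.adduct_atoms <- list(
  "+H"   = c(H = 1L),
  "+Na"  = c(Na = 1L),
  "+NH4" = c(N = 1L, H = 4L)
)

#' Supported adduct species
#'
#' @return Character vector of adduct names (`"+H"`, `"+Na"`, `"+NH4"`).
#'   All are singly charged cations: the stated atoms are added and one
#'   electron removed.
#' @export
adduct_species <- function() names(.adduct_atoms)

# accept "+Na", "Na", "[M+Na]+", "M+Na" spellings
normalize_adduct <- function(adduct) {
  if (!is.character(adduct) || length(adduct) != 1L || is.na(adduct))
    stop("adduct must be a single character string")
  a <- gsub("\\[|\\]|\\s", "", adduct)
  a <- sub("^M", "", a)
  a <- sub("\\+$", "", a)
  if (!startsWith(a, "+")) a <- paste0("+", a)
  if (!a %in% names(.adduct_atoms))
    stop("unsupported adduct species: ", sQuote(adduct),
         " (supported: ", paste(names(.adduct_atoms), collapse = ", "), ")")
  a
}

adduct_atom_mass <- function(adduct) {
  atoms <- .adduct_atoms[[normalize_adduct(adduct)]]
  sum(atoms * monoisotopic_masses()[names(atoms)])
}

#' m/z of an adduct ion
#'
#' Computes `(M + adduct atoms - electron) / z` for a singly charged cation
#' of the given neutral formula, the electron-corrected convention that
#' high-resolution instruments report.
#'
#' @param neutral Neutral molecular formula (string or named counts). If the
#'   formula carries a trailing Na (printed sodiated formulas), strip it
#'   first with [split_adduct_formula()].
#' @param adduct Adduct species: `"+H"`, `"+Na"` or `"+NH4"` (bracketed
#'   spellings like `"[M+Na]+"` are accepted).
#' @param charge Must be `1`; only singly charged cations are supported.
#' @return The theoretical m/z in Da per unit charge (full precision; round
#'   to 4 decimals for reporting).
#' @export
#' @examples
#' adduct_mz("C36H62O11", "+Na")   # monensin A sodium adduct
#' adduct_mz("C36H62O11", "+NH4")
adduct_mz <- function(neutral, adduct = "+Na", charge = 1L) {
  if (!identical(as.integer(charge), 1L))
    stop("only singly charged cations are supported (charge = 1)")
  (monoisotopic_mass(neutral) + adduct_atom_mass(adduct) - ELECTRON_MASS) / 1
}

#' Exact-mass spacing between two adduct species
#'
#' The signed mass difference of the adduct atoms; independent of the
#' neutral molecule, so paired adduct signals of one species are always
#' separated by this constant (e.g. [M+Na]+ vs [M+NH4]+ by 4.9554 Da).
#'
#' @param a1,a2 Adduct species names.
#' @return Signed difference `mass(a1 atoms) - mass(a2 atoms)` in Da.
#' @export
#' @examples
#' adduct_pair_delta("+Na", "+NH4")
adduct_pair_delta <- function(a1, a2) {
  adduct_atom_mass(a1) - adduct_atom_mass(a2)
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (Da). May be a vector.
#' @param theoretical Theoretical m/z (Da); must be positive. Recycled
#'   against `observed`.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
#' @examples
#' ppm_error(693.4205, 693.4184)
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}
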
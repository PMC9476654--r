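#' Physical constants and unit conversion
#'
#' All internal computation uses Hartree atomic units: energies in hartree,
#' lengths in bohr, masses in electron masses (m_e), time in atomic time
#' units, and hbar = 1. Conversion happens only at I/O boundaries.
#'
#' @name units
NULL

# CODATA-2018 conversion factors.
.vq_const <- list(
  hartree_cm1   = 219474.6313632,   # 1 hartree in cm^-1
  hartree_kcal  = 627.5094740631,   # 1 hartree in kcal/mol
  hartree_kj    = 2625.4996394799,  # 1 hartree in kJ/mol
  amu_me        = 1822.888486209,   # 1 amu in electron masses
  bohr_angstrom = 0.529177210903    # 1 bohr in Angstrom
)

# conversion factor of each registered energy unit to hartree
.vq_energy_units <- function() {
  c(hartree  = 1,
    cm1      = 1 / .vq_const$hartree_cm1,
    kcal_mol = 1 / .vq_const$hartree_kcal,
    kj_mol   = 1 / .vq_const$hartree_kj)
}

#' Convert an energy between registered units
#'
#' Registered units: `"hartree"`, `"cm1"` (wavenumbers), `"kcal_mol"`,
#' `"kj_mol"`. The conversion is exact (a single multiplication), so
#' round trips are identity to machine precision.
#'
#' @param value numeric vector of energies.
#' @param from,to unit names.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "cm1")     # 219474.63...
#' convert_energy(0.12, "kcal_mol", "cm1") # ~42 cm^-1
#' @export
convert_energy <- function(value, from, to) {
  reg <- .vq_energy_units()
  if (!from %in% names(reg)) stop("unknown energy unit: ", from)
  if (!to %in% names(reg)) stop("unknown energy unit: ", to)
  value * reg[[from]] / reg[[to]]
}

#' Convert a mass from amu to electron masses
#' @param amu mass in unified atomic mass units.
#' @return mass in m_e.
#' @export
amu_to_me <- function(amu) amu * .vq_const$amu_me

#' @rdname amu_to_me
#' @param me mass in electron masses.
#' @export
me_to_amu <- function(me) me / .vq_const$amu_me

#' Convert lengths between bohr and Angstrom
#' @param x numeric vector of lengths.
#' @export
bohr_to_angstrom <- function(x) x * .vq_const$bohr_angstrom

#' @rdname bohr_to_angstrom
#' @export
angstrom_to_bohr <- function(x) x / .vq_const$bohr_angstrom

# Isotope masses (amu). The usual light isotopes plus deuterium; values are
# the standard isotopic masses, converted to m_e with amu_to_me().
.vq_isotope_masses <- c(
  H = 1.007825, D = 2.014102, C = 12.0, O = 15.994915, N = 14.003074
)

#' Isotope mass lookup
#'
#' Returns the mass of an element symbol (isotope-resolved: `"D"` is
#' deuterium) in electron masses.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in m_e.
#' @export
element_mass <- function(element) {
  m <- .vq_isotope_masses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(amu_to_me(m))
}
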
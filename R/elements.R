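# Periodic data used by the valence/electron model and by fingerprinting.
# Weights are standard atomic weights (IUPAC 2021), quantised to 2 decimals
# before hashing; isotopes are not distinguished.

.element_data <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Fe", "Co", "Ni", "Cu", "Zn", "As", "Se", "Br", "Kr",
           "Ag", "Sn", "Te", "I", "Xe", "Pt", "Au", "Hg", "Pb", "*")
  num <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
           11, 12, 13, 14, 15, 16, 17, 18, 19, 20,
           26, 27, 28, 29, 30, 33, 34, 35, 36,
           47, 50, 52, 53, 54, 78, 79, 80, 82, 0)
  wt <- c(1.008, 4.003, 6.94, 9.012, 10.81, 12.011, 14.007, 15.999, 18.998,
          20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45,
          39.95, 39.098, 40.078, 55.845, 58.933, 58.693, 63.546, 65.38,
          74.922, 78.971, 79.904, 83.798, 107.868, 118.71, 127.60, 126.904,
          131.293, 195.084, 196.967, 200.592, 207.2, 0)
  data.frame(symbol = sym, number = num, weight = wt,
             stringsAsFactors = FALSE)
})

atomic_number <- function(element) {
  i <- match(element, .element_data$symbol)
  ifelse(is.na(i), 0L, .element_data$number[i])
}

atomic_weight <- function(element) {
  i <- match(element, .element_data$symbol)
  ifelse(is.na(i), 0, .element_data$weight[i])
}

# Valence electrons in the outermost shell (main-group elements).
.valence_electrons <- c(
  H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
  Si = 4, P = 5, S = 6, Cl = 7, As = 5, Se = 6, Br = 7, I = 7
)

# Number of orbitals available for bonding in the valence shell: period-2
# elements have s + 3p = 4; period >= 3 elements may expand into d
# orbitals (s + 3p + 5d = 9).
.bonding_orbitals <- c(
  H = 1, B = 4, C = 4, N = 4, O = 4, F = 4,
  Si = 9, P = 9, S = 9, Cl = 9, As = 9, Se = 9, Br = 9, I = 9
)

# Elements of the SMILES organic subset (may be written without brackets).
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Lowercase aromatic symbols accepted by the reader.
.aromatic_symbols <- c(b = "B", c = "C", n = "N", o = "O", p = "P",
                       s = "S", se = "Se", as = "As")

#' Allowed valencies for an element at a given formal charge
#'
#' The kit models a small table of chemically achievable valencies
#' (e.g. sulphur 2/4/6, phosphorus 3/5), shifted by formal charge for the
#' common organic ions. Elements outside the table (metals, noble gases)
#' return `NULL`, meaning any bond-order sum is accepted as-is and no
#' implicit hydrogens are inferred.
#'
#' @param element chemical symbol.
#' @param charge integer formal charge.
#' @return integer vector of allowed valencies in increasing order, or
#'   `NULL` for elements with no tabulated valence model.
#' @keywords internal
allowed_valences <- function(element, charge = 0L) {
  key <- paste0(element, "|", charge)
  v <- switch(
    key,
    "H|0" = 1L, "H|1" = 0L, "H|-1" = 0L,
    "B|0" = 3L, "B|-1" = 4L, "B|1" = 2L,
    "C|0" = 4L, "C|1" = 3L, "C|-1" = 3L,
    # neutral N may transiently be assigned 5 during parsing; the nitro
    # correction or a bonding-law error resolves it before validation.
    "N|0" = c(3L, 5L), "N|1" = 4L, "N|-1" = 2L,
    "O|0" = 2L, "O|1" = 3L, "O|-1" = 1L,
    "F|0" = 1L, "F|-1" = 0L,
    "P|0" = c(3L, 5L), "P|1" = 4L, "P|-1" = c(2L, 4L, 6L),
    "S|0" = c(2L, 4L, 6L), "S|1" = c(3L, 5L), "S|-1" = 1L,
    "Si|0" = 4L,
    "As|0" = c(3L, 5L), "As|1" = 4L,
    "Se|0" = c(2L, 4L, 6L), "Se|1" = c(3L, 5L), "Se|-1" = 1L,
    "Cl|0" = c(1L, 3L, 5L, 7L), "Cl|-1" = 0L,
    "Br|0" = c(1L, 3L, 5L, 7L), "Br|-1" = 0L,
    "I|0" = c(1L, 3L, 5L, 7L), "I|-1" = 0L,
    NULL
  )
  v
}

valence_electron_count <- function(element) {
  v <- .valence_electrons[element]
  ifelse(is.na(v), NA_real_, unname(v))
}

bonding_orbital_count <- function(element) {
  v <- .bonding_orbitals[element]
  ifelse(is.na(v), 9, unname(v))
}
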
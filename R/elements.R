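# Element tables shared across the package.

# Elements the parameter tables cover.  Anything else renders a molecule
# ineligible for prediction but does not prevent reading it.
ELEMENT_WHITELIST <- c("H", "B", "C", "N", "O", "P", "S", "Si",
                       "F", "Cl", "Br", "I")

HALOGENS <- c("F", "Cl", "Br", "I")

# Canonical element ordering inside neighbour strings: main-group centers
# first, halogens last.  Iodine is written "J" in neighbour strings.
NEIGHBOR_ELEMENT_ORDER <- c("B", "C", "N", "O", "P", "S", "Si",
                            "F", "Cl", "Br", "J")

# Symbols accepted when reading structures (superset of the whitelist so
# that e.g. a selenium compound can be read, flagged and reported).
KNOWN_ELEMENTS <- c(ELEMENT_WHITELIST,
                    "He", "Li", "Be", "Ne", "Na", "Mg", "Al", "Ar",
                    "K", "Ca", "Ti", "Cr", "Mn", "Fe", "Co", "Ni",
                    "Cu", "Zn", "As", "Se", "Sn", "Sb", "Te", "Hg", "Pb")

# Default valences used to materialise implicit hydrogens, keyed by
# "element" or "element<charge>" for charged variants.  For S and P a
# vector of admissible valences is given; the smallest one that
# accommodates the explicit bond order sum is used.
VALENCE_MODEL <- list(
  "H"  = 1,
  "B"  = 3, "B-1" = 4,
  "C"  = 4, "C+1" = 3, "C-1" = 3,
  "N"  = 3, "N+1" = 4, "N-1" = 2,
  "O"  = 2, "O+1" = 3, "O-1" = 1,
  "P"  = c(3, 5), "P+1" = 4, "P-1" = 6,
  "S"  = c(2, 4, 6), "S+1" = 3, "S-1" = 1,
  "Si" = 4,
  "F"  = 1, "Cl" = 1, "Br" = 1, "I" = 1,
  "F-1" = 0, "Cl-1" = 0, "Br-1" = 0, "I-1" = 0
)

# Closed vocabulary of atom-type labels occurring in the published
# parameter tables (used by perceive(strict = TRUE)).
KNOWN_ATOM_TYPES <- c(
  "B(-)",
  "C sp3", "C sp2", "C sp", "C aromatic", "C(+) aromatic",
  "N sp3", "N sp2", "N aromatic",
  "N(+) sp3", "N(+) sp2", "N(+) aromatic", "N(-)",
  "O", "P4", "P(+)", "P(-)", "S2", "S4", "Si"
)

element_valence <- function(element, charge) {
  key <- if (charge == 0L) element else sprintf("%s%+d", element, charge)
  v <- VALENCE_MODEL[[key]]
  if (is.null(v)) v <- VALENCE_MODEL[[element]]
  v
}
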
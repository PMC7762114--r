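## Physical constants (SI) and element data used across the package.
## Internal coordinate units are Angstrom, times are ns, masses amu,
## energies kJ/mol, temperatures K.

.kB <- 1.380649e-23        # J/K
.hbar <- 1.054571817e-34   # J s
.amu <- 1.66053906660e-27  # kg
.R_kcal <- 1.9872e-3       # gas constant, kcal/(mol K); converts S/kB to kcal/(mol K)
.A2m <- 1e-10              # Angstrom -> m

## element -> (mass amu, atomic number)
.elements <- data.frame(
  element = c("H", "C", "N", "O", "P", "S", "Na", "K", "Cl"),
  mass = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 22.990, 39.098, 35.453),
  anum = c(1L, 6L, 7L, 8L, 15L, 16L, 11L, 19L, 17L),
  stringsAsFactors = FALSE
)

elementMass <- function(element) {
  i <- match(element, .elements$element)
  if (anyNA(i)) stop("unknown element(s): ", paste(unique(element[is.na(i)]), collapse = ", "))
  .elements$mass[i]
}

elementNumber <- function(element) {
  i <- match(element, .elements$element)
  if (anyNA(i)) stop("unknown element(s): ", paste(unique(element[is.na(i)]), collapse = ", "))
  .elements$anum[i]
}

## Guess the element from a PDB atom name (first alphabetic character,
## two-letter ions recognised explicitly).
elementFromName <- function(name, resname = NULL) {
  nm <- toupper(trimws(name))
  out <- character(length(nm))
  out[nm %in% c("NA", "SOD")] <- "Na"
  out[nm %in% c("K", "POT")] <- "K"
  out[nm %in% c("CL", "CLA")] <- "Cl"
  rest <- out == ""
  first <- substr(gsub("[^A-Z]", "", nm[rest]), 1, 1)
  map <- c(H = "H", C = "C", N = "N", O = "O", P = "P", S = "S")
  out[rest] <- unname(map[first])
  if (anyNA(out) || any(out == "")) {
    bad <- unique(name[is.na(out) | out == ""])
    stop("cannot infer element for atom name(s): ", paste(bad, collapse = ", "))
  }
  out
}
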
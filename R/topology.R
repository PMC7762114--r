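#' Static description of a simulated system
#'
#' A `Topology` holds the per-atom static information needed by every
#' analysis: identity (name, element, residue, molecule), masses and atomic
#' numbers, the hydrogen-to-heavy-atom bond list, and the interaction-typing
#' flags (H-bond donor/acceptor, hydrophobic, formal charge class).
#'
#' @param atoms data.frame with columns `eleno`, `name`, `element`, `mass`,
#'   `anum`, `resname`, `resno`, `mol`, `chain`, `kind`, `donor`, `acceptor`,
#'   `hydrophobic`, `charge`, `leaflet`.
#' @param bonds two-column integer matrix (columns `h`, `heavy`): covalent
#'   bonds of hydrogens to their parent heavy atom (0-row matrix allowed).
#'
#' @return An object of class `Topology`.
#' @export
Topology <- function(atoms, bonds = matrix(integer(0), 0, 2)) {
  required <- c("eleno", "name", "element", "mass", "anum", "resname",
                "resno", "mol", "chain", "kind", "donor", "acceptor",
                "hydrophobic", "charge", "leaflet")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) stop("atoms is missing column(s): ", paste(missing, collapse = ", "))
  if (any(atoms$mass <= 0)) stop("all atomic masses must be > 0")
  bonds <- matrix(as.integer(bonds), ncol = 2,
                  dimnames = list(NULL, c("h", "heavy")))
  hyd <- which(atoms$element == "H")
  nb <- tabulate(bonds[, 1], nbins = nrow(atoms))
  if (length(hyd) && any(nb[hyd] != 1L))
    stop("every hydrogen must be bonded to exactly one heavy atom")
  if (nrow(bonds) && any(atoms$element[bonds[, 2]] == "H"))
    stop("bond targets must be heavy atoms")
  structure(list(atoms = atoms, bonds = bonds), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  a <- x$atoms
  cat("Topology:", nrow(a), "atoms,", length(unique(a$mol)), "molecules\n")
  tab <- table(a$kind[!duplicated(a$mol)])
  cat("  molecules:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  donors:", sum(a$donor), " acceptors:", sum(a$acceptor),
      " hydrophobic:", sum(a$hydrophobic),
      " charged:", sum(a$charge != 0), "\n")
  invisible(x)
}

#' @export
nAtoms <- function(x) UseMethod("nAtoms")

#' @export
nAtoms.Topology <- function(x) nrow(x$atoms)

#' Atom interaction-typing tables
#'
#' Returns the table that drives donor/acceptor/hydrophobic/charge
#' classification. The default is shipped as editable JSON in
#' `inst/extdata/atom_typing.json`; pass `path` to load a modified copy.
#'
#' Classification rules:
#' * kind: residue name mapped to lipid / protein / water / ion;
#' * donor: any N or O with a covalently bonded hydrogen;
#' * acceptor: oxygens of listed residues plus nitrogens explicitly listed
#'   (quaternary / protonated amine nitrogens are excluded);
#' * hydrophobic: carbons listed per residue (carbons with no covalent bond
#'   to N, O or P: lipid acyl-tail carbons, apolar side-chain carbons);
#' * charge: formal charge class from residue templates (one representative
#'   atom per charged group).
#'
#' @param path optional path to a JSON typing table.
#' @return A list with components `residue_kind`, `acceptor_n`,
#'   `nonacceptor_o`, `hydrophobic`, `charge`.
#' @export
atomTypingTables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atom_typing.json", package = "memdyn")
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Classify atoms for interaction detection
#'
#' Applies the typing tables to an atom table: molecule kind, H-bond
#' donor/acceptor flags, hydrophobic flag and formal charge class.
#' Unknown residues are classified all-neutral/non-donor with a warning.
#'
#' @param atoms atom data.frame (needs `name`, `element`, `resname`).
#' @param bonds hydrogen-to-heavy bond matrix (columns h, heavy).
#' @param tables typing tables from [atomTypingTables()].
#' @return The atom data.frame with columns `kind`, `donor`, `acceptor`,
#'   `hydrophobic`, `charge` filled in.
#' @export
classifyAtoms <- function(atoms, bonds, tables = atomTypingTables()) {
  n <- nrow(atoms)
  res <- toupper(atoms$resname)
  kind <- rep(NA_character_, n)
  for (k in names(tables$residue_kind))
    kind[res %in% tables$residue_kind[[k]]] <- k
  kind[is.na(kind) & res %in% .aa3] <- "protein"
  unknown <- unique(res[is.na(kind)])
  if (length(unknown)) {
    warning("unknown residue(s) classified neutral/non-donor: ",
            paste(unknown, collapse = ", "))
    kind[is.na(kind)] <- "other"
  }
  atoms$kind <- kind

  ## donors: N/O heavy parents of bonded hydrogens
  donor <- rep(FALSE, n)
  if (nrow(bonds)) {
    heavy <- bonds[, 2]
    donor[heavy[atoms$element[heavy] %in% c("N", "O")]] <- TRUE
  }
  atoms$donor <- donor & kind != "other"

  ## acceptors: all O except listed exclusions; N only if listed
  key <- paste(res, toupper(atoms$name))
  acceptor <- atoms$element == "O" & !(key %in% tables$nonacceptor_o)
  acceptor <- acceptor | (atoms$element == "N" & key %in% tables$acceptor_n)
  atoms$acceptor <- acceptor & kind != "other"

  ## hydrophobic carbons, from per-residue name patterns
  hydro <- rep(FALSE, n)
  for (i in seq_along(tables$hydrophobic)) {
    rn <- names(tables$hydrophobic)[i]
    pat <- tables$hydrophobic[[i]]
    hit <- if (rn == "*") rep(TRUE, n) else res == rn
    hydro[hit & atoms$element == "C" &
            grepl(pat, toupper(atoms$name))] <- TRUE
  }
  atoms$hydrophobic <- hydro

  ## formal charge class: one representative atom per charged group
  charge <- rep(0L, n)
  for (i in seq_along(tables$charge)) {
    z <- tables$charge[[i]]
    hit <- (z$resname == "*" | res == z$resname) & toupper(atoms$name) %in% z$atoms
    if (!is.null(z$element)) hit <- hit & atoms$element == z$element
    charge[hit] <- as.integer(z$charge)
  }
  charge[kind == "other"] <- 0L
  atoms$charge <- charge
  atoms
}

#' Infer hydrogen-to-heavy-atom bonds from geometry
#'
#' Each hydrogen is bonded to the nearest heavy atom of the same residue
#' within `cutoff` (default 1.35 Angstrom).
#'
#' @param atoms atom data.frame (needs `element`, `mol`, `resno`).
#' @param xyz n x 3 coordinate matrix (Angstrom) of one frame.
#' @param cutoff maximum H-heavy covalent distance, Angstrom.
#' @return two-column integer matrix (h, heavy).
#' @export
inferHBonding <- function(atoms, xyz, cutoff = 1.35) {
  hyd <- which(atoms$element == "H")
  if (!length(hyd)) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("h", "heavy"))))
  out <- matrix(NA_integer_, length(hyd), 2)
  resid <- paste(atoms$mol, atoms$resno)
  for (i in seq_along(hyd)) {
    h <- hyd[i]
    cand <- which(resid == resid[h] & atoms$element != "H")
    if (!length(cand)) next
    d2 <- colSums((t(xyz[cand, , drop = FALSE]) - xyz[h, ])^2)
    j <- which.min(d2)
    if (d2[j] <= cutoff^2) out[i, ] <- c(h, cand[j])
  }
  if (anyNA(out[, 1] + out[, 2]))
    stop("hydrogen(s) with no heavy atom within ", cutoff, " Angstrom")
  dimnames(out) <- list(NULL, c("h", "heavy"))
  out
}
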
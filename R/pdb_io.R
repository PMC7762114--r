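#' Read a multi-model PDB file as topology + trajectory
#'
#' Parses MODEL/ENDMDL frames (via `bio3d::read.pdb`) and the CRYST1 record
#' into a [Topology] and a [Trajectory]. Atom typing (donor/acceptor/
#' hydrophobic/charge, molecule kind) is inferred from residue and atom
#' names through the editable tables of [atomTypingTables()]; hydrogens are
#' associated to their heavy parents by distance in the first frame.
#'
#' Molecule grouping: protein atoms form one molecule per chain; every
#' other residue (lipid, water, ion) is its own molecule.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ns used to build frame times (PDB carries no
#'   time axis); default 1 ns.
#' @param tables typing tables, see [atomTypingTables()].
#' @return `list(topology = Topology, trajectory = Trajectory)`.
#' @export
readMultimodelPDB <- function(path, dt = 1, tables = atomTypingTables()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ## per-model atom counts must agree
  model_breaks <- cumsum(grepl("^MODEL", lines))
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (any(model_breaks > 0)) {
    counts <- table(model_breaks[is_atom & model_breaks > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("atom-count mismatch across MODEL records")
  }
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- NULL
  if (length(cryst)) {
    v <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
    if (!anyNA(v) && all(v > 0)) box <- v
  } else {
    warning("no CRYST1 record: box unset")
  }

  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  nf <- nrow(p$xyz)
  n <- nrow(at)
  coords <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(p$xyz[f, ], ncol = 3, byrow = TRUE)

  element <- at$elesy
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- elementFromName(at$elety[bad])
  ## normalise two-letter ions that bio3d upper-cases
  element[element %in% c("NA")] <- "Na"
  element[element %in% c("CL")] <- "Cl"

  atoms <- data.frame(
    eleno = at$eleno, name = at$elety, element = element,
    mass = elementMass(element), anum = elementNumber(element),
    resname = at$resid, resno = at$resno,
    mol = NA_integer_,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    kind = NA_character_, donor = FALSE, acceptor = FALSE,
    hydrophobic = FALSE, charge = 0L, leaflet = NA_character_,
    stringsAsFactors = FALSE)

  is_protein <- toupper(atoms$resname) %in% .aa3
  grp <- ifelse(is_protein,
                paste0("P:", atoms$chain),
                paste0("R:", atoms$chain, ":", atoms$resno, ":", atoms$resname))
  atoms$mol <- as.integer(factor(grp, levels = unique(grp)))

  bonds <- inferHBonding(atoms, coords[, , 1])
  atoms <- classifyAtoms(atoms, bonds, tables)
  topology <- Topology(atoms, bonds)
  trajectory <- Trajectory(coords, times = dt * (seq_len(nf) - 1), box = box)
  list(topology = topology, trajectory = trajectory)
}

#' Write a topology + trajectory as a multi-model PDB file
#'
#' Emits one CRYST1 record (first-frame box) and one MODEL/ENDMDL block per
#' frame, PDB v3.3 fixed-width ATOM/HETATM records (protein atoms as ATOM,
#' everything else as HETATM), coordinates to 0.001 Angstrom.
#'
#' @param topology a [Topology].
#' @param trajectory a [Trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMultimodelPDB <- function(topology, trajectory, path) {
  a <- topology$atoms
  n <- nrow(a)
  stopifnot(dim(trajectory$coords)[1] == n)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trajectory$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       trajectory$box[1, 1], trajectory$box[1, 2],
                       trajectory$box[1, 3], 90, 90, 90), con)
  rectype <- ifelse(a$kind == "protein", "ATOM  ", "HETATM")
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  nm <- formatC(nm, width = -4)
  esy <- formatC(toupper(a$element), width = 2)
  serial <- a$eleno %% 100000L
  pre <- sprintf("%s%5d %s %-4s%1s%4d    ", rectype, serial, nm,
                 substr(a$resname, 1, 4), substr(a$chain, 1, 1),
                 a$resno %% 10000L)
  post <- sprintf("  1.00  0.00          %s", esy)
  nf <- nFrames(trajectory)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- trajectory$coords[, , f]
    writeLines(paste0(pre, sprintf("%8.3f%8.3f%8.3f", x[, 1], x[, 2], x[, 3]),
                      post), con)
    writeLines(c("ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
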
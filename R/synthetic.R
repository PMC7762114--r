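## Synthetic bilayer + protein systems with known ground truth.
##
## Lipid templates carry realistic atom counts and head-group naming
## (P, N, O13, O14, O22, C11, C12, acyl-tail carbons); geometry is a
## schematic head-up/tails-down chain - only atom typing and coarse
## placement matter for the analyses, not chemistry.

## heavy-atom rows: name, element, nh (bonded hydrogens), x, y, z offsets
.templateHeavy <- function(template, minimal_k = 10) {
  tail_z <- function(n, z0, dz) z0 - dz * (seq_len(n) - 1)
  if (template == "DPPC") {
    sn2 <- 15; sn1 <- 15   # C22..C216, C32..C316
    h <- rbind(
      data.frame(name = "N", element = "N", nh = 0, x = 0, y = 1.8, z = 7.4),
      data.frame(name = c("C13", "C14", "C15"), element = "C", nh = 3,
                 x = c(1.0, -1.0, 0), y = c(2.4, 2.4, 3.2), z = c(7.8, 7.8, 7.0)),
      data.frame(name = c("C12", "C11"), element = "C", nh = 2,
                 x = c(0.4, 0.3), y = c(1.2, 0.6), z = c(7.9, 7.3)),
      data.frame(name = "O12", element = "O", nh = 0, x = 0, y = 0, z = 6.9),
      data.frame(name = "P", element = "P", nh = 0, x = 0, y = 0, z = 6.3),
      data.frame(name = c("O11", "O13", "O14"), element = "O", nh = 0,
                 x = c(-0.9, -0.8, -0.8), y = c(0, 0.6, -0.6),
                 z = c(5.9, 6.5, 6.5)),
      data.frame(name = c("C1", "C2", "C3"), element = "C", nh = c(2, 1, 2),
                 x = c(0.5, 0, 0.6), y = c(0, 0.3, -0.3), z = c(4.8, 4.0, 3.2)),
      data.frame(name = c("O21", "C21", "O22"), element = c("O", "C", "O"),
                 nh = 0, x = c(1.2, 1.8, 2.2), y = c(1.1, 0.6, 1.2),
                 z = c(3.6, 2.9, 3.4)),
      data.frame(name = paste0("C2", 2:(sn2 + 1)), element = "C",
                 nh = c(rep(2, sn2 - 1), 3),
                 x = 1.8, y = 0.6, z = tail_z(sn2, 2.0, 0.9)),
      data.frame(name = c("O31", "C31", "O32"), element = c("O", "C", "O"),
                 nh = 0, x = c(0.2, 0.6, 1.2), y = c(-0.9, -1.2, -1.8),
                 z = c(2.6, 1.9, 2.2)),
      data.frame(name = paste0("C3", 2:(sn1 + 1)), element = "C",
                 nh = c(rep(2, sn1 - 1), 3),
                 x = 0.6, y = -1.2, z = tail_z(sn1, 1.0, 0.9)))
    resname <- "DPP"
  } else if (template == "POPE") {
    sn2 <- 17; sn1 <- 15   # C22..C218 (oleoyl), C32..C316 (palmitoyl)
    nh2 <- c(rep(2, 7), 1, 1, rep(2, 7), 3)  # C29=C210 double bond
    h <- rbind(
      data.frame(name = "N", element = "N", nh = 3, x = 0, y = 1.5, z = 7.6),
      data.frame(name = c("C12", "C11"), element = "C", nh = 2,
                 x = c(0.5, 0.3), y = c(0.7, 0.6), z = c(8.3, 7.3)),
      data.frame(name = "O12", element = "O", nh = 0, x = 0, y = 0, z = 6.9),
      data.frame(name = "P", element = "P", nh = 0, x = 0, y = 0, z = 6.3),
      data.frame(name = c("O11", "O13", "O14"), element = "O", nh = 0,
                 x = c(-0.9, -0.8, -0.8), y = c(0, 0.6, -0.6),
                 z = c(5.9, 6.5, 6.5)),
      data.frame(name = c("C1", "C2", "C3"), element = "C", nh = c(2, 1, 2),
                 x = c(0.5, 0, 0.6), y = c(0, 0.3, -0.3), z = c(4.8, 4.0, 3.2)),
      data.frame(name = c("O21", "C21", "O22"), element = c("O", "C", "O"),
                 nh = 0, x = c(1.2, 1.8, 2.2), y = c(1.1, 0.6, 1.2),
                 z = c(3.6, 2.9, 3.4)),
      data.frame(name = paste0("C2", 2:(sn2 + 1)), element = "C", nh = nh2,
                 x = 1.8, y = 0.6, z = tail_z(sn2, 2.0, 0.8)),
      data.frame(name = c("O31", "C31", "O32"), element = c("O", "C", "O"),
                 nh = 0, x = c(0.2, 0.6, 1.2), y = c(-0.9, -1.2, -1.8),
                 z = c(2.6, 1.9, 2.2)),
      data.frame(name = paste0("C3", 2:(sn1 + 1)), element = "C",
                 nh = c(rep(2, sn1 - 1), 3),
                 x = 0.6, y = -1.2, z = tail_z(sn1, 1.0, 0.9)))
    resname <- "POP"
  } else if (template == "minimal") {
    k <- minimal_k
    if (k < 7) stop("minimal lipid template needs at least 7 atoms")
    h <- rbind(
      data.frame(name = c("P", "N", "O13", "O14", "O22", "C11", "C12"),
                 element = c("P", "N", "O", "O", "O", "C", "C"), nh = 0,
                 x = c(0, 0.8, -0.8, -0.8, 1.2, 0.3, 0.9),
                 y = c(0, 0.4, 0.6, -0.6, 0.8, -0.8, 0.2),
                 z = c(6.3, 9.0, 6.6, 6.6, 3.4, 7.8, 8.5)))
    extra <- k - 7
    if (extra > 0)
      h <- rbind(h, data.frame(name = paste0("C2", 1 + seq_len(extra)),
                               element = "C", nh = 0, x = 1.8, y = 0.6,
                               z = 2.0 - 0.9 * (seq_len(extra) - 1)))
    resname <- "LIP"
  } else stop("unknown lipid template: ", template)
  list(heavy = h, resname = resname)
}

## full template: heavy atoms + hydrogens, local bond list
.lipidTemplate <- function(template, minimal_k = 10) {
  tp <- .templateHeavy(template, minimal_k)
  h <- tp$heavy
  hdir <- matrix(c(0.63, 0, 0.2, -0.63, 0, 0.2, 0, 0.63, -0.2), 3, 3,
                 byrow = TRUE)
  atoms <- data.frame(name = h$name, element = h$element,
                      x = h$x, y = h$y, z = h$z, stringsAsFactors = FALSE)
  bonds <- matrix(integer(0), 0, 2)
  hn <- 0L
  for (i in seq_len(nrow(h))) {
    if (h$nh[i] == 0) next
    for (r in seq_len(h$nh[i])) {
      hn <- hn + 1L
      atoms <- rbind(atoms, data.frame(
        name = paste0("H", hn), element = "H",
        x = h$x[i] + hdir[((r - 1) %% 3) + 1, 1] * (1 + 0.05 * (r > 3)),
        y = h$y[i] + hdir[((r - 1) %% 3) + 1, 2],
        z = h$z[i] + hdir[((r - 1) %% 3) + 1, 3] * (1 + 0.3 * ((r - 1) %/% 3)),
        stringsAsFactors = FALSE))
      bonds <- rbind(bonds, c(nrow(atoms), i))
    }
  }
  list(atoms = atoms, bonds = bonds, resname = tp$resname)
}

## coarse amino-acid clusters: name, element, nh, offsets (residue frame)
.residueTemplate <- function(res) {
  bb <- data.frame(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                   nh = c(1, 1, 0, 0),
                   x = c(0, 1.2, 2.2, 2.4), y = c(0, 0.6, 0, 0.9),
                   z = c(0, 0, 0.5, 1.4))
  side <- switch(toupper(res),
    LYS = data.frame(name = c("CB", "CG", "CD", "CE", "NZ"), element = c(rep("C", 4), "N"),
                     nh = c(0, 0, 0, 0, 3),
                     x = 1.2, y = 0.6, z = -(1:5) * 1.2),
    PHE = data.frame(name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                     element = "C", nh = 0,
                     x = c(1.2, 1.2, 0.4, 2.0, 0.4, 2.0, 1.2),
                     y = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
                     z = c(-1.2, -2.4, -3.1, -3.1, -4.3, -4.3, -5.0)),
    TRP = data.frame(name = c("CB", "CG", "CD1", "NE1", "CE2", "CZ2"),
                     element = c("C", "C", "C", "N", "C", "C"),
                     nh = c(0, 0, 0, 1, 0, 0),
                     x = c(1.2, 1.2, 0.4, 0.8, 1.8, 2.2),
                     y = 0.6, z = -(1:6) * 1.0),
    LEU = data.frame(name = c("CB", "CG", "CD1", "CD2"), element = "C", nh = 0,
                     x = c(1.2, 1.2, 0.5, 1.9), y = 0.6, z = c(-1.2, -2.4, -3.3, -3.3)),
    SER = data.frame(name = c("CB", "OG"), element = c("C", "O"), nh = c(0, 1),
                     x = 1.2, y = 0.6, z = c(-1.2, -2.3)),
    THR = data.frame(name = c("CB", "OG1", "CG2"), element = c("C", "O", "C"),
                     nh = c(0, 1, 0),
                     x = c(1.2, 0.5, 1.9), y = 0.6, z = c(-1.2, -2.2, -2.2)),
    TYR = data.frame(name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
                     element = c(rep("C", 7), "O"), nh = c(rep(0, 7), 1),
                     x = c(1.2, 1.2, 0.4, 2.0, 0.4, 2.0, 1.2, 1.2),
                     y = 0.6,
                     z = c(-1.2, -2.4, -3.1, -3.1, -4.3, -4.3, -5.0, -6.1)),
    ASP = data.frame(name = c("CB", "CG", "OD1", "OD2"),
                     element = c("C", "C", "O", "O"), nh = 0,
                     x = c(1.2, 1.2, 0.5, 1.9), y = 0.6, z = c(-1.2, -2.4, -3.2, -3.2)),
    ALA = data.frame(name = "CB", element = "C", nh = 0, x = 1.2, y = 0.6, z = -1.2),
    GLY = NULL,
    stop("unsupported residue: ", res))
  rbind(bb, side)
}

#' Specification of a synthetic bilayer + protein system
#'
#' Defaults reproduce the reference study conditions: 144 lipids per
#' leaflet (288 total), DPPC-like 130-atom lipids, a 95 x 86 x 196
#' Angstrom box, 1000 frames saved every 0.05 ns (20 frames/ns, 50 ns
#' total), and fractional-Brownian lipid-center motion with per-leaflet
#' `(alpha, D)` such that the ensemble MSD is `6 D t^alpha`.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (default 144).
#' @param lipid_template `"DPPC"` (130 atoms), `"POPE"` (125) or
#'   `"minimal"` (`minimal_k` atoms, no hydrogens).
#' @param minimal_k atom count of the minimal template (>= 7).
#' @param leaflet_alpha named vector `c(upper=, lower=)` of anomalous
#'   exponents (0 < alpha <= 2).
#' @param leaflet_D named vector of generalized diffusion coefficients,
#'   Angstrom^2/ns^alpha (>= 0).
#' @param internal_covariance intramolecular Gaussian fluctuation
#'   covariance across template atoms, Angstrom^2: `NULL` (none), a
#'   scalar (isotropic diagonal) or a symmetric PSD matrix.
#' @param n_frames number of frames (>= 2; default 1000).
#' @param frame_interval time between frames, ns (default 0.05).
#' @param box `c(Lx, Ly, Lz)`, Angstrom.
#' @param rng_seed integer seed; same seed gives a bit-identical system.
#' @param head_to_head distance between leaflet head planes, Angstrom.
#' @param protein include the coarse protein chain (default TRUE).
#' @param protein_residues residue names of the coarse protein.
#' @param protein_resno_start first residue number (default 244).
#' @param protein_gap z gap between the contact head plane and the lowest
#'   protein atom, Angstrom.
#' @param n_waters number of water molecules.
#' @param n_ions `c(cations, anions)`.
#' @param wrap wrap molecules into the box (whole-molecule wrapping).
#' @return A `SyntheticSpec` list.
#' @export
syntheticSpec <- function(n_lipids_per_leaflet = 144,
                          lipid_template = c("DPPC", "POPE", "minimal"),
                          minimal_k = 10,
                          leaflet_alpha = c(upper = 1, lower = 1),
                          leaflet_D = c(upper = 1, lower = 1),
                          internal_covariance = NULL,
                          n_frames = 1000, frame_interval = 0.05,
                          box = c(95, 86, 196), rng_seed = 1,
                          head_to_head = 40,
                          protein = TRUE,
                          protein_residues = c("LYS", "PHE", "TRP", "LEU", "SER",
                                               "THR", "TYR", "ASP", "ALA", "GLY"),
                          protein_resno_start = 244,
                          protein_gap = 6,
                          n_waters = 60, n_ions = c(6, 6),
                          wrap = FALSE) {
  lipid_template <- match.arg(lipid_template)
  stopifnot(n_frames >= 2, all(leaflet_alpha > 0), all(leaflet_alpha <= 2),
            all(leaflet_D >= 0), all(box > 0), frame_interval > 0,
            n_lipids_per_leaflet >= 1)
  for (nm in c("upper", "lower")) {
    if (!nm %in% names(leaflet_alpha)) stop("leaflet_alpha needs '", nm, "'")
    if (!nm %in% names(leaflet_D)) stop("leaflet_D needs '", nm, "'")
  }
  if (!is.null(internal_covariance) && !is.matrix(internal_covariance) &&
      length(internal_covariance) != 1)
    stop("internal_covariance must be NULL, a scalar or a matrix")
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 lipid_template = lipid_template, minimal_k = minimal_k,
                 leaflet_alpha = leaflet_alpha, leaflet_D = leaflet_D,
                 internal_covariance = internal_covariance,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, box = box,
                 rng_seed = as.integer(rng_seed),
                 head_to_head = head_to_head, protein = protein,
                 protein_residues = protein_residues,
                 protein_resno_start = protein_resno_start,
                 protein_gap = protein_gap,
                 n_waters = n_waters, n_ions = n_ions, wrap = wrap),
            class = "SyntheticSpec")
}

#' Build the topology (and base coordinates) of a synthetic system
#'
#' Two planar leaflets of template lipids on a jittered lateral grid,
#' heads outward; an optional coarse protein chain above the upper
#' leaflet; waters and monovalent ions in the solvent slabs. The base
#' coordinates used by [generateTrajectory()] are stored in the
#' `"base_coords"` attribute.
#'
#' @param spec a [syntheticSpec()].
#' @return A [Topology] (lipid `leaflet` column prefilled upper/lower).
#' @export
generateTopology <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$rng_seed)
  tpl <- .lipidTemplate(spec$lipid_template, spec$minimal_k)
  nt <- nrow(tpl$atoms)
  n <- spec$n_lipids_per_leaflet
  zmid <- spec$box[3] / 2
  p_off <- tpl$atoms$z[tpl$atoms$name == "P"]

  nside <- ceiling(sqrt(n))
  sx <- spec$box[1] / nside
  sy <- spec$box[2] / nside
  gx <- (rep(seq_len(nside), nside)[seq_len(n)] - 0.5) * sx
  gy <- (rep(seq_len(nside), each = nside)[seq_len(n)] - 0.5) * sy

  rows <- list(); bonds <- list(); base <- list()
  mol <- 0L
  addMol <- function(df, xyz, bnd, kind_chain, resname, resno, leaflet = NA) {
    mol <<- mol + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      name = df$name, element = df$element, resname = resname,
      resno = resno, mol = mol, chain = kind_chain, leaflet = leaflet,
      stringsAsFactors = FALSE)
    base[[length(base) + 1L]] <<- xyz
    if (nrow(bnd)) {
      off <- sum(vapply(rows[seq_len(length(rows) - 1)], nrow, 1L))
      bonds[[length(bonds) + 1L]] <<- bnd + off
    }
  }

  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    plane <- zmid + sgn * spec$head_to_head / 2
    for (i in seq_len(n)) {
      jx <- stats::runif(1, -0.3, 0.3) * sx / 2
      jy <- stats::runif(1, -0.3, 0.3) * sy / 2
      xyz <- cbind(tpl$atoms$x + gx[i] + jx,
                   tpl$atoms$y + gy[i] + jy,
                   sgn * tpl$atoms$z + (plane - sgn * p_off))
      addMol(tpl$atoms, xyz, tpl$bonds, "L", tpl$resname,
             resno = i + if (leaf == "lower") n else 0L, leaflet = leaf)
    }
  }

  upper_plane <- zmid + spec$head_to_head / 2
  if (spec$protein) {
    resno <- spec$protein_resno_start
    px <- spec$box[1] / 2 - 3.8 * length(spec$protein_residues) / 2
    first <- TRUE
    prot_rows <- list(); prot_xyz <- list(); prot_bonds <- list()
    off0 <- 0L
    for (r in spec$protein_residues) {
      rt <- .residueTemplate(r)
      xyz <- cbind(rt$x + px, rt$y + spec$box[2] / 2,
                   rt$z + upper_plane + spec$protein_gap + 6.5)
      hb <- matrix(integer(0), 0, 2)
      at <- rt[, c("name", "element")]
      hcount <- 0L
      nheavy <- nrow(rt)
      for (ii in seq_len(nheavy)) {
        if (rt$nh[ii] == 0) next
        ## choose hydrogen directions with maximal clearance from the other
        ## heavy atoms, so the nearest heavy atom of any H is its parent
        others <- xyz[setdiff(seq_len(nheavy), ii), , drop = FALSE]
        cand <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
        cand <- cand[rowSums(cand^2) > 0, ]
        cand <- cand / sqrt(rowSums(cand^2))
        pos <- sweep(0.95 * cand, 2, xyz[ii, ], "+")
        clearance <- apply(pos, 1, function(p)
          min(sqrt(colSums((t(others) - p)^2))))
        best <- order(clearance, decreasing = TRUE)
        for (hh in seq_len(rt$nh[ii])) {
          hcount <- hcount + 1L
          at <- rbind(at, data.frame(name = paste0("H", resno %% 10, hcount),
                                     element = "H"))
          xyz <- rbind(xyz, pos[best[hh], ])
          hb <- rbind(hb, c(nrow(xyz), ii))
        }
      }
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        name = at$name, element = at$element, resname = toupper(r),
        resno = resno, stringsAsFactors = FALSE)
      prot_xyz[[length(prot_xyz) + 1L]] <- xyz
      if (nrow(hb)) prot_bonds[[length(prot_bonds) + 1L]] <- hb + off0
      off0 <- off0 + nrow(xyz)
      resno <- resno + 1L
      px <- px + 3.8
      first <- FALSE
    }
    pr <- do.call(rbind, prot_rows)
    mol <- mol + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      name = pr$name, element = pr$element, resname = pr$resname,
      resno = pr$resno, mol = mol, chain = "P", leaflet = NA,
      stringsAsFactors = FALSE)
    base[[length(base) + 1L]] <- do.call(rbind, prot_xyz)
    if (length(prot_bonds)) {
      off <- sum(vapply(rows[seq_len(length(rows) - 1)], nrow, 1L))
      bonds[[length(bonds) + 1L]] <- do.call(rbind, prot_bonds) + off
    }
  }

  ## waters on a grid in the solvent slab above the protein region
  if (spec$n_waters > 0) {
    nwx <- ceiling(sqrt(spec$n_waters))
    wsp <- min(spec$box[1], spec$box[2]) / (nwx + 1)
    wz <- upper_plane + spec$protein_gap + 22
    watoms <- data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                         stringsAsFactors = FALSE)
    wb <- rbind(c(2L, 1L), c(3L, 1L))
    for (i in seq_len(spec$n_waters)) {
      ox <- ((i - 1) %% nwx + 1) * wsp
      oy <- ((i - 1) %/% nwx + 1) * wsp
      oz <- wz + 3 * ((i - 1) %/% (nwx * nwx))
      xyz <- rbind(c(ox, oy, oz), c(ox + 0.76, oy + 0.59, oz),
                   c(ox - 0.76, oy + 0.59, oz))
      addMol(watoms, xyz, wb, "W", "HOH", resno = i)
    }
  }

  ni <- spec$n_ions
  if (sum(ni) > 0) {
    iz <- upper_plane + spec$protein_gap + 18
    k <- 0L
    for (s in seq_len(ni[1])) {
      k <- k + 1L
      addMol(data.frame(name = "SOD", element = "Na"),
             rbind(c(3 + 5 * k, 3, iz)), matrix(integer(0), 0, 2), "I", "SOD",
             resno = k)
    }
    for (s in seq_len(ni[2])) {
      k <- k + 1L
      addMol(data.frame(name = "CLA", element = "Cl"),
             rbind(c(3 + 5 * k, 6, iz)), matrix(integer(0), 0, 2), "I", "CLA",
             resno = k)
    }
  }

  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, base)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$mass <- elementMass(atoms$element)
  atoms$anum <- elementNumber(atoms$element)
  atoms$kind <- NA_character_
  atoms$donor <- FALSE; atoms$acceptor <- FALSE
  atoms$hydrophobic <- FALSE; atoms$charge <- 0L
  b <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  atoms <- classifyAtoms(atoms, b)
  topo <- Topology(atoms, b)
  attr(topo, "base_coords") <- xyz
  ## generation-time leaflet labels survive later contact/noncontact
  ## relabeling by assignLeaflets()
  attr(topo, "gen_leaflet") <- atoms$leaflet
  attr(topo, "spec") <- spec
  topo
}

#' Exact fractional-Brownian-motion displacement paths
#'
#' Generates `n` independent 3D fBm displacement paths (zero at `times[1]`)
#' whose per-coordinate covariance is
#' `K(s, t) = D (s^a + t^a - |s - t|^a)`, so the ensemble MSD over the
#' three coordinates is exactly `6 D t^a`. Sampling is by Cholesky
#' factorization of the exact path covariance, so the target
#' autocovariance holds at any number of frames (no approximation).
#'
#' @param n number of molecules.
#' @param times frame times, ns (first frame is the origin).
#' @param alpha anomalous exponent (0 < alpha <= 2).
#' @param D generalized diffusion coefficient, Angstrom^2/ns^alpha.
#' @return array `n x 3 x length(times)` of displacements, Angstrom.
#' @export
fbmPaths <- function(n, times, alpha, D) {
  stopifnot(alpha > 0, alpha <= 2, D >= 0, length(times) >= 2)
  F <- length(times)
  out <- array(0, c(n, 3, F))
  if (D == 0) return(out)
  t <- times[-1] - times[1]
  K <- D * (outer(t, t, function(a, b) a^alpha + b^alpha - abs(a - b)^alpha))
  L <- chol(K + diag(1e-10 * max(K), length(t)))
  Z <- matrix(stats::rnorm(length(t) * n * 3), length(t), n * 3)
  X <- crossprod(L, Z)                 # (F-1) x (3n), exact covariance K
  out[, , -1] <- aperm(array(t(X), c(n, 3, F - 1)), c(1, 2, 3))
  out
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Lipid geometric centers follow independent 3D fractional Brownian
#' motion with the leaflet's `(alpha, D)` (ensemble MSD `6 D t^alpha`);
#' atom positions are center + template offset + optional zero-mean
#' Gaussian intramolecular fluctuation drawn (independently per frame and
#' axis) from `internal_covariance`. Hydrogens reuse their parent heavy
#' atom's fluctuation so covalent geometry survives the noise (the
#' covariance ground truth therefore applies to heavy atoms; hydrogen-free
#' templates realize it exactly). Protein, waters and ions are static.
#' Deterministic under `spec$rng_seed`.
#'
#' @param topology from [generateTopology()].
#' @param spec the same [syntheticSpec()].
#' @return A [Trajectory]; attribute `"ground_truth"` holds the planted
#'   per-leaflet `(alpha, D)` and the fluctuation covariance.
#' @export
generateTrajectory <- function(topology, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$rng_seed + 1L)
  base <- attr(topology, "base_coords")
  if (is.null(base)) stop("topology lacks base coordinates")
  a <- topology$atoms
  F <- spec$n_frames
  times <- (seq_len(F) - 1) * spec$frame_interval
  coords <- array(base, c(nrow(base), 3, F))

  ## covariance factor for intramolecular fluctuations
  Afact <- NULL
  nt <- sum(a$mol == a$mol[which(a$kind == "lipid")[1]])
  if (!is.null(spec$internal_covariance)) {
    S <- spec$internal_covariance
    if (length(S) == 1) S <- diag(as.numeric(S), nt)
    if (!all(dim(S) == nt))
      stop("internal_covariance must be ", nt, " x ", nt,
           " (the lipid template atom count)")
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop("internal_covariance must be symmetric")
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (any(es$values < -1e-8 * max(abs(es$values), 1)))
      stop("internal_covariance is not positive semi-definite")
    if (any(es$values > 0))
      Afact <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), nt)
  }

  gl <- attr(topology, "gen_leaflet")
  if (is.null(gl)) gl <- a$leaflet
  for (leaf in c("upper", "lower")) {
    lm <- unique(a$mol[a$kind == "lipid" & gl == leaf])
    if (!length(lm)) next
    disp <- fbmPaths(length(lm), times,
                     spec$leaflet_alpha[[leaf]], spec$leaflet_D[[leaf]])
    for (k in seq_along(lm)) {
      idx <- which(a$mol == lm[k])
      for (ax in 1:3)
        coords[idx, ax, ] <- coords[idx, ax, ] +
          matrix(disp[k, ax, ], length(idx), F, byrow = TRUE)
    }
    if (!is.null(Afact)) {
      ## hydrogens ride their parent heavy atom (same fluctuation draw),
      ## keeping covalent geometry intact under intramolecular noise
      idx1 <- which(a$mol == lm[1])
      brow <- topology$bonds[topology$bonds[, 1] %in% idx1, , drop = FALSE]
      hloc <- match(brow[, 1], idx1)
      ploc <- match(brow[, 2], idx1)
      for (k in seq_along(lm)) {
        idx <- which(a$mol == lm[k])
        eps <- Afact %*% matrix(stats::rnorm(nt * 3 * F), nt, 3 * F)
        if (length(hloc)) eps[hloc, ] <- eps[ploc, , drop = FALSE]
        coords[idx, , ] <- coords[idx, , ] + array(eps, c(nt, 3, F))
      }
    }
  }

  if (spec$wrap) {
    for (m in unique(a$mol)) {
      idx <- which(a$mol == m)
      for (f in seq_len(F)) {
        ctr <- colMeans(coords[idx, , f, drop = FALSE][, , 1, drop = TRUE])
        if (length(idx) == 1) ctr <- coords[idx, , f]
        shift <- floor(ctr / spec$box) * spec$box
        if (any(shift != 0))
          coords[idx, , f] <- coords[idx, , f] -
            matrix(shift, length(idx), 3, byrow = TRUE)
      }
    }
  }

  tr <- Trajectory(coords, times, box = spec$box)
  attr(tr, "ground_truth") <- list(leaflet_alpha = spec$leaflet_alpha,
                                   leaflet_D = spec$leaflet_D,
                                   internal_covariance = spec$internal_covariance)
  tr
}

#' Plant contacts with known detection outcome into a trajectory
#'
#' Adjusts the coordinates of selected atoms so that each requested
#' contact's geometry holds in every frame, strictly inside or outside the
#' detection thresholds. Returns the modified trajectory together with the
#' expected ground-truth detection counts per kind.
#'
#' Contact specification: a list with `kind` (`"hbond"`, `"hp"`,
#' `"ionic"`, `"water_bridge"`), atom selectors `a` and `b`
#' (`list(mol =, name =)`), for water bridges additionally `water`
#' (water molecule id), a `geometry` list (`d` = H..acceptor distance and
#' `theta` = donor angle for H-bonds; `d` = pair separation and optional
#' unit placement direction `dir` for hp/ionic), and `expected_detected`.
#'
#' Contacts whose construction would clash (moved atom within 0.5
#' Angstrom of an unrelated atom) are reported with a warning and
#' skipped.
#'
#' @param trajectory a [Trajectory].
#' @param topology the matching [Topology].
#' @param contacts list of contact specifications.
#' @return list: `trajectory` (modified), `expected` (named counts of
#'   contacts planted in-threshold), `skipped` (indices of skipped
#'   contacts).
#' @export
plantContacts <- function(trajectory, topology, contacts) {
  a <- topology$atoms
  coords <- trajectory$coords
  F <- nFrames(trajectory)
  expected <- c(hbond = 0L, hp = 0L, ionic = 0L, water_bridge = 0L)
  skipped <- integer(0)

  resolve <- function(sel) {
    i <- which(a$mol == sel$mol & a$name == sel$name)
    if (!length(i)) stop("selector does not resolve: mol ", sel$mol,
                         " atom ", sel$name)
    i[1]
  }
  clash <- function(idx_new, pos_new, exclude) {
    others <- setdiff(seq_len(nrow(a)), c(idx_new, exclude))
    if (!length(others)) return(FALSE)
    d2 <- colSums((t(coords[others, , 1]) - pos_new)^2)
    any(d2 < 0.25)
  }

  for (ci in seq_along(contacts)) {
    ct <- contacts[[ci]]
    g <- ct$geometry
    if (ct$kind == "hbond") {
      don <- resolve(ct$a); acc <- resolve(ct$b)
      hrow <- topology$bonds[topology$bonds[, 2] == don, , drop = FALSE]
      if (!nrow(hrow)) stop("hbond contact: atom ", a$name[don], " has no bonded H")
      h <- hrow[1, 1]
      th <- (if (is.null(g$theta)) 180 else g$theta) * pi / 180
      d <- if (is.null(g$d)) 2.0 else g$d
      ok <- TRUE
      for (f in seq_len(F)) {
        u <- coords[don, , f] - coords[h, , f]
        u <- u / sqrt(sum(u^2))
        w <- c(u[2], -u[1], 0)
        if (sum(w^2) < 1e-12) w <- c(1, 0, 0)
        w <- w - sum(w * u) * u
        w <- w / sqrt(sum(w^2))
        newpos <- coords[h, , f] + d * (cos(th) * u + sin(th) * w)
        if (f == 1 && clash(acc, newpos, c(don, h))) { ok <- FALSE; break }
        coords[acc, , f] <- newpos
      }
      if (!ok) { warning("contact ", ci, " skipped (clash)"); skipped <- c(skipped, ci); next }
      if (isTRUE(ct$expected_detected)) expected["hbond"] <- expected["hbond"] + 1L
    } else if (ct$kind %in% c("hp", "ionic")) {
      i1 <- resolve(ct$a); i2 <- resolve(ct$b)
      d <- if (is.null(g$d)) 4.0 else g$d
      dir <- if (is.null(g$dir)) c(0, 1, 0) else g$dir / sqrt(sum(g$dir^2))
      newpos <- t(coords[i1, , ] + d * dir)
      if (clash(i2, newpos[1, ], i1)) {
        warning("contact ", ci, " skipped (clash)"); skipped <- c(skipped, ci); next
      }
      coords[i2, , ] <- t(newpos)
      if (isTRUE(ct$expected_detected)) expected[ct$kind] <- expected[ct$kind] + 1L
    } else if (ct$kind == "water_bridge") {
      i1 <- resolve(ct$a); i2 <- resolve(ct$b)
      wmol <- which(a$mol == ct$water)
      if (!length(wmol)) stop("water molecule ", ct$water, " not found")
      wo <- wmol[a$element[wmol] == "O"][1]
      wh <- topology$bonds[topology$bonds[, 2] == wo, 1]
      if (length(wh) < 2) stop("water ", ct$water, " needs two hydrogens")
      d <- if (is.null(g$d)) 1.9 else g$d
      e1 <- c(0, 0, 1); e2 <- c(1, 0, 0)
      for (f in seq_len(F)) {
        o <- coords[i1, , f] + (d + 1.0) * e1
        coords[wo, , f] <- o
        coords[wh[1], , f] <- o - e1 * 1.0
        coords[wh[2], , f] <- o + e2 * 1.0
        coords[i2, , f] <- o + e2 * (d + 1.0)
      }
      if (isTRUE(ct$expected_detected))
        expected["water_bridge"] <- expected["water_bridge"] + 1L
    } else stop("unknown contact kind: ", ct$kind)
  }
  list(trajectory = Trajectory(coords, trajectory$times, trajectory$box),
       expected = expected, skipped = skipped)
}

#' Inject box-length jump artefacts
#'
#' From each listed frame onward, all atoms of one molecule are translated
#' by plus/minus one box length along one axis, mimicking the wrapping
#' artefact that [levelJumps()] repairs.
#'
#' @param trajectory a [Trajectory] with a known box.
#' @param topology the matching [Topology].
#' @param jumps list of `list(frame =, axis =, sign =, mol =)` (axis 1-3).
#' @return The modified [Trajectory].
#' @export
injectJumps <- function(trajectory, topology, jumps) {
  if (!length(jumps)) return(trajectory)
  if (is.null(trajectory$box)) stop("injectJumps requires a known box")
  coords <- trajectory$coords
  F <- nFrames(trajectory)
  for (j in jumps) {
    stopifnot(j$frame >= 1, j$frame <= F, j$axis %in% 1:3, j$sign %in% c(-1, 1))
    idx <- which(topology$atoms$mol == j$mol)
    if (!length(idx)) stop("molecule ", j$mol, " not found")
    L <- trajectory$box[j$frame, j$axis]
    coords[idx, j$axis, j$frame:F] <- coords[idx, j$axis, j$frame:F] + j$sign * L
  }
  Trajectory(coords, trajectory$times, trajectory$box)
}
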
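#' Interaction-detection parameters
#'
#' Defaults implement an energy H-bond criterion with a 25 kJ/mol optimum:
#' a donor-H...acceptor triple counts as hydrogen-bonded when its modeled
#' energy is strictly greater than `hb_threshold_fraction` (25%) of the
#' optimum, i.e. 6.25 kJ/mol. The energy is the product of a linear
#' distance ramp (full strength at H..acceptor distances up to
#' `hb_d_plateau` = 2.1 Angstrom, zero from `hb_d_zero` = 2.6 Angstrom) and
#' a linear donor-angle ramp (zero at `hb_angle_floor` = 100 degrees, full
#' at 180). Hydrophobic and ionic contacts use plain distance cutoffs
#' (5.0 Angstrom each by default).
#'
#' @param hb_optimal_energy optimum H-bond energy, kJ/mol.
#' @param hb_threshold_fraction fraction of the optimum defining the
#'   detection threshold (0 < f < 1).
#' @param hb_d_plateau,hb_d_zero distance ramp ends, Angstrom.
#' @param hb_angle_floor,hb_angle_span angle ramp: zero below floor
#'   (degrees), full strength at floor + span.
#' @param hp_cutoff hydrophobic-contact cutoff, Angstrom.
#' @param ionic_cutoff ionic-contact cutoff, Angstrom.
#' @return An object of class `InteractionParams`.
#' @export
interactionParams <- function(hb_optimal_energy = 25,
                              hb_threshold_fraction = 0.25,
                              hb_d_plateau = 2.1, hb_d_zero = 2.6,
                              hb_angle_floor = 100, hb_angle_span = 80,
                              hp_cutoff = 5.0, ionic_cutoff = 5.0) {
  stopifnot(hb_threshold_fraction > 0, hb_threshold_fraction < 1,
            hb_d_plateau < hb_d_zero, hp_cutoff > 0, ionic_cutoff > 0,
            hb_angle_span > 0)
  structure(list(hb_optimal_energy = hb_optimal_energy,
                 hb_threshold_fraction = hb_threshold_fraction,
                 hb_d_plateau = hb_d_plateau, hb_d_zero = hb_d_zero,
                 hb_angle_floor = hb_angle_floor,
                 hb_angle_span = hb_angle_span,
                 hp_cutoff = hp_cutoff, ionic_cutoff = ionic_cutoff),
            class = "InteractionParams")
}

#' H-bond detection threshold implied by the parameters
#' @param params an `InteractionParams` object.
#' @return threshold energy in kJ/mol (default 6.25).
#' @export
hbondThreshold <- function(params = interactionParams()) {
  params$hb_optimal_energy * params$hb_threshold_fraction
}

## vectorized energy from geometry: d = H..acceptor distance (Angstrom),
## theta = donor-H-acceptor angle (degrees)
.hbEnergy <- function(d, theta, params) {
  fd <- (params$hb_d_zero - pmax(d, params$hb_d_plateau)) /
    (params$hb_d_zero - params$hb_d_plateau)
  fd <- pmin(pmax(fd, 0), 1)
  fa <- pmin(pmax((theta - params$hb_angle_floor) / params$hb_angle_span, 0), 1)
  params$hb_optimal_energy * fd * fa
}

#' Hydrogen-bond energy of a donor-H-acceptor triple
#'
#' @param donor,hydrogen,acceptor length-3 coordinate vectors, Angstrom.
#' @param box optional length-3 box for minimum-image distances.
#' @param params an [interactionParams()] object.
#' @return energy in kJ/mol, in `[0, hb_optimal_energy]`.
#' @export
hbondEnergy <- function(donor, hydrogen, acceptor, box = NULL,
                        params = interactionParams()) {
  if (!all(is.finite(c(donor, hydrogen, acceptor))))
    stop("non-finite coordinates")
  vHD <- rbind(donor - hydrogen)
  vHA <- rbind(acceptor - hydrogen)
  if (!is.null(box)) {
    vHD <- .miVec(vHD, box)
    vHA <- .miVec(vHA, box)
  }
  d <- sqrt(sum(vHA^2))
  ct <- sum(vHD * vHA) / (sqrt(sum(vHD^2)) * d)
  theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  .hbEnergy(d, theta, params)
}

.emptyRecords <- function() {
  data.frame(kind = character(0), frame = integer(0),
             i = integer(0), j = integer(0), h = integer(0),
             water = integer(0), energy = numeric(0),
             mol_i = integer(0), mol_j = integer(0),
             name_i = character(0), name_j = character(0),
             resno_i = integer(0), resname_i = character(0),
             resno_j = integer(0), resname_j = character(0),
             scope = character(0), solvent_ion = logical(0),
             stringsAsFactors = FALSE)
}

.scopeOf <- function(kind_i, kind_j) {
  a <- pmin(kind_i, kind_j)
  b <- pmax(kind_i, kind_j)
  paste(a, b, sep = "-")
}

.mkRecords <- function(kind, frame, i, j, topology, h = NA_integer_,
                       water = NA_integer_, energy = NA_real_,
                       solvent_ion = NA) {
  a <- topology$atoms
  if (!length(i)) return(.emptyRecords())
  data.frame(kind = kind, frame = frame, i = i, j = j, h = h, water = water,
             energy = energy,
             mol_i = a$mol[i], mol_j = a$mol[j],
             name_i = a$name[i], name_j = a$name[j],
             resno_i = a$resno[i], resname_i = a$resname[i],
             resno_j = a$resno[j], resname_j = a$resname[j],
             scope = .scopeOf(a$kind[i], a$kind[j]),
             solvent_ion = solvent_ion, stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds in one frame
#'
#' Finds every donor-H...acceptor triple whose energy ([hbondEnergy()])
#' strictly exceeds the threshold (default 6.25 kJ/mol, 25% of the
#' 25 kJ/mol optimum). Donor and acceptor heavy atoms must be distinct;
#' a donor may bond several acceptors simultaneously (no pruning).
#'
#' @param xyz n x 3 coordinates of the frame, Angstrom.
#' @param topology a [Topology].
#' @param params an [interactionParams()] object.
#' @param box optional length-3 box (minimum image).
#' @param frame frame index stored in the records.
#' @return data.frame of interaction records (`i` = donor heavy atom,
#'   `h` = hydrogen, `j` = acceptor, `energy` kJ/mol).
#' @export
detectHbonds <- function(xyz, topology, params = interactionParams(),
                         box = NULL, frame = 1L) {
  a <- topology$atoms
  b <- topology$bonds
  if (!nrow(b)) return(.emptyRecords())
  don_h <- b[a$donor[b[, 2]], , drop = FALSE]   # (h, heavy) with donor parent
  acc <- which(a$acceptor)
  if (!nrow(don_h) || !length(acc)) return(.emptyRecords())
  pr <- pairsWithinCutoff(xyz[don_h[, 1], , drop = FALSE], seq_len(nrow(don_h)),
                          xyz[acc, , drop = FALSE], acc,
                          cutoff = params$hb_d_zero, box = box)
  if (!nrow(pr)) return(.emptyRecords())
  hyd <- don_h[pr$i, 1]
  don <- don_h[pr$i, 2]
  keep <- don != pr$j
  hyd <- hyd[keep]; don <- don[keep]; accj <- pr$j[keep]; dHA <- pr$d[keep]
  if (!length(hyd)) return(.emptyRecords())
  vHD <- xyz[don, , drop = FALSE] - xyz[hyd, , drop = FALSE]
  vHA <- xyz[accj, , drop = FALSE] - xyz[hyd, , drop = FALSE]
  if (!is.null(box)) {
    vHD <- .miVec(vHD, box)
    vHA <- .miVec(vHA, box)
  }
  ct <- rowSums(vHD * vHA) / (sqrt(rowSums(vHD^2)) * sqrt(rowSums(vHA^2)))
  theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  E <- .hbEnergy(dHA, theta, params)
  sel <- E > hbondThreshold(params)
  .mkRecords("hbond", frame, don[sel], accj[sel], topology,
             h = hyd[sel], energy = E[sel])
}

#' Detect hydrophobic contacts in one frame
#'
#' All pairs of hydrophobic atoms from different residues within
#' `hp_cutoff` (minimum image).
#'
#' @inheritParams detectHbonds
#' @return data.frame of interaction records.
#' @export
detectHPContacts <- function(xyz, topology, params = interactionParams(),
                             box = NULL, frame = 1L) {
  a <- topology$atoms
  hp <- which(a$hydrophobic)
  if (length(hp) < 2) return(.emptyRecords())
  pr <- pairsWithinCutoff(xyz[hp, , drop = FALSE], hp,
                          xyz[hp, , drop = FALSE], hp,
                          cutoff = params$hp_cutoff, box = box,
                          same_set = TRUE)
  if (!nrow(pr)) return(.emptyRecords())
  sameres <- a$mol[pr$i] == a$mol[pr$j] & a$resno[pr$i] == a$resno[pr$j]
  pr <- pr[!sameres, , drop = FALSE]
  .mkRecords("hp", frame, pr$i, pr$j, topology)
}

#' Detect ionic interactions in one frame
#'
#' All pairs of atoms with opposite formal charge class from different
#' residues within `ionic_cutoff` (minimum image); a residue's own
#' zwitterion pair is not an interaction. Records flag whether a solvent
#' ion participates.
#'
#' @inheritParams detectHbonds
#' @return data.frame of interaction records.
#' @export
detectIonic <- function(xyz, topology, params = interactionParams(),
                        box = NULL, frame = 1L) {
  a <- topology$atoms
  ch <- which(a$charge != 0)
  if (length(ch) < 2) return(.emptyRecords())
  pr <- pairsWithinCutoff(xyz[ch, , drop = FALSE], ch,
                          xyz[ch, , drop = FALSE], ch,
                          cutoff = params$ionic_cutoff, box = box,
                          same_set = TRUE)
  if (!nrow(pr)) return(.emptyRecords())
  opp <- a$charge[pr$i] * a$charge[pr$j] < 0
  sameres <- a$mol[pr$i] == a$mol[pr$j] & a$resno[pr$i] == a$resno[pr$j]
  pr <- pr[opp & !sameres, , drop = FALSE]
  .mkRecords("ionic", frame, pr$i, pr$j, topology,
             solvent_ion = a$kind[pr$i] == "ion" | a$kind[pr$j] == "ion")
}

#' Detect water bridges in one frame
#'
#' A water bridge is a water molecule simultaneously hydrogen-bonded (by
#' the [detectHbonds()] criterion, water acting as donor or acceptor) to
#' atoms of two distinct non-water molecules; one record is produced per
#' (water, partner-atom pair).
#'
#' @inheritParams detectHbonds
#' @param hbonds optionally, precomputed H-bond records for the frame.
#' @return data.frame of interaction records (`i`, `j` = bridged partner
#'   atoms, `water` = water molecule id).
#' @export
detectWaterBridges <- function(xyz, topology, params = interactionParams(),
                               box = NULL, frame = 1L, hbonds = NULL) {
  a <- topology$atoms
  if (!any(a$kind == "water")) return(.emptyRecords())
  if (is.null(hbonds))
    hbonds <- detectHbonds(xyz, topology, params, box, frame)
  if (!nrow(hbonds)) return(.emptyRecords())
  wi <- a$kind[hbonds$i] == "water"
  wj <- a$kind[hbonds$j] == "water"
  hb <- hbonds[xor(wi, wj), , drop = FALSE]
  if (!nrow(hb)) return(.emptyRecords())
  water_mol <- ifelse(a$kind[hb$i] == "water", hb$mol_i, hb$mol_j)
  partner <- ifelse(a$kind[hb$i] == "water", hb$j, hb$i)
  out <- list(); k <- 0L
  for (w in unique(water_mol)) {
    p <- unique(partner[water_mol == w])
    if (length(p) < 2) next
    pm <- a$mol[p]
    cmb <- utils::combn(seq_along(p), 2)
    keep <- pm[cmb[1, ]] != pm[cmb[2, ]]
    if (!any(keep)) next
    i1 <- p[cmb[1, keep]]; i2 <- p[cmb[2, keep]]
    ## canonical order: lower atom index first
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)
    k <- k + 1L
    out[[k]] <- .mkRecords("water_bridge", frame, lo, hi, topology, water = w)
  }
  if (!k) return(.emptyRecords())
  do.call(rbind, out)
}

#' Aggregate interaction records into a labeled count matrix
#'
#' Mirrors the residue-by-atom interaction maps used for protein-membrane
#' contact analysis: rows can be protein residues (`"protein_residue"`,
#' label "246 LYS") or atom names; columns are partner atom names. For
#' atom-by-atom maps of symmetric interactions the pair is ordered
#' alphabetically so each record lands in a single cell.
#'
#' @param records interaction record data.frame.
#' @param row_scheme `"protein_residue"` or `"atom"`.
#' @param col_scheme `"atom"` (partner atom name).
#' @return An `InteractionMap`: integer matrix with labeled dimnames; the
#'   matrix total equals `nrow(records)`.
#' @export
buildInteractionMap <- function(records, row_scheme = c("protein_residue", "atom"),
                                col_scheme = "atom") {
  row_scheme <- match.arg(row_scheme)
  if (!nrow(records)) {
    m <- matrix(0L, 0, 0)
    class(m) <- c("InteractionMap", class(m))
    return(m)
  }
  if (row_scheme == "protein_residue") {
    ## protein side defines the row; partner atom name the column
    ipro <- records$resname_i %in% .aa3
    jpro <- records$resname_j %in% .aa3
    use <- ipro | jpro
    r <- records[use, , drop = FALSE]
    pi_ <- ipro[use]
    rows <- ifelse(pi_, paste(r$resno_i, r$resname_i), paste(r$resno_j, r$resname_j))
    cols <- ifelse(pi_, r$name_j, r$name_i)
  } else {
    a1 <- records$name_i
    a2 <- records$name_j
    rows <- pmin(a1, a2)
    cols <- pmax(a1, a2)
  }
  m <- table(rows, cols)
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  class(m) <- c("InteractionMap", class(m))
  m
}

#' Detect all interaction kinds in one frame
#'
#' @inheritParams detectHbonds
#' @param kinds subset of `c("hbond", "hp", "ionic", "water_bridge")`.
#' @return combined record data.frame.
#' @export
detectFrame <- function(xyz, topology, params = interactionParams(),
                        box = NULL, frame = 1L,
                        kinds = c("hbond", "hp", "ionic", "water_bridge")) {
  out <- list()
  hb <- NULL
  if (any(c("hbond", "water_bridge") %in% kinds))
    hb <- detectHbonds(xyz, topology, params, box, frame)
  if ("hbond" %in% kinds) out$hbond <- hb
  if ("hp" %in% kinds) out$hp <- detectHPContacts(xyz, topology, params, box, frame)
  if ("ionic" %in% kinds) out$ionic <- detectIonic(xyz, topology, params, box, frame)
  if ("water_bridge" %in% kinds)
    out$water_bridge <- detectWaterBridges(xyz, topology, params, box, frame,
                                           hbonds = hb)
  do.call(rbind, out)
}

#' Interaction counts over time
#'
#' Per frame: number of records of each kind within a scope, the number of
#' distinct lipids participating, and the minimum/maximum number of
#' interactions per participating lipid.
#'
#' @param trajectory a (jump-leveled) [Trajectory].
#' @param topology a [Topology].
#' @param params an [interactionParams()] object.
#' @param scope scope label(s) to keep, e.g. `"lipid-protein"`; `NULL` for all.
#' @param kinds interaction kinds to detect.
#' @param frames frame indices to analyse (default all).
#' @return list with `series` (per-frame data.frame) and `records`
#'   (all matching records).
#' @export
interactionTimeSeries <- function(trajectory, topology,
                                  params = interactionParams(),
                                  scope = "lipid-protein",
                                  kinds = c("hbond", "hp", "ionic", "water_bridge"),
                                  frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(trajectory))
  a <- topology$atoms
  recs <- list()
  series <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    box <- if (is.null(trajectory$box)) NULL else trajectory$box[f, ]
    r <- detectFrame(trajectory$coords[, , f], topology, params, box, f, kinds)
    if (!is.null(scope) && nrow(r)) r <- r[r$scope %in% scope, , drop = FALSE]
    recs[[k]] <- r
    lipmol <- c(r$mol_i[a$kind[r$i] == "lipid"], r$mol_j[a$kind[r$j] == "lipid"])
    perlip <- if (length(lipmol)) table(lipmol) else integer(0)
    cnt <- function(kk) sum(r$kind == kk)
    series[[k]] <- data.frame(
      frame = f, time = trajectory$times[f],
      n_hbond = cnt("hbond"), n_hp = cnt("hp"), n_ionic = cnt("ionic"),
      n_water_bridge = cnt("water_bridge"), n_total = nrow(r),
      n_lipids = length(perlip),
      per_lipid_min = if (length(perlip)) min(perlip) else 0L,
      per_lipid_max = if (length(perlip)) max(perlip) else 0L)
  }
  list(series = do.call(rbind, series), records = do.call(rbind, recs))
}
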
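#' Electron density profile along the bilayer normal
#'
#' Each atom contributes its atomic number of electrons to the z bin
#' containing its (box-wrapped) z coordinate; the density is
#' electrons / (Lx * Ly * bin width), averaged over the frame window.
#' Components are resolved by molecule kind (lipid, water, protein, ion).
#'
#' @param trajectory a [Trajectory] with a known box.
#' @param topology a [Topology].
#' @param bin_width z bin width, Angstrom (default 1).
#' @param frames frame window (default all frames).
#' @return A `DensityProfile` data.frame: `z` (bin centers, Angstrom),
#'   `lipid`, `water`, `protein`, `ion`, `total` (e-/Angstrom^3).
#' @export
electronDensityProfile <- function(trajectory, topology, bin_width = 1,
                                   frames = NULL) {
  if (is.null(trajectory$box)) stop("electron density profile requires a box")
  if (is.null(frames)) frames <- seq_len(nFrames(trajectory))
  a <- topology$atoms
  box <- trajectory$box[frames[1], ]
  nbin <- max(1L, ceiling(box[3] / bin_width))
  edges <- seq(0, by = bin_width, length.out = nbin + 1)
  comp <- c("lipid", "water", "protein", "ion")
  dens <- matrix(0, nbin, length(comp), dimnames = list(NULL, comp))
  vol <- box[1] * box[2] * bin_width * length(frames)
  for (f in frames) {
    z <- trajectory$coords[, 3, f] %% box[3]
    bin <- pmin(nbin, floor(z / bin_width) + 1L)
    for (k in comp) {
      sel <- a$kind == k
      if (!any(sel)) next
      e <- rowsum(as.numeric(a$anum[sel]), bin[sel])
      dens[as.integer(rownames(e)), k] <- dens[as.integer(rownames(e)), k] + e
    }
  }
  dens <- dens / vol
  out <- data.frame(z = (edges[-1] + edges[-(nbin + 1)]) / 2, dens,
                    total = rowSums(dens))
  attr(out, "bin_width") <- bin_width
  attr(out, "box") <- box
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("DensityProfile", class(out))
  out
}

#' Bilayer thickness from the lipid electron density profile
#'
#' Distance between the two head-group peaks of the lipid component
#' (peak-to-peak convention, the standard for electron density profiles).
#' The second peak must lie at least `min_separation` from the first, so
#' sub-features of one head-group region (e.g. phosphate vs choline
#' clusters) are not mistaken for the opposite leaflet. An optional
#' moving-average smoothing (`smooth` bins) is available for noisy
#' profiles; it is off by default because it flattens sharp head-group
#' peaks.
#'
#' @param profile a `DensityProfile` from [electronDensityProfile()].
#' @param min_separation minimum peak separation, Angstrom (default 10).
#' @param smooth odd moving-average window in bins (default 1 = none).
#' @return thickness in Angstrom; attribute `"peaks"` holds the two peak
#'   z positions.
#' @export
bilayerThickness <- function(profile, min_separation = 10, smooth = 1) {
  y <- profile$lipid
  if (smooth > 1)
    y <- as.numeric(stats::filter(y, rep(1 / smooth, smooth), sides = 2))
  y[is.na(y)] <- 0
  i1 <- which.max(y)
  far <- abs(profile$z - profile$z[i1]) >= min_separation
  if (!any(far) || max(y[far]) <= 0)
    stop("lipid profile is not bimodal: no bilayer thickness defined")
  i2 <- which(far)[which.max(y[far])]
  lo <- min(i1, i2); hi <- max(i1, i2)
  if (min(y[lo:hi]) >= min(y[i1], y[i2]))
    stop("lipid profile is not bimodal: no bilayer thickness defined")
  z <- sort(profile$z[c(i1, i2)])
  structure(abs(diff(z)), peaks = z)
}

#' Protein penetration depth into the contact leaflet
#'
#' Per frame, the reference plane is the mean z of the contact-leaflet
#' phosphorus atoms; the depth is how far the deepest protein atom has
#' passed that plane toward the bilayer center (0 when the protein stays
#' outside). The residues owning the deepest atoms are reported.
#'
#' @param trajectory a [Trajectory].
#' @param topology a [Topology] with leaflets assigned
#'   ([assignLeaflets()]).
#' @param leaflet label of the contact leaflet (default `"contact"`).
#' @return A `PenetrationReport` data.frame: `frame`, `time`, `depth`
#'   (Angstrom), `deepest_resno`, `deepest_resname`, `deepest_atom`.
#' @export
penetrationDepth <- function(trajectory, topology, leaflet = "contact") {
  a <- topology$atoms
  pidx <- which(a$kind == "lipid" & a$element == "P" &
                  !is.na(a$leaflet) & a$leaflet == leaflet)
  if (!length(pidx)) stop("no phosphorus atoms in the ", leaflet, " leaflet")
  prot <- which(a$kind == "protein")
  if (!length(prot)) stop("no protein atoms")
  lip <- which(a$kind == "lipid")
  nf <- nFrames(trajectory)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    plane <- mean(trajectory$coords[pidx, 3, f])
    mid <- mean(trajectory$coords[lip, 3, f])
    dir <- sign(mid - plane)            # toward bilayer center
    if (dir == 0) dir <- -1
    pen <- (trajectory$coords[prot, 3, f] - plane) * dir
    k <- which.max(pen)
    out[[f]] <- data.frame(frame = f, time = trajectory$times[f],
                           depth = max(0, pen[k]),
                           deepest_resno = a$resno[prot[k]],
                           deepest_resname = a$resname[prot[k]],
                           deepest_atom = a$name[prot[k]])
  }
  res <- do.call(rbind, out)
  class(res) <- c("PenetrationReport", class(res))
  res
}

#' Count waters inside the bilayer core
#'
#' Number of water oxygens whose z lies strictly between the two leaflet
#' head-group phosphorus planes, per frame.
#'
#' @param trajectory a [Trajectory].
#' @param topology a [Topology] with leaflets assigned.
#' @return data.frame: `frame`, `time`, `n_interior_waters`.
#' @export
interiorWaterCount <- function(trajectory, topology) {
  a <- topology$atoms
  leaf <- unique(a$leaflet[!is.na(a$leaflet)])
  if (length(leaf) != 2) stop("two leaflets must be assigned")
  p1 <- which(a$kind == "lipid" & a$element == "P" & a$leaflet == leaf[1])
  p2 <- which(a$kind == "lipid" & a$element == "P" & a$leaflet == leaf[2])
  if (!length(p1) || !length(p2)) stop("missing phosphorus atoms in a leaflet")
  wox <- which(a$kind == "water" & a$element == "O")
  nf <- nFrames(trajectory)
  n <- integer(nf)
  for (f in seq_len(nf)) {
    z1 <- mean(trajectory$coords[p1, 3, f])
    z2 <- mean(trajectory$coords[p2, 3, f])
    lo <- min(z1, z2); hi <- max(z1, z2)
    zw <- trajectory$coords[wox, 3, f]
    n[f] <- sum(zw > lo & zw < hi)
  }
  data.frame(frame = seq_len(nf), time = trajectory$times,
             n_interior_waters = n)
}
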
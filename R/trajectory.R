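#' Ordered coordinate frames of a simulated system
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param times numeric vector of frame times, ns, strictly increasing.
#' @param box per-frame orthorhombic box lengths: either a length-3 vector
#'   (constant box) or an `n_frames x 3` matrix, Angstrom; `NULL` if unknown.
#'
#' @return An object of class `Trajectory`.
#' @export
Trajectory <- function(coords, times, box = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  nf <- dim(coords)[3]
  if (length(times) != nf) stop("times length must equal number of frames")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
    if (!all(dim(box) == c(nf, 3))) stop("box must be length 3 or n_frames x 3")
    if (any(box <= 0)) stop("box lengths must be > 0")
  }
  structure(list(coords = coords, times = as.numeric(times), box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("Trajectory:", d[3], "frames x", d[1], "atoms,",
      sprintf("t = %g..%g ns", x$times[1], x$times[d[3]]), "\n")
  if (!is.null(x$box))
    cat("  box (frame 1):", paste(signif(x$box[1, ], 4), collapse = " x "), "Angstrom\n")
  invisible(x)
}

#' @export
nFrames <- function(x) UseMethod("nFrames")

#' @export
nFrames.Trajectory <- function(x) dim(x$coords)[3]

#' Minimum-image distance in an orthorhombic box
#'
#' @param x1,x2 coordinates: length-3 vectors or n x 3 matrices, Angstrom.
#' @param box length-3 box vector (Lx, Ly, Lz), Angstrom.
#' @return Euclidean distance(s) under the minimum-image convention.
#' @export
minimumImageDistance <- function(x1, x2, box) {
  if (any(box <= 0)) stop("box lengths must be > 0")
  if (is.null(dim(x1))) x1 <- matrix(x1, ncol = 3)
  if (is.null(dim(x2))) x2 <- matrix(x2, ncol = 3)
  d <- x1 - x2
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  sqrt(rowSums(d^2))
}

## minimum-image displacement vectors (n x 3)
.miVec <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Per-frame geometric centers of molecules
#'
#' Unweighted mean of the coordinates of each molecule's atoms
#' (optionally excluding hydrogens), for every frame.
#'
#' @param trajectory a [Trajectory].
#' @param topology a [Topology].
#' @param kind molecule kind(s) to include (default `"lipid"`); `NULL` for all.
#' @param include_h include hydrogens in the center (default `TRUE`).
#' @return array `n_molecules x 3 x n_frames`; `dimnames[[1]]` holds molecule ids.
#' @export
geometricCenters <- function(trajectory, topology, kind = "lipid",
                             include_h = TRUE) {
  a <- topology$atoms
  sel <- if (is.null(kind)) rep(TRUE, nrow(a)) else a$kind %in% kind
  if (!include_h) sel <- sel & a$element != "H"
  if (!any(sel)) stop("no atoms selected for geometric centers")
  mol <- a$mol[sel]
  mols <- sort(unique(mol))
  g <- match(mol, mols)
  cnt <- tabulate(g, nbins = length(mols))
  nf <- nFrames(trajectory)
  out <- array(0, c(length(mols), 3, nf), dimnames = list(mols, NULL, NULL))
  xs <- trajectory$coords[sel, , , drop = FALSE]
  for (f in seq_len(nf))
    out[, , f] <- rowsum(xs[, , f], g, reorder = TRUE) / cnt
  out
}

#' Repair box-length jump artefacts
#'
#' Simulation software occasionally translates a whole molecule by one box
#' length between consecutive saved frames (a wrapping artefact). This
#' detects, per molecule and axis, center displacements between consecutive
#' frames larger than half the box length and shifts the trailing trajectory
#' by the integer multiple of the box length that minimizes the displacement.
#' Shifts are applied to whole molecules, so molecules stay internally rigid.
#'
#' The operation is idempotent provided genuine motion between saved frames
#' is below half a box length per axis.
#'
#' @param trajectory a [Trajectory] with a known box.
#' @param topology a [Topology].
#' @return The repaired [Trajectory].
#' @export
levelJumps <- function(trajectory, topology) {
  if (is.null(trajectory$box)) stop("levelJumps requires a known box")
  nf <- nFrames(trajectory)
  if (nf < 2) return(trajectory)
  centers <- geometricCenters(trajectory, topology, kind = NULL)
  mols <- as.integer(dimnames(centers)[[1]])
  coords <- trajectory$coords
  atomRow <- match(topology$atoms$mol, mols)
  nm <- length(mols)
  cum <- matrix(0, nm, 3)   # cumulative shift, in box-length multiples
  prev <- centers[, , 1, drop = FALSE][, , 1]
  if (is.null(dim(prev))) prev <- matrix(prev, nm, 3)
  for (f in 2:nf) {
    L <- trajectory$box[f, ]
    Lm <- matrix(L, nm, 3, byrow = TRUE)
    cur <- centers[, , f]
    if (is.null(dim(cur))) cur <- matrix(cur, nm, 3)
    d <- cur + cum * Lm - prev
    n <- round(d / Lm)
    n[abs(d) <= Lm / 2] <- 0
    cum <- cum - n
    if (any(cum != 0)) {
      shiftA <- (cum * Lm)[atomRow, , drop = FALSE]
      coords[, , f] <- coords[, , f] + shiftA
    }
    prev <- cur + cum * Lm
  }
  Trajectory(coords, trajectory$times, trajectory$box)
}
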
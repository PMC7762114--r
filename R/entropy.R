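#' Coordinate covariance matrix of one molecule
#'
#' For each atom the x, y and z position series over the frames are
#' mean-subtracted per coordinate and concatenated, giving `3 F`
#' realizations per atom for `F` frames; the covariance element is the
#' average product of the concatenated series of atoms i and j:
#' `sigma_ij = < (x_i - <x_i>) (x_j - <x_j>) >`. The matrix has dimension
#' n_atoms x n_atoms (Angstrom^2).
#'
#' @param coords atom coordinates of one molecule, array `n x 3 x F`
#'   (jump-leveled), Angstrom.
#' @param masses atomic masses, amu (stored alongside for entropy).
#' @return A `CovarianceModel` list: `sigma` (n x n, Angstrom^2),
#'   `n_realizations` (= 3F), `masses`.
#' @export
covarianceMatrix <- function(coords, masses = NULL) {
  if (length(dim(coords)) != 3) stop("coords must be n x 3 x F")
  n <- dim(coords)[1]
  F <- dim(coords)[3]
  if (F < 2) stop("covariance needs at least 2 frames")
  ## n x 3F matrix of per-coordinate mean-centered series, concatenated
  X <- matrix(NA_real_, n, 3 * F)
  for (ax in 1:3) {
    s <- coords[, ax, , drop = FALSE]
    dim(s) <- c(n, F)
    X[, (ax - 1) * F + seq_len(F)] <- s - rowMeans(s)
  }
  sigma <- tcrossprod(X) / (3 * F)
  structure(list(sigma = sigma, n_realizations = 3L * F, masses = masses),
            class = "CovarianceModel")
}

#' Schlitter configurational entropy
#'
#' Upper-bound entropy estimate from a mass-weighted coordinate covariance:
#' `S = kB ln det(1 + (kB T e^2 / hbar^2) M^(1/2) sigma M^(1/2))`, with
#' `M` the diagonal atomic mass matrix and `sigma` the covariance of
#' [covarianceMatrix()]. The mass weighting is applied symmetrically
#' (determinant-identical to `M sigma` for diagonal `M`, numerically
#' stable), the log-determinant is computed in the log domain from the
#' eigenvalues, and the identity addition keeps the determinant nonzero
#' for few-frame windows. The conventional extra 1/2 prefactor of the
#' Schlitter bound is off by default (`half = FALSE`); enable it with
#' `half = TRUE`.
#'
#' Negative eigenvalues beyond `-tol` trigger a warning and are clamped
#' at zero.
#'
#' @param cov a `CovarianceModel`, or a plain covariance matrix
#'   (Angstrom^2) if `masses` is given.
#' @param temperature temperature, K.
#' @param masses atomic masses, amu (taken from `cov` when present).
#' @param half apply the conventional 1/2 prefactor.
#' @param tol tolerance for negative-eigenvalue clamping.
#' @return list: `S_kB` (entropy in units of kB), `S_kcal_molK`
#'   (kcal/(mol K)).
#' @export
schlitterEntropy <- function(cov, temperature = 310, masses = NULL,
                             half = FALSE, tol = 1e-8) {
  if (inherits(cov, "CovarianceModel")) {
    sigma <- cov$sigma
    if (is.null(masses)) masses <- cov$masses
  } else sigma <- as.matrix(cov)
  if (is.null(masses)) stop("atomic masses required")
  n <- nrow(sigma)
  stopifnot(length(masses) == n, temperature > 0)
  ## kB T e^2 / hbar^2 * m[kg] * sigma[m^2], dimensionless
  c0 <- .kB * temperature * exp(2) / .hbar^2 * .amu * .A2m^2
  sm <- sqrt(masses)
  W <- c0 * (sigma * tcrossprod(sm))
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (any(ev < -tol * scale))
    warning("covariance has negative eigenvalue(s); clamping at zero")
  ev <- pmax(ev, 0)
  S_kB <- sum(log1p(ev))
  if (half) S_kB <- S_kB / 2
  list(S_kB = S_kB, S_kcal_molK = S_kB * .R_kcal)
}

#' Entropy-vs-time curve averaged over lipids
#'
#' For each output time t the covariance is estimated from all frames in
#' [0, t] and the Schlitter entropy computed per lipid, then averaged over
#' the selected lipids (by default the leaflet in contact with the
#' protein, falling back to all lipids when no leaflet labels are set).
#' Coordinates are used as-is after jump leveling (no removal of overall
#' translation) unless `remove_com = TRUE`.
#'
#' @param trajectory a jump-leveled [Trajectory].
#' @param topology a [Topology] (leaflets assigned if contact selection is
#'   wanted).
#' @param temperature temperature, K.
#' @param leaflet leaflet label to average over (default `"contact"`).
#' @param eval_frames frame indices at which the cumulative entropy is
#'   evaluated (default: every frame from the third).
#' @param half,remove_com see [schlitterEntropy()].
#' @return An `EntropyResult` data.frame: `time` (ns), `S_mean_kcal_molK`,
#'   `S_sd_kcal_molK` (spread over lipids), `n_frames`.
#' @export
entropyTimeCurve <- function(trajectory, topology, temperature = 310,
                             leaflet = "contact", eval_frames = NULL,
                             half = FALSE, remove_com = FALSE) {
  a <- topology$atoms
  sel_mol <- unique(a$mol[a$kind == "lipid" &
                            (is.na(leaflet) | is.null(leaflet) |
                               (!is.na(a$leaflet) & a$leaflet %in% leaflet))])
  if (!length(sel_mol)) sel_mol <- unique(a$mol[a$kind == "lipid"])
  if (!length(sel_mol)) stop("no lipid molecules")
  nf <- nFrames(trajectory)
  if (is.null(eval_frames)) eval_frames <- seq(3L, nf)
  out <- vector("list", length(eval_frames))
  molcoords <- lapply(sel_mol, function(m) {
    idx <- which(a$mol == m)
    list(coords = trajectory$coords[idx, , , drop = FALSE],
         masses = a$mass[idx])
  })
  for (k in seq_along(eval_frames)) {
    f <- eval_frames[k]
    S <- vapply(molcoords, function(mc) {
      x <- mc$coords[, , seq_len(f), drop = FALSE]
      if (remove_com) {
        com <- colMeans(x)                # 3 x F means over atoms
        x <- sweep(x, 2:3, com, "-")
      }
      cv <- covarianceMatrix(x, mc$masses)
      schlitterEntropy(cv, temperature, half = half)$S_kcal_molK
    }, numeric(1))
    out[[k]] <- data.frame(time = trajectory$times[f],
                           S_mean_kcal_molK = mean(S),
                           S_sd_kcal_molK = stats::sd(S),
                           n_frames = f)
  }
  res <- do.call(rbind, out)
  class(res) <- c("EntropyResult", class(res))
  res
}

#' Gaussianity and correlation diagnostics of intramolecular fluctuations
#'
#' Pearson correlation matrix of the concatenated zero-mean coordinate
#' series of one molecule, plus per-atom histograms of the concatenated
#' series for inspecting departures from normality.
#'
#' @param coords one molecule's coordinates, array `n x 3 x F`, F >= 30.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list: `correlation` (n x n), `histograms` (list of histogram
#'   objects, one per atom), `n_realizations`.
#' @export
gaussianityDiagnostics <- function(coords, breaks = 30) {
  n <- dim(coords)[1]
  F <- dim(coords)[3]
  if (F < 30) stop("need at least 30 frames for diagnostics")
  X <- matrix(NA_real_, n, 3 * F)
  for (ax in 1:3) {
    s <- coords[, ax, , drop = FALSE]
    dim(s) <- c(n, F)
    X[, (ax - 1) * F + seq_len(F)] <- s - rowMeans(s)
  }
  corr <- suppressWarnings(stats::cor(t(X)))
  corr[!is.finite(corr)] <- 0
  diag(corr) <- 1
  hists <- lapply(seq_len(n), function(i)
    graphics::hist(X[i, ], breaks = breaks, plot = FALSE))
  list(correlation = corr, histograms = hists, n_realizations = 3L * F)
}
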
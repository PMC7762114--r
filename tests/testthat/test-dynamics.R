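test_that("geometric centers equal the brute-force mean and translate rigidly", {
  s <- sparseSystem(template = "DPPC", n_lip = 1, n_frames = 2)
  a <- s$topology$atoms
  ctr <- geometricCenters(s$trajectory, s$topology, kind = NULL)
  mols <- as.integer(dimnames(ctr)[[1]])
  set.seed(1)
  for (m in sample(mols, 4)) {
    want <- colMeans(matrix(s$trajectory$coords[a$mol == m, , 1], ncol = 3))
    expect_equal(unname(ctr[as.character(m), , 1]), unname(want))
  }
  ## rigid translation moves every center by the same vector
  tr2 <- s$trajectory
  v <- c(3.2, -1.1, 7.4)
  tr2$coords <- sweep(tr2$coords, 2, v, "+")
  ctr2 <- geometricCenters(tr2, s$topology, kind = NULL)
  expect_equal(ctr2[, , 1] - ctr[, , 1],
               matrix(v, length(mols), 3, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("leaflets split evenly and the protein side is the contact side", {
  s <- sparseSystem(n_lip = 8, n_frames = 2)
  topo <- assignLeaflets(s$topology, s$trajectory)
  a <- topo$atoms
  leafOf <- a$leaflet[a$kind == "lipid"][!duplicated(a$mol[a$kind == "lipid"])]
  expect_equal(sum(leafOf == "contact"), 8)
  expect_equal(sum(leafOf == "noncontact"), 8)
  ## the protein sits above the upper leaflet by construction
  up <- a$leaflet == "contact" & !is.na(a$leaflet)
  lo <- a$leaflet == "noncontact" & !is.na(a$leaflet)
  x <- s$trajectory$coords[, , 1]
  expect_gt(mean(x[up, 3]), mean(x[lo, 3]))
  ## without a protein the labels fall back to upper/lower
  spec <- syntheticSpec(n_lipids_per_leaflet = 4, lipid_template = "minimal",
                        n_frames = 2, protein = FALSE, n_waters = 0,
                        n_ions = c(0, 0), leaflet_D = c(upper = 0, lower = 0),
                        rng_seed = 2)
  t2 <- generateTopology(spec)
  t2 <- assignLeaflets(t2, generateTrajectory(t2, spec))
  expect_setequal(unique(stats::na.omit(t2$atoms$leaflet)), c("upper", "lower"))
})

test_that("origin-based MSD matches closed forms", {
  times <- seq(0, 4, by = 0.5)
  ## static paths
  p0 <- array(5, c(3, 3, length(times)))
  expect_true(all(computeMSD(p0, times)$msd == 0))
  ## single molecule at constant velocity: MSD = |v|^2 t^2
  v <- c(1, -2, 0.5)
  p1 <- array(0, c(1, 3, length(times)))
  for (f in seq_along(times)) p1[1, , f] <- v * times[f]
  m <- computeMSD(p1, times)
  expect_equal(m$msd, sum(v^2) * times^2)
  expect_equal(m$msd[1], 0)
})

test_that("power-law fit is exact on noiseless input and units round-trip", {
  t <- seq(0.05, 10, by = 0.05)
  m1 <- structure(data.frame(t = t, msd = 6 * 1 * t), class = c("MSDSeries", "data.frame"))
  f1 <- fitPowerLaw(m1, fit_range = range(t))
  expect_equal(f1$alpha, 1, tolerance = 1e-10)
  expect_equal(f1$D, 1, tolerance = 1e-10)

  m2 <- structure(data.frame(t = t, msd = 6 * 0.5 * t^0.3), class = c("MSDSeries", "data.frame"))
  f2 <- fitPowerLaw(m2, fit_range = range(t))
  expect_equal(f2$alpha, 0.3, tolerance = 1e-10)
  expect_equal(f2$D, 0.5, tolerance = 1e-10)

  ## cm^2/s^alpha conversion round-trips
  back <- f2$D_cm2s / (1e-16 / (1e-9)^f2$alpha)
  expect_equal(back, f2$D, tolerance = 1e-12)

  expect_error(fitPowerLaw(structure(data.frame(t = t, msd = 0 * t),
                                     class = c("MSDSeries", "data.frame"))),
               "nonpositive")
})

test_that("fitted exponent on a subdiffusive ensemble is within its error bars", {
  set.seed(17)
  times <- seq(0, 50, by = 0.25)
  p <- fbmPaths(300, times, alpha = 0.35, D = 0.8)
  fit <- fitPowerLaw(computeMSD(p, times))
  expect_lt(abs(fit$alpha - 0.35), 3 * fit$std_alpha + 0.02)
})

test_that("box jumps corrupt the MSD and leveling restores it", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 4, lipid_template = "minimal",
                        n_frames = 40, n_waters = 0, n_ions = c(0, 0),
                        protein = FALSE,
                        leaflet_D = c(upper = 0.5, lower = 0.5), rng_seed = 6)
  topo <- generateTopology(spec)
  traj <- generateTrajectory(topo, spec)
  mols <- unique(topo$atoms$mol)
  bad <- injectJumps(traj, topo, list(list(frame = 12, axis = 3, sign = 1,
                                           mol = mols[2])))
  msd0 <- computeMSD(geometricCenters(traj, topo), traj$times)$msd
  msdBad <- computeMSD(geometricCenters(bad, topo), bad$times)$msd
  expect_gt(max(abs(msdBad - msd0)), 100)
  lev <- levelJumps(bad, topo)
  msdLev <- computeMSD(geometricCenters(lev, topo), lev$times)$msd
  expect_lt(max(abs(msdLev - msd0)), 1e-6)
})

test_that("radius of gyration matches closed forms and brute force", {
  mk <- function(xyz, mass) {
    n <- nrow(xyz)
    atoms <- data.frame(eleno = 1:n, name = paste0("C", 1:n), element = "C",
                        mass = mass, anum = 6L, resname = "DPP", resno = 1L,
                        mol = 1L, chain = "A", kind = "lipid", donor = FALSE,
                        acceptor = FALSE, hydrophobic = FALSE, charge = 0L,
                        leaflet = NA)
    list(topo = Topology(atoms),
         traj = Trajectory(array(xyz, c(n, 3, 1)), times = 0))
  }
  ## coincident atoms
  z <- mk(matrix(1, 4, 3), 12)
  expect_equal(radiusOfGyration(z$traj, z$topo), 0)
  ## two equal masses 2 A apart: Rg = 1
  z2 <- mk(rbind(c(0, 0, 0), c(2, 0, 0)), 12)
  expect_equal(radiusOfGyration(z2$traj, z2$topo), 1)
  ## random molecule vs direct formula
  set.seed(3)
  xyz <- matrix(rnorm(15), 5, 3)
  mass <- runif(5, 1, 30)
  z3 <- mk(xyz, mass)
  com <- colSums(xyz * mass) / sum(mass)
  want <- sqrt(sum(mass * rowSums(sweep(xyz, 2, com)^2)) / sum(mass))
  expect_equal(radiusOfGyration(z3$traj, z3$topo), want, tolerance = 1e-12)
})
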
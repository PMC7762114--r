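test_that("lipid templates carry the reference atom counts", {
  s_dppc <- sparseSystem(template = "DPPC", n_lip = 1)
  a <- s_dppc$topology$atoms
  lip <- a$mol[a$kind == "lipid"][1]
  expect_equal(sum(a$mol == lip), 130)

  s_pope <- sparseSystem(template = "POPE", n_lip = 1)
  a <- s_pope$topology$atoms
  lip <- a$mol[a$kind == "lipid"][1]
  expect_equal(sum(a$mol == lip), 125)

  spec <- syntheticSpec(n_lipids_per_leaflet = 144, lipid_template = "minimal",
                        n_frames = 2, n_waters = 0, n_ions = c(0, 0),
                        protein = FALSE, rng_seed = 1)
  topo <- generateTopology(spec)
  a <- topo$atoms
  expect_equal(length(unique(a$mol[a$kind == "lipid"])), 288)
  expect_equal(sum(a$leaflet == "upper", na.rm = TRUE) / 10, 144)
})

test_that("head-group atoms are named and placed on both leaflets", {
  s <- sparseSystem(template = "DPPC", n_lip = 2)
  a <- s$topology$atoms
  for (nm in c("P", "N", "O13", "O14", "O22", "C11", "C12"))
    expect_equal(sum(a$name == nm & a$kind == "lipid"), 4)
  ## heads point outward: upper-leaflet P above its tail carbons
  up <- a$leaflet == "upper" & !is.na(a$leaflet)
  x <- s$trajectory$coords[, , 1]
  expect_gt(mean(x[up & a$name == "P", 3]), mean(x[up & a$name == "C216", 3]))
  lo <- a$leaflet == "lower" & !is.na(a$leaflet)
  expect_lt(mean(x[lo & a$name == "P", 3]), mean(x[lo & a$name == "C216", 3]))
})

test_that("same seed gives a bit-identical system, frozen spec gives static frames", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 3, lipid_template = "minimal",
                        n_frames = 8, internal_covariance = 0.1,
                        leaflet_D = c(upper = 0.4, lower = 0.2),
                        leaflet_alpha = c(upper = 0.6, lower = 1),
                        n_waters = 3, n_ions = c(1, 1), rng_seed = 31)
  t1 <- generateTrajectory(generateTopology(spec), spec)
  t2 <- generateTrajectory(generateTopology(spec), spec)
  expect_identical(t1$coords, t2$coords)

  frozen <- syntheticSpec(n_lipids_per_leaflet = 3, lipid_template = "minimal",
                          n_frames = 5, leaflet_D = c(upper = 0, lower = 0),
                          n_waters = 2, n_ions = c(0, 0), rng_seed = 3)
  tf <- generateTrajectory(generateTopology(frozen), frozen)
  for (f in 2:5) expect_identical(tf$coords[, , f], tf$coords[, , 1])
})

test_that("fBm paths have the exact target ensemble MSD", {
  set.seed(1)
  times <- seq(0, 5, by = 0.1)
  ## normal diffusion: MSD(t) ~ 6 t within sampling error
  p <- fbmPaths(600, times, alpha = 1, D = 1)
  msd <- computeMSD(p, times)
  mid <- msd$msd[msd$t > 1]
  expect_lt(max(abs(mid / (6 * msd$t[msd$t > 1]) - 1)), 0.2)

  ## subdiffusion: fitted exponent close to the planted one
  set.seed(2)
  p2 <- fbmPaths(400, seq(0, 20, by = 0.1), alpha = 0.5, D = 1)
  fit <- fitPowerLaw(computeMSD(p2, seq(0, 20, by = 0.1)))
  expect_lt(abs(fit$alpha - 0.5), 0.06)
})

test_that("planted intramolecular fluctuations reproduce the target covariance", {
  n <- 7
  set.seed(5)
  A <- matrix(rnorm(n * n, sd = 0.3), n)
  Sigma <- crossprod(A) + diag(0.05, n)
  spec <- syntheticSpec(n_lipids_per_leaflet = 3, lipid_template = "minimal",
                        minimal_k = 7,
                        n_frames = 1000, internal_covariance = Sigma,
                        leaflet_D = c(upper = 0, lower = 0),
                        protein = FALSE, n_waters = 0, n_ions = c(0, 0),
                        rng_seed = 8)
  topo <- generateTopology(spec)
  traj <- generateTrajectory(topo, spec)
  a <- topo$atoms
  mols <- unique(a$mol[a$kind == "lipid"])
  est <- matrix(0, n, n)
  for (m in mols) {
    cv <- covarianceMatrix(traj$coords[a$mol == m, , , drop = FALSE])
    expect_equal(cv$n_realizations, 3000)
    est <- est + cv$sigma / length(mols)
  }
  frob <- norm(est - Sigma, "F") / norm(Sigma, "F")
  expect_lt(frob, 0.10)
})

test_that("planted contacts are detected exactly as declared", {
  s <- sparseSystem(n_frames = 2, seed = 11, n_lip = 4, template = "minimal")
  a <- s$topology$atoms
  lip <- unique(a$mol[a$kind == "lipid"])
  pro <- unique(a$mol[a$kind == "protein"])
  wat <- unique(a$mol[a$kind == "water"])
  contacts <- list(
    ## water as a single-partner donor, lipid phosphate oxygen as acceptor
    list(kind = "hbond", a = list(mol = wat[2], name = "O"),
         b = list(mol = lip[1], name = "O13"),
         geometry = list(d = 2.0, theta = 180), expected_detected = TRUE),
    ## donor-acceptor pair placed far beyond any cutoff
    list(kind = "hbond", a = list(mol = wat[3], name = "O"),
         b = list(mol = lip[2], name = "O13"),
         geometry = list(d = 5.0, theta = 180), expected_detected = FALSE),
    list(kind = "hp", a = list(mol = lip[3], name = "C22"),
         b = list(mol = lip[4], name = "C22"),
         geometry = list(d = 4.0), expected_detected = TRUE),
    list(kind = "ionic", a = list(mol = pro, name = "OD2"),
         b = list(mol = lip[1], name = "N"),
         geometry = list(d = 3.0), expected_detected = TRUE),
    list(kind = "water_bridge", a = list(mol = lip[5], name = "O22"),
         b = list(mol = lip[6], name = "O22"),
         water = wat[1], geometry = list(d = 1.9), expected_detected = TRUE))
  pl <- plantContacts(s$trajectory, s$topology, contacts)
  expect_equal(unname(pl$expected), c(1L, 1L, 1L, 1L))
  for (f in 1:2) {
    box <- pl$trajectory$box[f, ]
    r <- detectFrame(pl$trajectory$coords[, , f], s$topology, box = box,
                     frame = f)
    ## exactly the planted in-threshold contacts: one direct water-lipid
    ## H-bond plus the two H-bonds forming the bridge; the out-of-threshold
    ## pair contributes nothing
    expect_equal(sum(r$kind == "hbond" & r$scope == "lipid-water"), 3L)
    expect_equal(sum(r$kind == "hp" & r$scope == "lipid-lipid"), 1L)
    expect_equal(sum(r$kind == "ionic"), 1L)
    expect_equal(sum(r$kind == "water_bridge"), 1L)
  }
})

test_that("unresolvable selectors and clashes are handled", {
  s <- sparseSystem(n_frames = 2, seed = 12, n_lip = 2)
  expect_error(plantContacts(s$trajectory, s$topology,
                             list(list(kind = "hp",
                                       a = list(mol = 1, name = "ZZ"),
                                       b = list(mol = 2, name = "P"),
                                       geometry = list(d = 4)))),
               "does not resolve")
})
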
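test_that("H-bond energy reproduces its closed-form anchor points", {
  p <- interactionParams()
  D <- c(0, 0, 0); H <- c(0, 0, 1)
  at <- function(d) c(0, 0, 1 + d)  # collinear: theta = 180
  expect_equal(hbondEnergy(D, H, at(2.1)), 25)
  expect_equal(hbondEnergy(D, H, at(2.0)), 25)   # plateau
  expect_equal(hbondEnergy(D, H, at(2.35)), 12.5)
  expect_equal(hbondEnergy(D, H, at(2.6)), 0)
  expect_equal(hbondEnergy(D, H, at(3.5)), 0)
  ## angle ramp: 140 degrees is halfway
  a140 <- H + 2.0 * c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  expect_equal(hbondEnergy(D, H, a140), 12.5, tolerance = 1e-12)
  ## at or below the 100-degree floor the energy vanishes
  a100 <- H + 2.0 * c(sin(80 * pi / 180), 0, cos(80 * pi / 180))
  expect_equal(hbondEnergy(D, H, a100), 0, tolerance = 1e-12)
})

test_that("H-bond energy is continuous and monotone in distance and angle", {
  p <- interactionParams()
  D <- c(0, 0, 0); H <- c(0, 0, 1)
  ds <- seq(1.6, 3.0, by = 0.01)
  E <- vapply(ds, function(d) hbondEnergy(D, H, c(0, 0, 1 + d)), numeric(1))
  expect_true(all(diff(E) <= 1e-12))             # non-increasing in d
  expect_lt(max(abs(diff(E))), 25 * 0.011 / 0.5 + 1e-9)  # no jumps
  thetas <- seq(100, 180, by = 1)
  Ea <- vapply(thetas, function(th) {
    acc <- H + 2.0 * c(sin((180 - th) * pi / 180), 0, cos((180 - th) * pi / 180))
    hbondEnergy(D, H, acc)
  }, numeric(1))
  expect_true(all(diff(Ea) >= -1e-9))            # non-decreasing in theta
})

test_that("a triple at exactly the threshold energy is not reported", {
  ## theta = 180, distance chosen so E = 6.25 exactly
  d_thr <- 2.6 - 0.25 * (2.6 - 2.1)
  atoms <- data.frame(eleno = 1:3, name = c("N", "H", "O"),
                      element = c("N", "H", "O"), mass = c(14, 1, 16),
                      anum = c(7L, 1L, 8L), resname = "XXX", resno = c(1L, 1L, 2L),
                      mol = c(1L, 1L, 2L), chain = "A", kind = "protein",
                      donor = c(TRUE, FALSE, FALSE),
                      acceptor = c(FALSE, FALSE, TRUE),
                      hydrophobic = FALSE, charge = 0L, leaflet = NA)
  topo <- Topology(atoms, rbind(c(2L, 1L)))
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1 + d_thr))
  expect_equal(hbondEnergy(xyz[1, ], xyz[2, ], xyz[3, ]), 6.25)
  expect_equal(nrow(detectHbonds(xyz, topo)), 0L)
  ## epsilon inside the threshold it is reported
  xyz[3, 3] <- 1 + d_thr - 1e-6
  expect_equal(nrow(detectHbonds(xyz, topo)), 1L)
})

test_that("frame with no polar atoms yields no H-bonds", {
  atoms <- data.frame(eleno = 1:2, name = c("C22", "C23"), element = "C",
                      mass = 12, anum = 6L, resname = "DPP", resno = 1:2,
                      mol = 1:2, chain = "A", kind = "lipid", donor = FALSE,
                      acceptor = FALSE, hydrophobic = TRUE, charge = 0L,
                      leaflet = NA)
  topo <- Topology(atoms)
  xyz <- rbind(c(0, 0, 0), c(0, 0, 3))
  expect_equal(nrow(detectHbonds(xyz, topo)), 0L)
  ## but they do form one hydrophobic contact at 3 A and none at 6 A
  expect_equal(nrow(detectHPContacts(xyz, topo)), 1L)
  expect_equal(nrow(detectHPContacts(rbind(c(0, 0, 0), c(0, 0, 6)), topo)), 0L)
})

test_that("detectors match exhaustive brute-force enumeration", {
  p <- interactionParams()
  for (seed in c(1, 7, 23)) {
    rs <- randomSystem(n_mol = 35, seed = seed)
    expect_lte(nAtoms(rs$topology), 500)
    for (box in list(NULL, rs$box)) {
      got <- detectHbonds(rs$xyz, rs$topology, p, box)
      want <- bruteHbonds(rs$xyz, rs$topology, p, box)
      expect_equal(nrow(got), nrow(want))
      key <- function(i, h, j) paste(i, h, j)
      expect_setequal(key(got$i, got$h, got$j), key(want$i, want$h, want$j))

      gotHP <- detectHPContacts(rs$xyz, rs$topology, p, box)
      wantHP <- brutePairScan(rs$xyz, which(rs$topology$atoms$hydrophobic),
                              p$hp_cutoff, box, rs$topology$atoms,
                              exclude_same_residue = TRUE)
      expect_equal(nrow(gotHP), nrow(wantHP))
      if (nrow(wantHP))
        expect_setequal(paste(gotHP$i, gotHP$j),
                        paste(wantHP[, 1], wantHP[, 2]))

      a <- rs$topology$atoms
      gotIon <- detectIonic(rs$xyz, rs$topology, p, box)
      wantIonAll <- brutePairScan(rs$xyz, which(a$charge != 0),
                                  p$ionic_cutoff, box, a,
                                  exclude_same_residue = TRUE)
      if (nrow(wantIonAll)) {
        opp <- a$charge[wantIonAll[, 1]] * a$charge[wantIonAll[, 2]] < 0
        wantIon <- wantIonAll[opp, , drop = FALSE]
      } else wantIon <- wantIonAll
      expect_equal(nrow(gotIon), nrow(wantIon))
      if (nrow(wantIon))
        expect_setequal(paste(gotIon$i, gotIon$j),
                        paste(wantIon[, 1], wantIon[, 2]))

      gotBr <- detectWaterBridges(rs$xyz, rs$topology, p, box)
      wantBr <- bruteBridges(rs$xyz, rs$topology, p, box)
      expect_equal(nrow(gotBr), nrow(wantBr))
      if (nrow(wantBr))
        expect_setequal(paste(pmin(gotBr$i, gotBr$j), pmax(gotBr$i, gotBr$j)),
                        paste(wantBr[, 1], wantBr[, 2]))
    }
  }
})

test_that("interaction counts are invariant under rigid motion", {
  rs <- randomSystem(n_mol = 25, seed = 5)
  counts <- function(xyz) {
    r <- detectFrame(xyz, rs$topology, box = NULL)
    table(factor(r$kind, levels = c("hbond", "hp", "ionic", "water_bridge")))
  }
  base <- counts(rs$xyz)
  ## translation
  expect_equal(counts(sweep(rs$xyz, 2, c(13.7, -4.2, 8.9), "+")), base)
  ## rotation about an arbitrary axis
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(counts(rs$xyz %*% R), base)
})

test_that("water bridged to two atoms of the same molecule is not a bridge", {
  atoms <- data.frame(
    eleno = 1:6,
    name = c("O13", "O14", "O", "H1", "H2", "P"),
    element = c("O", "O", "O", "H", "H", "P"),
    mass = c(16, 16, 16, 1, 1, 31), anum = c(8L, 8L, 8L, 1L, 1L, 15L),
    resname = c("DPP", "DPP", "HOH", "HOH", "HOH", "DPP"),
    resno = c(1L, 1L, 2L, 2L, 2L, 1L),
    mol = c(1L, 1L, 2L, 2L, 2L, 1L), chain = "A",
    kind = c("lipid", "lipid", "water", "water", "water", "lipid"),
    donor = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    acceptor = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    hydrophobic = FALSE, charge = 0L, leaflet = NA)
  topo <- Topology(atoms, rbind(c(4L, 3L), c(5L, 3L)))
  ## water donates to both O13 and O14 of the same lipid
  xyz <- rbind(c(2.9, 0, 0), c(-2.9, 0, 0), c(0, 0, 0),
               c(1, 0, 0), c(-1, 0, 0), c(0, 0, 9))
  hb <- detectHbonds(xyz, topo)
  expect_equal(nrow(hb), 2L)
  expect_equal(nrow(detectWaterBridges(xyz, topo)), 0L)
})

test_that("interaction maps aggregate and conserve record counts", {
  expect_equal(sum(buildInteractionMap(memdyn:::.emptyRecords())), 0L)
  ## three H-bonds from residue 246 LYS to lipid O13 land in one cell
  rec <- data.frame(kind = "hbond", frame = 1:3, i = 1L, j = 2L, h = 3L,
                    water = NA_integer_, energy = 10,
                    mol_i = 1L, mol_j = 2L, name_i = "NZ", name_j = "O13",
                    resno_i = 246L, resname_i = "LYS",
                    resno_j = 5L, resname_j = "DPP",
                    scope = "lipid-protein", solvent_ion = NA)
  m <- buildInteractionMap(rec, "protein_residue")
  expect_equal(m["246 LYS", "O13"], 3L)
  expect_equal(sum(m), nrow(rec))
  ## symmetric atom-atom map: O22-O22 bridge on the diagonal
  rec2 <- rec
  rec2$kind <- "water_bridge"; rec2$name_i <- "O22"; rec2$name_j <- "O22"
  m2 <- buildInteractionMap(rec2, "atom")
  expect_equal(m2["O22", "O22"], 3L)
  ## map total always equals record count
  rs <- randomSystem(n_mol = 20, seed = 3)
  r <- detectFrame(rs$xyz, rs$topology, box = rs$box)
  expect_equal(sum(buildInteractionMap(r, "atom")), nrow(r))
})

test_that("time series report per-lipid participation correctly", {
  s <- sparseSystem(n_frames = 3, seed = 21, n_lip = 6)
  a <- s$topology$atoms
  lip <- unique(a$mol[a$kind == "lipid"])
  wat <- unique(a$mol[a$kind == "water"])
  ## plant water H-bonds to three lipids: 1, 1 and 2 bonds
  contacts <- list(
    list(kind = "hbond", a = list(mol = wat[1], name = "O"),
         b = list(mol = lip[1], name = "O13"),
         geometry = list(d = 2.0, theta = 180), expected_detected = TRUE),
    list(kind = "hbond", a = list(mol = wat[2], name = "O"),
         b = list(mol = lip[2], name = "O13"),
         geometry = list(d = 2.0, theta = 180), expected_detected = TRUE),
    list(kind = "hbond", a = list(mol = wat[3], name = "O"),
         b = list(mol = lip[3], name = "O13"),
         geometry = list(d = 2.0, theta = 180), expected_detected = TRUE),
    list(kind = "hbond", a = list(mol = wat[4], name = "O"),
         b = list(mol = lip[3], name = "O14"),
         geometry = list(d = 2.0, theta = 180), expected_detected = TRUE))
  pl <- plantContacts(s$trajectory, s$topology, contacts)
  ts <- interactionTimeSeries(pl$trajectory, s$topology,
                              scope = "lipid-water", kinds = "hbond")
  ## static planted trajectory: constant series
  expect_equal(length(unique(ts$series$n_hbond)), 1L)
  expect_equal(ts$series$n_hbond[1], 4L)
  expect_equal(ts$series$n_lipids[1], 3L)
  expect_equal(ts$series$per_lipid_min[1], 1L)
  expect_equal(ts$series$per_lipid_max[1], 2L)
  ## conservation: per-lipid counts sum to the total
  expect_equal(sum(table(ts$records$mol_j[ts$records$frame == 1])), 4L)
})
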
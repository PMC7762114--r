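## Brute-force oracles and small system builders used across tests.
## The oracles enumerate exhaustively and never share code with the
## package's neighbor-search path.

bruteMinImage <- function(x1, x2, box, span = 1) {
  best <- Inf
  for (ix in -span:span) for (iy in -span:span) for (iz in -span:span) {
    d <- x2 + c(ix, iy, iz) * box - x1
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

## all pairs of `idx` atoms within cutoff (min image), same-residue pairs
## optionally excluded
brutePairScan <- function(xyz, idx, cutoff, box, atoms = NULL,
                          exclude_same_residue = FALSE) {
  out <- list()
  n <- length(idx)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    i <- idx[a]; j <- idx[b]
    if (exclude_same_residue && !is.null(atoms) &&
        atoms$mol[i] == atoms$mol[j] && atoms$resno[i] == atoms$resno[j]) next
    d <- if (is.null(box)) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
         else bruteMinImage(xyz[i, ], xyz[j, ], box)
    if (d <= cutoff) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  t(vapply(out, identity, numeric(2)))
}

## exhaustive donor-H x acceptor scan through hbondEnergy()
bruteHbonds <- function(xyz, topology, params = interactionParams(),
                        box = NULL) {
  a <- topology$atoms
  b <- topology$bonds
  out <- list()
  thr <- hbondThreshold(params)
  for (r in seq_len(nrow(b))) {
    h <- b[r, 1]; don <- b[r, 2]
    if (!a$donor[don]) next
    for (acc in which(a$acceptor)) {
      if (acc == don) next
      E <- hbondEnergy(xyz[don, ], xyz[h, ], xyz[acc, ], box, params)
      if (E > thr) out[[length(out) + 1]] <- c(don, h, acc, E)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(0), h = integer(0), j = integer(0),
                      energy = numeric(0)))
  m <- t(vapply(out, identity, numeric(4)))
  data.frame(i = m[, 1], h = m[, 2], j = m[, 3], energy = m[, 4])
}

## bridges from the brute H-bond list: a water bonded to atoms of two
## distinct non-water molecules
bruteBridges <- function(xyz, topology, params = interactionParams(),
                         box = NULL) {
  a <- topology$atoms
  hb <- bruteHbonds(xyz, topology, params, box)
  if (!nrow(hb)) return(matrix(integer(0), 0, 2))
  wi <- a$kind[hb$i] == "water"
  wj <- a$kind[hb$j] == "water"
  hb <- hb[xor(wi, wj), , drop = FALSE]
  if (!nrow(hb)) return(matrix(integer(0), 0, 2))
  wmol <- ifelse(a$kind[hb$i] == "water", a$mol[hb$i], a$mol[hb$j])
  partner <- ifelse(a$kind[hb$i] == "water", hb$j, hb$i)
  out <- list()
  for (w in unique(wmol)) {
    p <- unique(partner[wmol == w])
    if (length(p) < 2) next
    for (a1 in seq_len(length(p) - 1)) for (a2 in (a1 + 1):length(p)) {
      if (a$mol[p[a1]] == a$mol[p[a2]]) next
      out[[length(out) + 1]] <- sort(c(p[a1], p[a2]))
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  t(vapply(out, identity, numeric(2)))
}

## random typed system for oracle-equivalence tests: molecules of mixed
## kinds with explicit flags, coordinates uniform in the box
randomSystem <- function(n_mol = 30, box = c(22, 20, 18), seed = 1) {
  set.seed(seed)
  rows <- list(); bonds <- list(); xyz <- list()
  nat <- 0L
  for (m in seq_len(n_mol)) {
    kind <- sample(c("lipid", "protein", "water"), 1,
                   prob = c(0.4, 0.3, 0.3))
    origin <- runif(3) * box
    if (kind == "water") {
      df <- data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                       resname = "HOH", donor = c(TRUE, FALSE, FALSE),
                       acceptor = c(TRUE, FALSE, FALSE),
                       hydrophobic = FALSE, charge = 0L)
      x <- rbind(origin, origin + c(0.8, 0.5, 0), origin + c(-0.8, 0.5, 0))
      bonds[[length(bonds) + 1]] <- rbind(c(nat + 2L, nat + 1L),
                                          c(nat + 3L, nat + 1L))
    } else {
      k <- sample(3:6, 1)
      el <- sample(c("C", "N", "O"), k, replace = TRUE, prob = c(0.5, 0.2, 0.3))
      df <- data.frame(name = paste0(el, seq_len(k)), element = el,
                       resname = if (kind == "lipid") "DPP" else "LEU",
                       donor = FALSE,
                       acceptor = el %in% c("O", "N") & runif(k) < 0.7,
                       hydrophobic = el == "C" & runif(k) < 0.7,
                       charge = ifelse(runif(k) < 0.15,
                                       sample(c(-1L, 1L), k, replace = TRUE), 0L))
      x <- sweep(matrix(runif(k * 3, -1.5, 1.5), k, 3), 2, origin, "+")
      ## give some N/O atoms a hydrogen (making them donors)
      for (i in which(el %in% c("N", "O") & runif(k) < 0.5)) {
        df <- rbind(df, data.frame(name = paste0("H", i), element = "H",
                                   resname = df$resname[1], donor = FALSE,
                                   acceptor = FALSE, hydrophobic = FALSE,
                                   charge = 0L))
        x <- rbind(x, x[i, ] + c(0.6, 0.6, 0.3))
        bonds[[length(bonds) + 1]] <- rbind(c(nat + nrow(df), nat + i))
        df$donor[i] <- TRUE
      }
    }
    df$mol <- m
    df$resno <- m
    df$kind <- kind
    rows[[m]] <- df
    xyz[[m]] <- x
    nat <- nat + nrow(df)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$mass <- memdyn:::elementMass(atoms$element)
  atoms$anum <- memdyn:::elementNumber(atoms$element)
  atoms$chain <- "A"
  atoms$leaflet <- NA_character_
  b <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  list(topology = Topology(atoms, b), xyz = do.call(rbind, xyz), box = box)
}

## small sparse bilayer + protein system used for planted-contact tests
sparseSystem <- function(n_frames = 2, seed = 11, n_lip = 4,
                         template = "minimal", minimal_k = 8,
                         n_waters = 4) {
  spec <- syntheticSpec(n_lipids_per_leaflet = n_lip,
                        lipid_template = template, minimal_k = minimal_k,
                        n_frames = n_frames, n_waters = n_waters,
                        n_ions = c(1, 1),
                        leaflet_D = c(upper = 0, lower = 0), rng_seed = seed)
  topo <- generateTopology(spec)
  list(spec = spec, topology = topo,
       trajectory = generateTrajectory(topo, spec))
}
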
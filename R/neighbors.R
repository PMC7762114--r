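## Neighbor search: all pairs within a cutoff, minimum-image convention.
## Cell lists are used when the box supports at least 3 cells per axis;
## otherwise a blocked brute-force scan. Both routes return identical pairs
## (enforced by tests against an exhaustive oracle).

## xa, xb: coordinate matrices (rows are atoms); ia, ib: atom indices the
## rows refer to. same_set = TRUE deduplicates to i < j.
pairsWithinCutoff <- function(xa, ia, xb, ib, cutoff, box = NULL,
                              same_set = FALSE) {
  if (length(ia) == 0 || length(ib) == 0)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  xa <- matrix(xa, ncol = 3)
  xb <- matrix(xb, ncol = 3)
  use_cells <- !is.null(box) && all(floor(box / cutoff) >= 3)
  pr <- if (use_cells) .cellPairs(xa, xb, cutoff, box)
        else .brutePairs(xa, xb, cutoff, box)
  if (!nrow(pr)) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  out <- data.frame(i = ia[pr$a], j = ib[pr$b], d = pr$d)
  if (same_set) {
    keep <- out$i < out$j
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$i, out$j), , drop = FALSE]
}

.brutePairs <- function(xa, xb, cutoff, box) {
  na <- nrow(xa); nb <- nrow(xb)
  chunk <- max(1L, floor(4e6 / nb))
  res <- vector("list", ceiling(na / chunk))
  k <- 0L
  for (s in seq(1L, na, by = chunk)) {
    e <- min(na, s + chunk - 1L)
    dx <- outer(xa[s:e, 1], xb[, 1], "-")
    dy <- outer(xa[s:e, 2], xb[, 2], "-")
    dz <- outer(xa[s:e, 3], xb[, 3], "-")
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    d2 <- dx^2 + dy^2 + dz^2
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    k <- k + 1L
    res[[k]] <- data.frame(a = hit[, 1] + s - 1L, b = hit[, 2],
                           d = sqrt(d2[hit]))
  }
  do.call(rbind, res[seq_len(k)])
}

.cellPairs <- function(xa, xb, cutoff, box) {
  nc <- pmax(3L, floor(box / cutoff))
  cell <- box / nc
  keyOf <- function(x) {
    w <- x - sweep(floor(sweep(x, 2, box, "/")), 2, box, "*")  # wrap into box
    ci <- pmin(floor(sweep(w, 2, cell, "/")), matrix(nc - 1L, nrow(w), 3, byrow = TRUE))
    ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3])
  }
  cia <- keyOf(xa)
  cib <- keyOf(xb)
  grpB <- split(seq_len(nrow(xb)), cib)
  ## decompose A cell key back into indices once
  ax <- cia %% nc[1]; rest <- cia %/% nc[1]
  ay <- rest %% nc[2]; az <- rest %/% nc[2]
  res <- list(); k <- 0L
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    nx <- (ax + ox) %% nc[1]
    ny <- (ay + oy) %% nc[2]
    nz <- (az + oz) %% nc[3]
    nkey <- nx + nc[1] * (ny + nc[2] * nz)
    grpA <- split(seq_len(nrow(xa)), nkey)
    shared <- intersect(names(grpA), names(grpB))
    for (key in shared) {
      aa <- grpA[[key]]; bb <- grpB[[key]]
      pa <- rep(aa, times = length(bb))
      pb <- rep(bb, each = length(aa))
      d <- minimumImageDistance(xa[pa, , drop = FALSE], xb[pb, , drop = FALSE], box)
      keep <- d <= cutoff
      if (any(keep)) {
        k <- k + 1L
        res[[k]] <- data.frame(a = pa[keep], b = pb[keep], d = d[keep])
      }
    }
  }
  if (!k) return(data.frame(a = integer(0), b = integer(0), d = numeric(0)))
  out <- do.call(rbind, res)
  unique(out)
}
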
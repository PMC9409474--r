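# Shared helpers: raw PDB text fixtures built in code, and independent
# oracles (circumcircle through three points; dense-sampling ellipse
# projection) kept deliberately separate from the package's own
# algorithms.

vnorm_test <- function(v) sqrt(sum(v * v))

pdb_atom_line <- function(serial, name, alt, resn, chain, resno, xyz,
                          occ = 1, icode = "") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, 0, substr(name, 1, 1))
}

# five-residue poly-alanine PDB text from the package's builder geometry
write_polyala_pdb <- function(path, n = 5, phi = -57, psi = -47,
                              res_number = seq_len(n), chain = "A",
                              drop_atom = NULL) {
  d <- dihedral_series(res_number, rep(phi, n), rep(psi, n))
  ch <- build_backbone(d, chain_id = chain)
  lines <- character(0)
  serial <- 0
  for (i in seq_len(n)) {
    for (at in c("N", "CA", "C", "O")) {
      if (!is.null(drop_atom) && i == drop_atom$res && at == drop_atom$atom) next
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, at, " ", "ALA", chain,
                                      res_number[i], ch[[at]][i, ]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

# exact circumcircle through three points: the independent oracle for
# the algebraic circle fit
circle3 <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
  list(center = c(ux, uy), r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# dense-sampling projection oracle: global scan at 1 degree over the 9
# periodic images, then an exhaustive 0.01 degree sweep in a +/-2 degree
# window around the coarse minimiser
oracle_project <- function(phi, psi, e, dt = 0.01) {
  shifts <- as.matrix(expand.grid(c(-360, 0, 360), c(-360, 0, 360)))
  tc <- seq(0, 359, by = 1)
  pc <- ellipse_point(e, tc)
  n <- length(phi)
  out <- data.frame(distance = numeric(n), t = numeric(n))
  for (i in seq_len(n)) {
    coarse <- matrix(NA_real_, nrow(shifts), 2) # min d2, argmin t
    for (s in seq_len(nrow(shifts))) {
      q <- c(phi[i] + shifts[s, 1], psi[i] + shifts[s, 2])
      d2 <- (pc[, 1] - q[1])^2 + (pc[, 2] - q[2])^2
      k <- which.min(d2)
      coarse[s, ] <- c(d2[k], tc[k])
    }
    # exhaustive 0.01-degree sweep around the coarse minimisers of every
    # image that could still win (within a safe 5-degree coarse margin)
    dmin <- sqrt(min(coarse[, 1]))
    cand <- which(sqrt(coarse[, 1]) <= dmin + 5)
    best <- c(Inf, NA)
    for (s in cand) {
      q <- c(phi[i] + shifts[s, 1], psi[i] + shifts[s, 2])
      tf <- seq(coarse[s, 2] - 2, coarse[s, 2] + 2, by = dt)
      pf <- ellipse_point(e, tf)
      d2f <- (pf[, 1] - q[1])^2 + (pf[, 2] - q[2])^2
      k <- which.min(d2f)
      if (d2f[k] < best[1]) best <- c(d2f[k], tf[k] %% 360)
    }
    out$distance[i] <- sqrt(best[1])
    out$t[i] <- best[2]
  }
  out
}

# minimal chain whose projected C-alpha coordinates are given 2D points
# (z = 0) and whose carbonyls all point +Z (non-degenerate frame): lets
# compute_R be exercised on exactly-known geometry
fake_oriented_chain <- function(pts2d) {
  n <- nrow(pts2d)
  ca <- cbind(pts2d, 0)
  backbone_chain(seq_len(n), rep("ALA", n),
                 N = ca + matrix(rep(c(-1, 0, 0), n), ncol = 3, byrow = TRUE),
                 CA = ca,
                 C = ca + matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE),
                 O = ca + matrix(rep(c(1, 0, 1.23), n), ncol = 3, byrow = TRUE))
}

rot_axis_test <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# synthetic chain whose consecutive C=O orientation vectors are set
# exactly: the geometric-limit construction for the V angle
chain_with_co <- function(co_vectors) {
  n <- nrow(co_vectors) + 1
  d <- dihedral_series(seq_len(n), rep(180, n), rep(180, n))
  ch <- build_backbone(d)
  for (i in seq_len(n - 1)) ch$O[i, ] <- ch$C[i, ] + co_vectors[i, ]
  ch
}
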
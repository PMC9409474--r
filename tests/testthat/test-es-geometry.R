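test_that("pentapeptide construction recovers its torsions and limits", {
  p <- build_pentapeptide(-57, -47)
  d <- compute_dihedrals(p)
  expect_equal(d$phi[2:5], rep(-57, 4), tolerance = 1e-6)
  expect_equal(d$psi[1:4], rep(-47, 4), tolerance = 1e-6)
  # extended limit: the projected trace in the common frame is collinear
  pe <- orient_common_frame(build_pentapeptide(180, 180))
  sv <- svd(sweep(pe$CA[, 1:2], 2, colMeans(pe$CA[, 1:2])))$d
  expect_lt(sv[2], 1e-3)
})

test_that("common-frame orientation is rigid, canonical and idempotent", {
  p <- build_pentapeptide(-57, -47)
  q <- orient_common_frame(p)
  # rigidity: all pairwise CA/N/C/O distances preserved
  for (at in c("N", "CA", "C", "O"))
    expect_equal(as.numeric(dist(q[[at]])), as.numeric(dist(p[[at]])),
                 tolerance = 1e-9)
  # mean C=O along +Z, CA centroid at origin
  co <- q$O - q$C
  co <- co / sqrt(rowSums(co^2))
  m <- colMeans(co); m <- m / vnorm_test(m)
  expect_gt(m[3], 0.999)
  expect_equal(colMeans(q$CA), c(0, 0, 0), tolerance = 1e-9)
  # idempotence
  q2 <- orient_common_frame(q)
  for (at in c("N", "CA", "C", "O"))
    expect_equal(q2[[at]], q[[at]], tolerance = 1e-9)
})

test_that("V angle hits its geometric limits for parallel/antiparallel planes", {
  par4 <- matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE)
  expect_equal(compute_V(chain_with_co(par4)), 0, tolerance = 1e-9)
  anti4 <- par4 * rep(c(1, -1), each = 1, length.out = 4)
  anti4 <- matrix(c(0, 0, 1, 0, 0, -1, 0, 0, 1, 0, 0, -1), ncol = 3, byrow = TRUE)
  expect_equal(compute_V(chain_with_co(anti4)), 180, tolerance = 1e-9)
  quarter <- matrix(c(0, 0, 1, 0, 1, 0, 0, 0, 1, 0, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(compute_V(chain_with_co(quarter)), 90, tolerance = 1e-9)
  # fewer than 2 planes is an error
  expect_error(compute_V(build_backbone(dihedral_series(1:2, c(NA, -60), c(-40, NA)))),
               "planes")
})

test_that("V is invariant under rigid motion and inversion-symmetric", {
  set.seed(3)
  for (k in 1:5) {
    phi <- runif(1, -180, 180); psi <- runif(1, -180, 180)
    p <- build_pentapeptide(phi, psi)
    v0 <- compute_V(p)
    ax <- rnorm(3)
    p2 <- transform_chain(p, R = rot_axis_test(ax, runif(1, 0, 360)),
                          t = rnorm(3, sd = 10))
    expect_equal(compute_V(p2), v0, tolerance = 1e-9)
    # inversion maps the R-helix side onto the L-helix side without
    # changing inter-plane angles
    vm <- compute_V(build_pentapeptide(-phi, -psi))
    expect_equal(vm, v0, tolerance = 1e-6)
  }
})

test_that("circle fit matches the exact circumcircle oracle", {
  set.seed(11)
  for (k in 1:10) {
    r <- runif(1, 1.5, 40)
    cen <- runif(2, -5, 5)
    th <- sort(runif(5, 0, 1.8 * pi))
    pts <- cbind(cen[1] + r * cos(th), cen[2] + r * sin(th))
    ch <- fake_oriented_chain(pts)
    got <- compute_R(ch)
    oracle <- circle3(pts[1, ], pts[3, ], pts[5, ])
    expect_false(got$capped)
    expect_equal(got$R, oracle$r, tolerance = 1e-6)
    expect_equal(got$R, r, tolerance = 1e-6)
    expect_equal(got$lnR, log(r), tolerance = 1e-6)
  }
})

test_that("radius caps in the beta limit and grows from the helix", {
  ext <- orient_common_frame(build_pentapeptide(180, 180))
  r_ext <- compute_R(ext)
  expect_true(r_ext$capped)
  expect_equal(r_ext$R, 1e6)
  r_helix <- compute_R(orient_common_frame(build_pentapeptide(-57, -47)))
  r_mid <- compute_R(orient_common_frame(build_pentapeptide(-100, 100)))
  r_ab <- compute_R(orient_common_frame(build_pentapeptide(-135, 135)))
  expect_lt(r_helix$R, r_mid$R)
  expect_lt(r_mid$R, r_ab$R)
  expect_equal(r_helix$R, 2.27, tolerance = 0.05)
  # coincident projected points are a degenerate-geometry error
  pts <- matrix(rep(c(0.5, 0.5), 5), ncol = 2, byrow = TRUE)
  expect_error(compute_R(fake_oriented_chain(pts)), "degenerate")
})

test_that("rv map covers the grid exactly and matches single-point values", {
  map <- generate_rv_map(step = 30)
  expect_identical(nrow(map), 144L)
  expect_false(any(duplicated(map[, c("phi", "psi")])))
  expect_setequal(unique(map$phi), seq(-150, 180, by = 30))
  coarse <- generate_rv_map(step = 90)
  expect_identical(nrow(coarse), 16L)
  expect_true(all(is.finite(coarse$V)))
  expect_true(all(is.finite(coarse$lnR)))
  i <- which(map$phi == -60 & map$psi == -60)
  p <- orient_common_frame(build_pentapeptide(-60, -60))
  expect_equal(map$V[i], compute_V(p), tolerance = 1e-9)
  expect_equal(map$lnR[i], compute_R(p)$lnR, tolerance = 1e-9)
  expect_error(generate_rv_map(step = 7), "divisor")
  # inversion symmetry of the map surface
  j <- which(map$phi == 60 & map$psi == 60)
  expect_equal(map$V[i], map$V[j], tolerance = 1e-6)
})

test_that("co-orientation classifies parallel, antiparallel and intermediate", {
  par2 <- chain_with_co(matrix(rep(c(0, 0, 1), 2), ncol = 3, byrow = TRUE))
  expect_identical(co_orientation(par2, 1), "parallel")
  anti2 <- chain_with_co(matrix(c(0, 0, 1, 0, 0, -1), ncol = 3, byrow = TRUE))
  expect_identical(co_orientation(anti2, 1), "antiparallel")
  mid2 <- chain_with_co(matrix(c(0, 0, 1, 0, 1, 0), ncol = 3, byrow = TRUE))
  expect_identical(co_orientation(mid2, 1), "intermediate")
  # interior positions of an extended beta fixture are antiparallel
  ch <- build_backbone(make_ideal("extended", 6))
  for (i in 2:4) expect_identical(co_orientation(ch, i), "antiparallel")
  expect_error(co_orientation(ch, 99), "out of range")
})
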
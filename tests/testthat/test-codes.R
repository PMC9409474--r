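test_that("distance to the Psi = -Phi line follows the closed form", {
  expect_equal(dist_to_antidiagonal(-135, 135), 0)
  expect_equal(dist_to_antidiagonal(-135, 145), 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(dist_to_antidiagonal(0, 0), 0)
  # invariance under reflection across the line: (phi,psi) -> (-psi,-phi)
  set.seed(5)
  phi <- runif(50, -180, 180); psi <- runif(50, -180, 180)
  expect_equal(dist_to_antidiagonal(-psi, -phi),
               dist_to_antidiagonal(phi, psi), tolerance = 1e-12)
})

test_that("classification hits the canonical zone examples", {
  zc <- zone_config()
  expect_identical(classify(-57, -47, zc), "R")
  expect_identical(classify(57, 47, zc), "L")
  expect_identical(classify(-135, 135, zc), "AB")
  expect_identical(classify(-90, 45, zc), "M")
  expect_identical(classify(-70, 150, zc), "F")
  expect_identical(classify(-120, 150, zc), "E")
  expect_identical(classify(0, -170, zc), "other")
  expect_true(is.na(classify(NA, 10, zc)))
})

test_that("every defined residue receives exactly one code and counts add up", {
  zc <- zone_config()
  set.seed(9)
  phi <- runif(500, -180, 180); psi <- runif(500, -180, 180)
  code <- classify(phi, psi, zc)
  expect_false(any(is.na(code)))
  expect_true(all(code %in% c("AB", "R", "L", "E", "F", "M", "other")))
  d <- dihedral_series(seq_along(phi), phi, psi)
  rep <- dispersion_report(d, zc)
  cnt <- function(cl) rep$count[rep$class == cl]
  expect_identical(cnt("E+F"), cnt("E") + cnt("F"))
  # AB residues are members of the E dispersion band
  expect_gte(cnt("E"), sum(code == "AB"))
  expect_identical(cnt("E+F"), sum(code %in% c("AB", "E", "F")))
})

test_that("dispersion means follow their definitions", {
  zc <- zone_config()
  # all members at one point: zero dispersion
  d0 <- make_ideal("R-helix", 7)
  r0 <- dispersion_report(d0, zc)
  expect_equal(r0$mean_distance[r0$class == "R-helix"], 0)
  expect_identical(r0$count[r0$class == "R-helix"], 7L)
  # two R points 10 degrees apart: mean centroid distance 5
  d2 <- dihedral_series(1:2, c(-57, -67), c(-47, -47))
  r2 <- dispersion_report(d2, zc)
  expect_equal(r2$mean_distance[r2$class == "R-helix"], 5)
  # beta means are distances to the line
  d3 <- dihedral_series(1:2, c(-135, -125), c(135, 145))
  r3 <- dispersion_report(d3, zc)
  expect_equal(r3$mean_distance[r3$class == "E"],
               mean(c(0, 20 / sqrt(2))), tolerance = 1e-9)
  # empty classes report count 0 and undefined mean
  expect_identical(r3$count[r3$class == "L-helix"], 0L)
  expect_true(is.na(r3$mean_distance[r3$class == "L-helix"]))
  expect_error(dispersion_report(dihedral_series(1, NA, NA)), "no residues")
})

test_that("synthetic amyloid stand-in shows the tight-dispersion signature", {
  # the flat amyloid chain concentrates on Psi = -Phi and on single
  # helical residues: its R, L and E dispersions must all be tighter
  # than the broad native-like stand-in's (synthetic data, not 6SDZ)
  zc <- zone_config()
  pair <- make_synthetic_pair(n = 120, seed = 4)
  ra <- dispersion_report(pair$amyloid, zc)
  rn <- dispersion_report(pair$native, zc)
  g <- function(r, cl) r$mean_distance[r$class == cl]
  expect_lt(g(ra, "E"), g(rn, "E"))
  expect_lt(g(ra, "R-helix"), g(rn, "R-helix"))
  cntE <- function(r) r$count[r$class == "E+F"]
  expect_identical(cntE(ra), ra$count[ra$class == "E"] + ra$count[ra$class == "F"])
})

test_that("structure comparison pairs by residue number and filters by code", {
  zc <- zone_config()
  d <- make_ideal("R-helix", 10)
  same <- compare_structures(d, d, zc)
  expect_identical(same$native_code, same$amyloid_code)
  # constructed R -> AB migration
  native <- dihedral_series(1:8, rep(-57, 8), rep(-47, 8))
  amyloid <- dihedral_series(1:8, rep(-135, 8), rep(135, 8))
  mig <- compare_structures(native, amyloid, zc)
  expect_true(all(mig$native_code == "R" & mig$amyloid_code == "AB"))
  rn <- compare_structures(native, amyloid, zc, mode = "R_in_native")
  expect_identical(nrow(rn), 8L)
  # residues absent from one structure are excluded and reported
  target <- dihedral_series(c(1:3, 20:22), rep(-135, 6), rep(135, 6))
  part <- compare_structures(native, target, zc)
  expect_identical(part$res_number, 1:3)
  expect_true("20|" %in% attr(part, "skipped")$amyloid_only)
  expect_error(compare_structures(native, dihedral_series(99, -60, -40), zc),
               "no residue")
})

test_that("mutation counting matches constructed differences", {
  d <- dihedral_series(1:6, rep(-57, 6), rep(-47, 6))
  a <- build_backbone(d, seq = rep("ALA", 6))
  expect_identical(as.integer(count_mutations(a, a)), 0L)
  b <- build_backbone(d, seq = c("ALA", "GLY", "ALA", "SER", "ALA", "VAL"))
  expect_identical(as.integer(count_mutations(a, b)), 3L)
  # unmatched positions are excluded and reported
  d2 <- dihedral_series(4:9, rep(-57, 6), rep(-47, 6))
  cshift <- build_backbone(d2, seq = rep("ALA", 6))
  m <- count_mutations(a, cshift)
  expect_identical(as.integer(m), 0L)
  expect_length(attr(m, "unmatched")$a_only, 3)
  expect_error(count_mutations(a, build_backbone(dihedral_series(50:52, rep(-57, 3), rep(-47, 3)))),
               "share no residue")
})
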
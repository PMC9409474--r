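test_that("parabola fit recovers exact coefficients and needs enough points", {
  V <- seq(5, 175, by = 5)
  pts <- data.frame(phi = 0, psi = 0, V = V,
                    lnR = 0.001 * V^2 + 0.01 * V + 1, capped = FALSE)
  fit <- fit_parabola(pts, mask = NULL)
  expect_equal(unname(fit$coef), c(0.001, 0.01, 1), tolerance = 1e-9)
  expect_lt(fit$residual, 1e-9)
  expect_error(fit_parabola(pts, mask = function(phi, psi) rep(FALSE, length(phi))),
               "at least 3")
})

test_that("conic fit recovers a known ellipse exactly", {
  truth <- ellipse_path(center = c(-10, 0), axes = c(120, 80), tilt = 45)
  t <- seq(0, 350, by = 10)
  pts <- ellipse_point(truth, t)
  got <- fit_ellipse_conic(pts[, 1], pts[, 2])
  expect_equal(got$center, truth$center, tolerance = 1e-6)
  expect_equal(got$axes, truth$axes, tolerance = 1e-6)
  expect_equal(got$tilt, truth$tilt, tolerance = 1e-6)
})

test_that("masked and unmasked parabola fits on a generated map are deterministic", {
  map <- generate_rv_map(step = 20)
  zc <- zone_config()
  f1 <- fit_parabola(map, mask = zc)
  f2 <- fit_parabola(map, mask = zc)
  expect_identical(f1$coef, f2$coef)
  f_un <- fit_parabola(map, mask = NULL)
  expect_true(all(is.finite(c(f1$coef, f_un$coef))))
  expect_gt(f1$residual, 0)
  expect_gt(f_un$residual, 0)
  expect_gt(f_un$n, f1$n)
})

test_that("the shipped default path satisfies the zone layout", {
  e <- default_ellipse()
  zc <- zone_config()
  # passes within the configured zone tolerance of both helix zones and
  # the amyloid representative on the Psi = -Phi line
  pr <- project_to_ellipse(c(zc$representatives$R[1], zc$representatives$L[1],
                             zc$representatives$AB[1]),
                           c(zc$representatives$R[2], zc$representatives$L[2],
                             zc$representatives$AB[2]), e)
  expect_true(all(pr$distance <= zc$zone_tolerance))
  # crosses the line Psi = -Phi (sign change of phi(t) + psi(t))
  cr <- ellipse_line_crossings(e)
  expect_length(cr, 2)
  cp <- ellipse_point(e, cr, wrap = TRUE)
  expect_equal(cp[, 1] + cp[, 2], c(0, 0), tolerance = 1e-6)
  # one crossing on the amyloid side (phi < 0, psi > 0)
  expect_true(any(cp[, 1] < 0 & cp[, 2] > 0))
})

test_that("frozen default ellipse reproduces its own derivation", {
  e_frozen <- default_ellipse()
  e_new <- es_derive_default_ellipse(step = 5, tol = 0.5)
  expect_equal(e_new$center, e_frozen$center, tolerance = 1e-6)
  expect_equal(e_new$axes, e_frozen$axes, tolerance = 1e-6)
  expect_equal(e_new$tilt, e_frozen$tilt, tolerance = 1e-6)
})

test_that("projection matches the dense-sampling oracle", {
  e <- default_ellipse()
  set.seed(101)
  n <- 1000
  phi <- runif(n, -180, 180); psi <- runif(n, -180, 180)
  mine <- project_to_ellipse(phi, psi, e)
  oracle <- oracle_project(phi, psi, e)
  expect_lt(max(abs(mine$distance - oracle$distance)), 0.05)
})

test_that("projection fixed points, center distance and idempotence", {
  e_ax <- ellipse_path(center = c(0, 0), axes = c(100, 40), tilt = 0)
  # a point on the ellipse maps to itself
  onp <- ellipse_point(e_ax, 77)
  pr <- project_to_ellipse(onp[1], onp[2], e_ax)
  expect_equal(c(pr$phie, pr$psie), as.numeric(onp), tolerance = 1e-6)
  expect_lt(pr$distance, 1e-6)
  # the center projects at semi-minor distance
  prc <- project_to_ellipse(0, 0, e_ax)
  expect_equal(prc$distance, 40, tolerance = 1e-6)
  # idempotence on a chain, and identical inputs share one projection
  e <- default_ellipse()
  d <- make_ideal("R-helix", 13)
  p1 <- project_chain(d, e)
  p2 <- project_chain(p1, e)
  expect_equal(p2$phi, p1$phi, tolerance = 1e-6)
  expect_equal(p2$psi, p1$psi, tolerance = 1e-6)
  expect_equal(length(unique(round(p1$phi, 6))), 1L)
  expect_true(all(p2$distance < 1e-6))
})

test_that("undefined angles survive chain projection untouched", {
  e <- default_ellipse()
  d <- dihedral_series(1:4, c(NA, -57, -57, -57), c(-47, -47, -47, NA))
  pr <- project_chain(d, e)
  expect_true(is.na(pr$phi[1]))
  expect_true(is.na(pr$psi[4]))
  expect_false(any(is.na(pr$phi[2:4])))
})

test_that("V and lnR behave as the model demands along the derived arc", {
  # from the helix-zone entry toward the beta crossing of the default
  # path: V never decreases (small numerical slack) and the radius ends
  # above its helix-zone start after the compressed-helix dip
  e <- default_ellipse()
  pr <- project_to_ellipse(-57, -47, e)
  cr <- ellipse_line_crossings(e)
  cp <- ellipse_point(e, cr, wrap = TRUE)
  tX <- cr[cp[, 1] < 0][1]
  dt <- (tX - pr$t) %% 360
  if (dt > 180) dt <- dt - 360
  ts <- pr$t + seq(0, dt, length.out = 45)
  pts <- ellipse_point(e, ts, wrap = TRUE)
  vv <- lr <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- orient_common_frame(build_pentapeptide(pts[i, 1], pts[i, 2]))
    vv[i] <- compute_V(p)
    lr[i] <- compute_R(p)$lnR
  }
  expect_true(all(diff(vv) > -0.5))
  expect_gt(vv[length(vv)] - vv[1], 100)
  expect_gt(lr[length(lr)], lr[1])
})
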
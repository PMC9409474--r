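#' Elliptical early-stage path in the Phi-Psi plane
#'
#' The early-stage model assumes that backbone-only folding intermediates
#' occupy a one-dimensional subspace of the Ramachandran plot: an ellipse
#' passing through the right-handed helical zone, the left-handed helical
#' zone and the beta field around the Psi = -Phi line. Points are mapped
#' onto it by shortest-distance projection, giving the (Phie, Psie)
#' coordinates.
#'
#' @param center numeric length-2, ellipse center (phi0, psi0) in degrees.
#' @param axes numeric length-2, semi-axes (a, b) in degrees, both > 0.
#' @param tilt rotation of the ellipse axes in the Phi-Psi plane, degrees.
#' @param provenance optional character noting how the parameters were
#'   obtained (derivation hash for the shipped default).
#' @return An object of class `ellipse_path`.
#' @export
ellipse_path <- function(center, axes, tilt, provenance = "user") {
  stopifnot(length(center) == 2, length(axes) == 2, all(axes > 0))
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 tilt = as.numeric(tilt)[1], provenance = provenance),
            class = "ellipse_path")
}

#' @export
print.ellipse_path <- function(x, ...) {
  cat(sprintf(paste0("ellipse_path: center (%.2f, %.2f), semi-axes ",
                     "(%.2f, %.2f), tilt %.2f deg [%s]\n"),
              x$center[1], x$center[2], x$axes[1], x$axes[2], x$tilt,
              x$provenance))
  invisible(x)
}

#' Evaluate the ellipse at parameter t
#'
#' @param e an [ellipse_path()].
#' @param t parameter in degrees (periodic with period 360).
#' @param wrap wrap the result into (-180, 180]? Default `FALSE` so that
#'   segment interpolation stays continuous.
#' @return matrix with columns phi, psi (one row per t).
#' @export
ellipse_point <- function(e, t, wrap = FALSE) {
  tr <- t / DEG
  th <- e$tilt / DEG
  x <- e$axes[1] * cos(tr)
  y <- e$axes[2] * sin(tr)
  phi <- e$center[1] + cos(th) * x - sin(th) * y
  psi <- e$center[2] + sin(th) * x + cos(th) * y
  if (wrap) { phi <- wrap_angle(phi); psi <- wrap_angle(psi) }
  cbind(phi = phi, psi = psi)
}

#' The default elliptical path shipped with the package
#'
#' Reads the frozen configuration derived once by
#' [es_derive_default_ellipse()] (R/V map at 5 degree step, default
#' low-energy mask, parabola tolerance 0.5). Freezing the derived
#' parameters into a versioned config keeps every downstream number
#' reproducible without re-running the map generation.
#'
#' @param path YAML config; default is the file shipped with the package.
#' @return An [ellipse_path()].
#' @export
default_ellipse <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ellipse-default.yaml", package = "espath",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  ellipse_path(cfg$center, cfg$axes, cfg$tilt, provenance = cfg$provenance)
}

#' Re-run the full default-path derivation
#'
#' Convenience wrapper for generate_rv_map -> fit_parabola ->
#' derive_ellipse with the shipped defaults; used to regenerate (and to
#' verify) the frozen configuration read by [default_ellipse()].
#'
#' @param step grid step in degrees.
#' @param tol parabola-agreement tolerance on lnR.
#' @param zones a [zone_config()].
#' @return An [ellipse_path()].
#' @export
es_derive_default_ellipse <- function(step = 5, tol = 0.5,
                                      zones = zone_config()) {
  map <- generate_rv_map(step = step)
  fit <- fit_parabola(map, mask = zones)
  derive_ellipse(map, fit, tol = tol, mask = zones)
}

#' Fit the parabolic ln(R)-versus-V relation
#'
#' Least-squares fit of lnR = c2 V^2 + c1 V + c0 over map points that lie
#' inside the low-energy mask and are not capped. The parabola expresses
#' the relaxed radius of curvature expected at each V angle and is the
#' selection criterion from which the elliptical path is derived.
#'
#' @param points an `rv_map` (or data frame with phi, psi, V, lnR, capped).
#' @param mask predicate `function(phi, psi) -> logical`, or a zone config
#'   (see [zone_config()]) whose low-energy polygons are used. `NULL`
#'   disables masking.
#' @return list of class `parabola_fit` with `coef` (c2, c1, c0) and
#'   `residual` (RMS).
#' @export
fit_parabola <- function(points, mask = zone_config()) {
  keep <- !points$capped
  if (!is.null(mask)) {
    pred <- if (is.function(mask)) mask else low_energy_mask(mask)
    keep <- keep & pred(points$phi, points$psi)
  }
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < 3 || length(unique(pts$V)) < 3)
    stop("need at least 3 usable map points with distinct V to fit a parabola")
  fit <- stats::lm(lnR ~ I(V^2) + V, data = pts)
  cf <- stats::coef(fit)
  structure(list(coef = c(c2 = unname(cf["I(V^2)"]), c1 = unname(cf["V"]),
                          c0 = unname(cf["(Intercept)"])),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 n = nrow(pts)),
            class = "parabola_fit")
}

#' Predict lnR from a parabola fit at given V
#' @param fit a `parabola_fit`.
#' @param V degrees.
#' @export
predict_parabola <- function(fit, V) {
  fit$coef[["c2"]] * V^2 + fit$coef[["c1"]] * V + fit$coef[["c0"]]
}

#' Derive the elliptical path from the R/V map
#'
#' Selects the map points that are relaxed in the model's sense — inside
#' the low-energy mask, not capped, and with lnR within `tol` of the
#' parabola's prediction at their V — and fits an ellipse to their
#' (Phi, Psi) coordinates by direct algebraic conic least squares
#' constrained to an ellipse. The low-energy restriction is what links
#' the helical and beta basins into a single closed path: without it the
#' parabola-agreement band alone is a two-dimensional swath of the map.
#'
#' @param map an `rv_map`.
#' @param fit a `parabola_fit` from [fit_parabola()].
#' @param tol agreement band on lnR.
#' @param mask predicate or [zone_config()] supplying the low-energy
#'   polygons; `NULL` disables the restriction.
#' @param include_capped treat capped points as satisfying the condition;
#'   default `FALSE` (capped points are sentinels, not measurements).
#' @return An [ellipse_path()] with provenance `"derived"`.
#' @export
derive_ellipse <- function(map, fit, tol = 0.5, mask = zone_config(),
                           include_capped = FALSE) {
  ok <- !map$capped & abs(map$lnR - predict_parabola(fit, map$V)) <= tol
  if (include_capped) ok <- ok | map$capped
  if (!is.null(mask)) {
    pred <- if (is.function(mask)) mask else low_energy_mask(mask)
    ok <- ok & pred(map$phi, map$psi)
  }
  sel <- map[ok, , drop = FALSE]
  if (nrow(sel) < 6)
    stop("fewer than 6 map points satisfy the parabola condition; cannot fit an ellipse")
  e <- fit_ellipse_conic(sel$phi, sel$psi)
  e$provenance <- "derived"
  e$n_points <- nrow(sel)
  e
}

#' Direct least-squares ellipse fit (Fitzgibbon) to 2D points
#'
#' @param x,y point coordinates.
#' @return An [ellipse_path()].
#' @export
fit_ellipse_conic <- function(x, y) {
  if (length(x) < 6) stop("need at least 6 points for a conic fit")
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (sc < 1e-12) stop("degenerate point cloud")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T
  Cinv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  M <- Cinv %*% M
  ev <- eigen(M)
  va <- Re(ev$vectors)
  cond <- 4 * va[1, ] * va[3, ] - va[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) stop("conic fit degenerated to a non-ellipse")
  a1 <- va[, idx[1]]
  coefs <- c(a1, T %*% a1) # A B C D E F in scaled coords
  # un-scale: substitute xs = (x-mx)/sc, ys = (y-my)/sc
  A <- coefs[1] / sc^2
  B <- coefs[2] / sc^2
  C <- coefs[3] / sc^2
  D <- -2 * coefs[1] * mx / sc^2 - coefs[2] * my / sc^2 + coefs[4] / sc
  E <- -2 * coefs[3] * my / sc^2 - coefs[2] * mx / sc^2 + coefs[5] / sc
  F <- coefs[1] * mx^2 / sc^2 + coefs[2] * mx * my / sc^2 +
    coefs[3] * my^2 / sc^2 - coefs[4] * mx / sc - coefs[5] * my / sc + coefs[6]
  conic_to_ellipse(c(A, B, C, D, E, F))
}

#' Convert conic coefficients (A,B,C,D,E,F) to center/axes/tilt form
#' @noRd
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  det2 <- 4 * A * C - B^2
  if (det2 <= 0) stop("conic is not an ellipse")
  x0 <- (B * E - 2 * C * D) / det2
  y0 <- (B * D - 2 * A * E) / det2
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(Mq, symmetric = TRUE)
  ax2 <- -F0 / ev$values
  if (any(ax2 <= 0)) stop("conic is not a real ellipse")
  # order: first eigenvector defines the tilt axis (semi-axis a)
  a <- sqrt(ax2[1]); b <- sqrt(ax2[2])
  v <- ev$vectors[, 1]
  tilt <- atan2(v[2], v[1]) * DEG
  # canonical form: a >= b, tilt in (-90, 90]
  if (b > a) { tmp <- a; a <- b; b <- tmp; v <- ev$vectors[, 2]; tilt <- atan2(v[2], v[1]) * DEG }
  tilt <- tilt - 180 * floor((tilt + 90) / 180)
  if (tilt <= -90) tilt <- tilt + 180
  ellipse_path(c(x0, y0), c(a, b), tilt)
}

#' Shortest-distance projection of a point onto the elliptical path
#'
#' Finds the ellipse point minimising the Euclidean distance in degrees,
#' honouring the torus topology of the Ramachandran space: the nine
#' periodic images of the query (shifts of +/-360 in each coordinate) are
#' all considered and the overall minimum wins. The per-image minimisation
#' uses a coarse parameter scan refined by Newton iterations on the
#' distance derivative. Equidistant solutions break ties toward smaller t.
#'
#' @param phi,psi query coordinates in degrees (vectorised).
#' @param e an [ellipse_path()].
#' @return data frame with columns phie, psie (in (-180, 180]), distance
#'   (degrees) and t (parameter in [0, 360)).
#' @export
project_to_ellipse <- function(phi, psi, e) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  out <- data.frame(phie = numeric(n), psie = numeric(n),
                    distance = numeric(n), t = numeric(n))
  shifts <- as.matrix(expand.grid(s1 = c(-360, 0, 360), s2 = c(-360, 0, 360)))
  tcoarse <- seq(0, 360 - 2, by = 2)
  pc <- ellipse_point(e, tcoarse)
  for (i in seq_len(n)) {
    best <- NULL
    for (s in seq_len(nrow(shifts))) {
      q <- c(phi[i] + shifts[s, 1], psi[i] + shifts[s, 2])
      d2 <- (pc[, 1] - q[1])^2 + (pc[, 2] - q[2])^2
      t0 <- tcoarse[which.min(d2)]
      tt <- .refine_projection(q, e, t0)
      p <- ellipse_point(e, tt)
      dd <- sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
      tt <- tt %% 360
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 && tt < best$t)) {
        best <- list(d = dd, t = tt)
      }
    }
    p <- ellipse_point(e, best$t, wrap = TRUE)
    out$phie[i] <- p[1]; out$psie[i] <- p[2]
    out$distance[i] <- best$d; out$t[i] <- best$t
  }
  out
}

#' Newton refinement of the squared-distance minimiser on the ellipse
#' @noRd
.refine_projection <- function(q, e, t0) {
  th <- e$tilt / DEG
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # work in the ellipse frame: query relative to center, unrotated
  qe <- t(R) %*% (q - e$center)
  a <- e$axes[1]; b <- e$axes[2]
  t <- t0 / DEG
  for (k in 1:60) {
    ct <- cos(t); st <- sin(t)
    # f(t) = d/dt 0.5*|p(t)-q|^2
    f <- (b^2 - a^2) * ct * st + a * qe[1] * st - b * qe[2] * ct
    fp <- (b^2 - a^2) * (ct^2 - st^2) + a * qe[1] * ct + b * qe[2] * st
    if (abs(fp) < 1e-14) break
    step <- f / fp
    step <- max(min(step, 0.2), -0.2) # trust region in radians
    t <- t - step
    if (abs(step) < 1e-13) break
  }
  t * DEG
}

#' Project a whole dihedral series onto the elliptical path
#'
#' Residues with both Phi and Psi defined are replaced by their
#' (Phie, Psie) projection; undefined angles stay undefined. Feeding the
#' result to [build_backbone()] yields the early-stage structure of the
#' chain.
#'
#' @param d a [dihedral_series()].
#' @param e an [ellipse_path()].
#' @return A `dihedral_series` of projected angles, with the projection
#'   `distance` and parameter `t` attached as extra columns.
#' @export
project_chain <- function(d, e) {
  ok <- !is.na(d$phi) & !is.na(d$psi)
  out <- dihedral_series(d$res_number, d$phi, d$psi, d$omega,
                         res_name = d$res_name, icode = d$icode)
  out$distance <- NA_real_
  out$t <- NA_real_
  if (any(ok)) {
    pr <- project_to_ellipse(d$phi[ok], d$psi[ok], e)
    out$phi[ok] <- pr$phie
    out$psi[ok] <- pr$psie
    out$distance[ok] <- pr$distance
    out$t[ok] <- pr$t
  }
  out
}

#' Parameter of the ellipse-line crossing with Psi = -Phi
#'
#' Solves phi(t) + psi(t) = 0 for t, returning the crossings (generically
#' two). Used by the morphing procedure to leave the ellipse onto the
#' amyloid Psi = -Phi line.
#'
#' @param e an [ellipse_path()].
#' @return numeric vector of t values in [0, 360) sorted increasingly;
#'   empty if the path does not cross the line.
#' @export
ellipse_line_crossings <- function(e) {
  th <- e$tilt / DEG
  # phi(t)+psi(t) = c0 + P cos t + Q sin t
  c0 <- sum(e$center)
  P <- e$axes[1] * (cos(th) + sin(th))
  Q <- e$axes[2] * (cos(th) - sin(th))
  amp <- sqrt(P^2 + Q^2)
  if (amp < abs(c0)) return(numeric(0))
  base <- atan2(Q, P)
  ac <- acos(max(-1, min(1, -c0 / amp)))
  sort(((c(base + ac, base - ac)) * DEG) %% 360)
}
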
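#' Build an alanine pentapeptide at fixed (Phi, Psi)
#'
#' The early-stage model characterises every point of the Ramachandran map
#' by a homogeneous alanine pentapeptide: five residues all at the same
#' (Phi, Psi) with trans peptide bonds. Two geometric descriptors of that
#' pentapeptide — the V angle between consecutive peptide-bond plane
#' orientations and the radius of curvature R of its projected C-alpha
#' trace — summarise the local chain shape.
#'
#' @param phi,psi backbone torsions in degrees, in (-180, 180].
#' @param g covalent geometry constants ([geometry_params()]).
#' @return A [backbone_chain()] of 5 alanines with attributes `phi`, `psi`;
#'   class `pentapeptide_conformation`.
#' @export
build_pentapeptide <- function(phi, psi, g = geometry_params()) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  d <- dihedral_series(1:5, rep(phi, 5), rep(psi, 5))
  p <- build_backbone(d, g = g)
  attr(p, "phi") <- phi
  attr(p, "psi") <- psi
  class(p) <- c("pentapeptide_conformation", class(p))
  p
}

#' Peptide-unit C=O orientation vectors of a chain
#'
#' One unit vector per peptide bond plane (residues 1..n-1), pointing from
#' the carbonyl C to its O. These directed orientations carry the
#' hydrogen-bond directionality of the plane: parallel in helices,
#' antiparallel in beta structure.
#' @noRd
peptide_orientations <- function(chain) {
  n <- length(chain)
  if (n < 2) stop("need at least 2 residues for a peptide plane")
  v <- chain$O[seq_len(n - 1), , drop = FALSE] - chain$C[seq_len(n - 1), , drop = FALSE]
  if (any(!is.finite(v))) stop("missing C or O atoms in peptide units")
  v / sqrt(rowSums(v * v))
}

#' C->O unit vectors of every residue (including the terminal carbonyl)
#'
#' The common-frame Z axis is the mean over all carbonyl groups, not only
#' the n-1 peptide-bond units. The distinction matters in the beta limit:
#' consecutive peptide units are antiparallel there and their mean
#' direction cancels pairwise along the chain's screw axis, whereas the
#' odd terminal carbonyl keeps the mean tilted off that axis, so the
#' projection plane retains the chain's rectilinear propagation and the
#' fitted radius of curvature grows toward the model's infinite beta
#' limit.
#' @noRd
carbonyl_orientations <- function(chain) {
  v <- chain$O - chain$C
  if (any(!is.finite(v))) stop("missing C or O atoms")
  v / sqrt(rowSums(v * v))
}

#' Orient a pentapeptide in the model's common frame
#'
#' Rigid-body transform only: the mean C->O direction over all carbonyl
#' groups defines the +Z axis, the centroid of the C-alpha atoms goes to
#' the origin, and the residual in-plane rotation is fixed by aligning the
#' XY projection of the first-to-last C-alpha displacement with +X (R and
#' V are invariant to rotation about Z, so this last step only
#' standardises coordinates).
#'
#' @param p a chain (typically from [build_pentapeptide()]).
#' @return The transformed chain (same class and attributes).
#' @export
orient_common_frame <- function(p) {
  ov <- carbonyl_orientations(p)
  m <- colMeans(ov)
  if (vnorm(m) < 1e-9)
    stop("degenerate mean C=O direction: peptide-plane orientations cancel")
  R1 <- rotation_between(m, c(0, 0, 1))
  q <- transform_chain(p, R = R1)
  cen <- colMeans(q$CA)
  q <- transform_chain(q, t = -cen)
  v <- q$CA[length(q), ] - q$CA[1, ]
  vxy <- c(v[1], v[2], 0)
  if (vnorm(vxy) > 1e-9) {
    th <- atan2(vxy[2], vxy[1]) * DEG
    q <- transform_chain(q, R = rotation_axis(c(0, 0, 1), -th))
  }
  attr(q, "phi") <- attr(p, "phi")
  attr(q, "psi") <- attr(p, "psi")
  class(q) <- class(p)
  q
}

#' V angle between consecutive peptide-bond plane orientations
#'
#' The model's V angle is computed between *directed* plane orientations:
#' each peptide unit is represented by its C->O bond direction, and V is
#' the angle (degrees, in \[0, 180\]) between consecutive units, averaged
#' over the chain's consecutive pairs. The direction matters: helical
#' planes carry parallel C=O vectors (V = 0) while beta structure flips
#' the carbonyl from unit to unit (V = 180) even though the planes
#' themselves are nearly coplanar. An undirected plane-normal variant is
#' available via `method = "normal"`.
#'
#' @param p a chain with at least 3 residues (2 peptide planes).
#' @param method `"co"` (directed C->O orientations, default) or
#'   `"normal"` (peptide-plane normal vectors).
#' @param pairs `"all"` to average over all consecutive plane pairs
#'   (default), `"central"` to use only the middle pair.
#' @return V in degrees in \[0, 180\].
#' @export
compute_V <- function(p, method = c("co", "normal"), pairs = c("all", "central")) {
  method <- match.arg(method)
  pairs <- match.arg(pairs)
  n <- length(p)
  if (n < 3) stop("need at least 2 peptide planes (3 residues) to define V")
  if (method == "co") {
    ov <- peptide_orientations(p)
  } else {
    k <- seq_len(n - 1)
    a <- p$O[k, , drop = FALSE] - p$C[k, , drop = FALSE]
    b <- p$N[k + 1, , drop = FALSE] - p$C[k, , drop = FALSE]
    ov <- t(vapply(seq_len(n - 1), function(i) unit(cross3(a[i, ], b[i, ])),
                   numeric(3)))
  }
  m <- nrow(ov)
  ang <- vapply(seq_len(m - 1), function(i) vec_angle(ov[i, ], ov[i + 1, ]),
                numeric(1))
  if (pairs == "central") ang <- ang[ceiling((m - 1) / 2)]
  mean(ang)
}

#' Radius of curvature of the projected C-alpha trace
#'
#' A circle is fitted (algebraic least squares, Kasa) to the XY
#' projections of the C-alpha atoms of a chain oriented in the common
#' frame. Near-linear traces — the beta limit, where the radius is
#' theoretically infinite — are capped at a finite ceiling so ln(R) stays
#' plottable; the `capped` flag records this.
#'
#' Capping reflects the model's beta limit in two ways: (i) projected
#' C-alpha points collinear within tolerance, and (ii) a degenerate common
#' frame — when consecutive C=O orientations approach the antiparallel
#' system their mean direction cancels and the Z axis (hence the
#' projection plane) loses meaning, which is precisely the rectilinear
#' Psi = -Phi construction whose curvature radius is theoretically
#' infinite.
#'
#' @param p an oriented chain (see [orient_common_frame()]).
#' @param cap ceiling for R in Angstrom.
#' @param collinear_tol smallest-singular-value threshold (Angstrom) below
#'   which the projected trace is treated as collinear.
#' @param frame_tol mean C=O norm below which the common frame is treated
#'   as degenerate (antiparallel limit).
#' @return list with `R` (Angstrom), `lnR`, and `capped`.
#' @export
compute_R <- function(p, cap = 1e6, collinear_tol = 1e-3, frame_tol = 0.1) {
  xy <- p$CA[, 1:2, drop = FALSE]
  if (any(!is.finite(xy))) stop("missing C-alpha atoms")
  cen <- sweep(xy, 2, colMeans(xy))
  dmax <- max(stats::dist(xy))
  if (dmax < 1e-6) stop("degenerate geometry: projected C-alpha points coincide")
  co_norm <- tryCatch(vnorm(colMeans(carbonyl_orientations(p))), error = function(e) 1)
  if (co_norm < frame_tol)
    return(list(R = cap, lnR = log(cap), capped = TRUE))
  sv <- svd(cen, nu = 0, nv = 0)$d
  if (min(sv) < collinear_tol)
    return(list(R = cap, lnR = log(cap), capped = TRUE))
  x <- cen[, 1]; y <- cen[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  sol <- qr.solve(A, b)
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (r2 <= 0) return(list(R = cap, lnR = log(cap), capped = TRUE))
  R <- sqrt(r2)
  if (R >= cap) return(list(R = cap, lnR = log(cap), capped = TRUE))
  list(R = unname(R), lnR = unname(log(R)), capped = FALSE)
}

#' Single-point R/V evaluation of the Ramachandran map
#' @noRd
rv_point <- function(phi, psi, g = geometry_params(), ...) {
  p <- orient_common_frame(build_pentapeptide(phi, psi, g = g))
  r <- compute_R(p, ...)
  list(phi = phi, psi = psi, V = compute_V(p), lnR = r$lnR, R = r$R,
       capped = r$capped)
}

#' Generate the R/V map over the Ramachandran grid
#'
#' Evaluates the V angle and ln(R) of the homogeneous alanine pentapeptide
#' on a regular (Phi, Psi) grid covering (-180, 180]^2. The default 5
#' degree step gives the 72 x 72 = 5184-point model surface from which the
#' elliptical early-stage path is derived.
#'
#' @param step grid step in degrees; must divide 360.
#' @param g covalent geometry constants.
#' @param cap,collinear_tol passed to [compute_R()].
#' @return A data frame of class `rv_map` with columns phi, psi, V, lnR,
#'   R, capped, and attribute `step`.
#' @export
generate_rv_map <- function(step = 5, g = geometry_params(), cap = 1e6,
                            collinear_tol = 1e-3) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-12)
    stop("grid step must be a positive divisor of 360")
  vals <- seq(-180 + step, 180, by = step)
  grid <- expand.grid(phi = vals, psi = vals, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i)
    rv_point(grid$phi[i], grid$psi[i], g = g, cap = cap,
             collinear_tol = collinear_tol))
  out <- data.frame(phi = grid$phi, psi = grid$psi,
                    V = vapply(res, `[[`, numeric(1), "V"),
                    lnR = vapply(res, `[[`, numeric(1), "lnR"),
                    R = vapply(res, `[[`, numeric(1), "R"),
                    capped = vapply(res, `[[`, logical(1), "capped"))
  attr(out, "step") <- step
  class(out) <- c("rv_map", "data.frame")
  out
}

#' Export an R/V map as TSV
#' @param map an `rv_map`.
#' @param path output file.
#' @export
write_rv_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# espath R/V map, step %g deg", attr(map, "step")), con)
  utils::write.table(as.data.frame(map)[, c("phi", "psi", "V", "lnR", "capped")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Co-orientation of consecutive peptide-bond C=O groups
#'
#' Classifies the angle between the C->O unit vectors of residues `i` and
#' `i + 1` as parallel (helical hydrogen-bond pattern), antiparallel (beta
#' pattern) or intermediate. In flat amyloid chains, single helical
#' residues re-orient the hydrogen-bond dipoles to the parallel system
#' while beta stretches keep the antiparallel one.
#'
#' @param chain a [backbone_chain()].
#' @param i residue index (file order); residues i and i+1 must have
#'   complete C=O groups.
#' @param threshold_parallel,threshold_antiparallel classification
#'   thresholds in degrees.
#' @return `"parallel"`, `"antiparallel"` or `"intermediate"`.
#' @export
co_orientation <- function(chain, i, threshold_parallel = 60,
                           threshold_antiparallel = 120) {
  if (i < 1 || i + 1 > length(chain)) stop("residue index out of range")
  v1 <- chain$O[i, ] - chain$C[i, ]
  v2 <- chain$O[i + 1, ] - chain$C[i + 1, ]
  if (any(!is.finite(c(v1, v2)))) stop("missing C or O atom at the requested residues")
  a <- vec_angle(v1, v2)
  if (a <= threshold_parallel) "parallel"
  else if (a >= threshold_antiparallel) "antiparallel"
  else "intermediate"
}
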
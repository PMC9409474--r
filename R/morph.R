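#' Plan the stepwise conformational path of a single residue
#'
#' The amyloid-transformation procedure moves each (Phi, Psi) point in
#' three stages: (1) straight to its shortest-distance projection
#' (Phie, Psie) on the elliptical path; (2) along the ellipse toward the
#' target's position on the path; (3) a terminal stage chosen by the
#' target's structural code — for an AB target the path leaves the
#' ellipse at its crossing with Psi = -Phi and continues exactly along
#' that line; for an L target the arc runs into the left-handed helical
#' basin and then straight to the target; otherwise straight from the
#' arc exit to the target. Residues already at their target are never
#' perturbed.
#'
#' @param start,target numeric length-2 (phi, psi) in degrees.
#' @param e an [ellipse_path()].
#' @param zones a [zone_config()].
#' @param steps integer length-3: waypoints per segment.
#' @param constrained take the complementary (longer) arc passing the
#'   compressed-helix flank instead of the shorter arc, honouring the
#'   constraint that chain-embedded helices cannot unwind freely.
#' @return list of class `morph_plan`: `waypoints` (matrix with
#'   `1 + sum(steps)` rows of unwrapped (phi, psi)), `segment` (integer
#'   vector, 0 = start, 1..3 per stage), `t_path` (ellipse parameter per
#'   waypoint, `NA` off the ellipse).
#' @export
plan_path <- function(start, target, e, zones = zone_config(),
                      steps = c(3, 3, 3), constrained = FALSE) {
  stopifnot(length(steps) == 3, all(steps >= 1))
  S <- sum(steps)
  seg_of <- c(0L, rep(1L, steps[1]), rep(2L, steps[2]), rep(3L, steps[3]))
  if (max(abs(ang_delta(start, target))) < 1e-9) {
    wp <- matrix(rep(start, S + 1), ncol = 2, byrow = TRUE)
    return(structure(list(waypoints = wp, segment = seg_of,
                          t_path = rep(NA_real_, S + 1), zero = TRUE),
                     class = "morph_plan"))
  }
  ps <- project_to_ellipse(start[1], start[2], e)
  pt <- project_to_ellipse(target[1], target[2], e)
  tcode <- classify(target[1], target[2], zones)

  terminal_ab <- !is.na(tcode) && tcode == "AB"
  if (terminal_ab) {
    cr <- ellipse_line_crossings(e)
    if (length(cr) == 0) {
      terminal_ab <- FALSE # path never meets the line; fall back to straight exit
    } else {
      crp <- ellipse_point(e, cr, wrap = TRUE)
      side <- which(crp[, 1] < 0 & crp[, 2] > 0)
      t_exit <- if (length(side)) cr[side[1]] else cr[1]
    }
  }
  if (!terminal_ab) t_exit <- pt$t

  # stage 1: straight approach to the ellipse (periodic-aware)
  p0 <- c(start[1], start[2])
  p1 <- c(ps$phie, ps$psie)
  d1 <- ang_delta(p0, p1)
  w1 <- t(vapply(seq_len(steps[1]), function(s) p0 + (s / steps[1]) * d1,
                 numeric(2)))

  # stage 2: monotone arc travel from t_start to t_exit
  dt <- (t_exit - ps$t) %% 360
  dt <- if (dt <= 180) dt else dt - 360 # shorter arc, signed
  if (constrained && abs(dt) > 1e-12) dt <- dt - sign(dt) * 360
  tseq <- ps$t + (seq_len(steps[2]) / steps[2]) * dt
  w2raw <- ellipse_point(e, tseq)
  # keep stage-2 continuous with the stage-1 endpoint in unwrapped space
  w2 <- w2raw
  anchor <- ellipse_point(e, ps$t)
  shift <- (w1[steps[1], ] - anchor) - ang_delta(anchor, w1[steps[1], ])
  w2[, 1] <- w2raw[, 1] + shift[1]
  w2[, 2] <- w2raw[, 2] + shift[2]

  # stage 3
  exit_pt <- w2[steps[2], ]
  if (terminal_ab) {
    # exactly on the line Psi = -Phi: parameterise by u -> (u, -u);
    # waypoints are built in wrapped coordinates and re-anchored so the
    # unwrapped path stays continuous with the arc exit
    ew <- wrap_angle(exit_pt)
    shift3 <- exit_pt - ew
    u_exit <- (ew[1] - ew[2]) / 2
    u_target <- (target[1] - target[2]) / 2
    w3 <- matrix(NA_real_, steps[3], 2)
    if (steps[3] > 1) {
      for (s in seq_len(steps[3] - 1)) {
        u <- u_exit + (s / (steps[3] - 1)) * (u_target - u_exit)
        w3[s, ] <- c(u, -u) + shift3
      }
    }
    w3[steps[3], ] <- c(target[1], target[2]) + shift3
  } else {
    d3 <- ang_delta(exit_pt, target)
    w3 <- t(vapply(seq_len(steps[3]), function(s) exit_pt + (s / steps[3]) * d3,
                   numeric(2)))
  }
  wp <- rbind(p0, w1, w2, w3)
  rownames(wp) <- NULL
  tp <- c(NA_real_, rep(NA_real_, steps[1] - 1), ps$t %% 360,
          tseq %% 360, rep(NA_real_, steps[3]))
  structure(list(waypoints = wp, segment = seg_of, t_path = tp,
                 t_start = ps$t, t_exit = t_exit, arc = dt,
                 terminal = if (terminal_ab) "line" else "straight",
                 zero = FALSE),
            class = "morph_plan")
}

#' @export
print.morph_plan <- function(x, ...) {
  cat(sprintf("morph_plan: %d waypoints, terminal %s, arc %.1f deg%s\n",
              nrow(x$waypoints), if (x$zero) "none (stationary)" else x$terminal,
              if (x$zero) 0 else x$arc, if (x$zero) "" else ""))
  invisible(x)
}

#' Morph a chain fragment from a start to a target conformation
#'
#' Executes per-residue path plans synchronously: all residues advance
#' one waypoint per frame, so the trajectory has `1 + sum(steps)` frames
#' regardless of residue count; residues whose paths are shorter (or
#' stationary) simply hold. Residues present in only one structure, or
#' with undefined angles in either, are held at their start values and
#' reported in the `held` attribute.
#'
#' @param start,target [dihedral_series()] objects sharing author
#'   residue numbering.
#' @param e an [ellipse_path()].
#' @param zones a [zone_config()].
#' @param steps integer length-3 waypoints per stage.
#' @param constrained passed to [plan_path()].
#' @return list of class `morph_trajectory`: `frames` (list of
#'   `dihedral_series`), `segment` (frame x residue stage matrix),
#'   `held` (residue keys not morphed).
#' @export
morph_fragment <- function(start, target, e, zones = zone_config(),
                           steps = c(3, 3, 3), constrained = FALSE) {
  ks <- paste(start$res_number, start$icode, sep = "|")
  kt <- paste(target$res_number, target$icode, sep = "|")
  common <- intersect(ks, kt)
  if (length(common) == 0) stop("start and target share no residue numbers")
  i <- match(common, ks); j <- match(common, kt)
  movable <- !is.na(start$phi[i]) & !is.na(start$psi[i]) &
    !is.na(target$phi[j]) & !is.na(target$psi[j])
  held <- c(setdiff(ks, kt), ks[i][!movable])
  S <- sum(steps)
  n <- nrow(start)
  frames <- vector("list", S + 1)
  wps <- array(NA_real_, c(S + 1, n, 2))
  wps[, , 1] <- matrix(start$phi, S + 1, n, byrow = TRUE)
  wps[, , 2] <- matrix(start$psi, S + 1, n, byrow = TRUE)
  seg <- matrix(0L, S + 1, n)
  for (k in seq_along(common)) {
    if (!movable[k]) next
    ii <- i[k]
    pl <- plan_path(c(start$phi[ii], start$psi[ii]),
                    c(target$phi[j[k]], target$psi[j[k]]),
                    e, zones, steps = steps, constrained = constrained)
    wps[, ii, 1] <- pl$waypoints[, 1]
    wps[, ii, 2] <- pl$waypoints[, 2]
    seg[, ii] <- pl$segment
  }
  for (f in seq_len(S + 1)) {
    frames[[f]] <- dihedral_series(start$res_number,
                                   wrap_angle(wps[f, , 1]),
                                   wrap_angle(wps[f, , 2]),
                                   omega = start$omega,
                                   res_name = start$res_name,
                                   icode = start$icode)
  }
  structure(list(frames = frames, segment = seg, steps = steps,
                 held = held), class = "morph_trajectory")
}

#' @export
print.morph_trajectory <- function(x, ...) {
  cat(sprintf("morph_trajectory: %d frames x %d residues (%d held)\n",
              length(x$frames), nrow(x$frames[[1]]), length(x$held)))
  invisible(x)
}

#' Number of AB-coded residues in each frame
#'
#' Convenience summary of trajectory progress toward the amyloid form.
#' @param tr a `morph_trajectory`.
#' @param zones a [zone_config()].
#' @return integer vector, one count per frame.
#' @export
ab_count <- function(tr, zones = zone_config()) {
  vapply(tr$frames, function(f)
    sum(classify(f$phi, f$psi, zones) == "AB", na.rm = TRUE), integer(1))
}

#' Write a trajectory as one PDB file per frame
#'
#' Frames are rebuilt in 3D with [build_backbone()] and written as
#' `frame_000.pdb`, `frame_001.pdb`, ... into `dir`.
#'
#' @param tr a `morph_trajectory`.
#' @param dir output directory (created if needed).
#' @param g covalent geometry constants for the rebuild.
#' @return character vector of written paths, invisibly.
#' @export
render_trajectory <- function(tr, dir, g = geometry_params()) {
  if (length(tr$frames) == 0) stop("empty trajectory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(tr$frames))
  for (f in seq_along(tr$frames)) {
    paths[f] <- file.path(dir, sprintf("frame_%03d.pdb", f - 1))
    write_pdb(build_backbone(tr$frames[[f]], g = g), paths[f])
  }
  invisible(paths)
}
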
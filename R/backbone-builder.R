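#' Covalent geometry constants for backbone reconstruction
#'
#' Standard single-conformer restraint values used when a 3D backbone is
#' rebuilt from torsion angles. The early-stage model treats the dihedrals
#' as the only degrees of freedom, so bond lengths and bond angles are held
#' at these community-standard values; all are overridable.
#'
#' @param n_ca,ca_c,c_n,c_o bond lengths in Angstrom.
#' @param n_ca_c,ca_c_n,c_n_ca,ca_c_o bond angles in degrees.
#' @param omega default peptide-bond torsion in degrees (trans).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                            c_o = 1.231, n_ca_c = 111.2, ca_c_n = 116.2,
                            c_n_ca = 121.7, ca_c_o = 120.8, omega = 180) {
  g <- list(n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
            n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca,
            ca_c_o = ca_c_o, omega = omega)
  stopifnot(all(unlist(g[1:4]) > 0),
            all(unlist(g[5:8]) > 0), all(unlist(g[5:8]) < 180))
  structure(g, class = "geometry_params")
}

#' Rebuild 3D backbone coordinates from a dihedral series
#'
#' The inverse of [compute_dihedrals()]: sequential atom placement in which
#' each atom is positioned from the three preceding ones by its bond
#' length, bond angle and torsion (natural-extension reference frame). The
#' first three atoms are placed canonically (N1 at the origin, CA1 on +X,
#' C1 in the XY plane) so rebuilt structures are byte-reproducible.
#'
#' Phi of the first residue and Psi/omega of the last do not influence the
#' geometry and may be `NA`; the terminal carbonyl O is placed by the trans
#' convention when Psi is undefined.
#'
#' @param d a [dihedral_series()] (or data frame with phi/psi/omega).
#' @param g a [geometry_params()].
#' @param seq optional character vector of 3-letter residue names;
#'   defaults to the residue names in `d` (poly-alanine if absent).
#' @param chain_id chain identifier for the result.
#' @return A [backbone_chain()] with `length(d)` residues.
#' @export
build_backbone <- function(d, g = geometry_params(), seq = NULL,
                           chain_id = "A") {
  n <- nrow(d)
  if (is.null(n) || n == 0) stop("empty dihedral series: nothing to build")
  if (is.null(seq)) seq <- if (!is.null(d$res_name)) d$res_name else rep("ALA", n)
  omega <- ifelse(is.na(d$omega), g$omega, d$omega)
  phi <- d$phi
  psi <- d$psi

  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  # canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- g$n_ca_c / DEG
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)

  for (i in seq_len(n)) {
    if (i < n) {
      if (is.na(psi[i]))
        stop(sprintf("psi undefined at interior residue %d: cannot place next N", i))
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, g$ca_c_n, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca, g$c_n_ca, omega[i])
      if (is.na(phi[i + 1]))
        stop(sprintf("phi undefined at interior residue %d: cannot place its C", i + 1))
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c, g$n_ca_c, phi[i + 1])
      # carbonyl O in the peptide plane, anti to the next N
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ca_c_o,
                           wrap_angle(psi[i] + 180))
    } else {
      psi_term <- if (!is.na(psi[i])) psi[i] else 180
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ca_c_o,
                           wrap_angle(psi_term + 180))
    }
  }
  backbone_chain(d$res_number, seq, N, CA, C, O, chain_id = chain_id,
                 icode = if (!is.null(d$icode)) d$icode else NULL)
}

#' Compute backbone dihedral angles of a chain
#'
#' Standard IUPAC torsions, in degrees in (-180, 180]:
#' Phi(i) = C(i-1)-N(i)-CA(i)-C(i); Psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1). A torsion is `NA` wherever a
#' flanking atom is absent (chain termini or incomplete residues).
#'
#' @param chain a [backbone_chain()].
#' @return A [dihedral_series()] aligned with the chain's residues.
#' @export
compute_dihedrals <- function(chain) {
  n <- length(chain)
  if (n < 2) stop("chain must have at least 2 residues to define any torsion")
  phi <- psi <- omega <- rep(NA_real_, n)
  ok <- function(...) all(is.finite(unlist(list(...))))
  for (i in seq_len(n)) {
    if (i > 1 && ok(chain$C[i - 1, ], chain$N[i, ], chain$CA[i, ], chain$C[i, ]))
      phi[i] <- torsion_angle(chain$C[i - 1, ], chain$N[i, ], chain$CA[i, ], chain$C[i, ])
    if (i < n) {
      if (ok(chain$N[i, ], chain$CA[i, ], chain$C[i, ], chain$N[i + 1, ]))
        psi[i] <- torsion_angle(chain$N[i, ], chain$CA[i, ], chain$C[i, ], chain$N[i + 1, ])
      if (ok(chain$CA[i, ], chain$C[i, ], chain$N[i + 1, ], chain$CA[i + 1, ]))
        omega[i] <- torsion_angle(chain$CA[i, ], chain$C[i, ], chain$N[i + 1, ], chain$CA[i + 1, ])
    }
  }
  dihedral_series(chain$res_number, phi, psi, omega,
                  res_name = chain$res_name, icode = chain$icode)
}
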
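#' Ideal conformer series
#'
#' Homogeneous dihedral series at the representative point of a
#' structural kind, generated from the same zone configuration the
#' classifier reads (so fixtures and classification can never drift
#' apart): `R-helix` (right-handed alpha), `L-helix` (left-handed),
#' `beta-AB` (the amyloid Psi = -Phi form) and `extended` (Phi = Psi =
#' 180).
#'
#' @param kind one of `"R-helix"`, `"L-helix"`, `"beta-AB"`,
#'   `"extended"`.
#' @param n residue count, >= 2.
#' @param zones a [zone_config()].
#' @return A [dihedral_series()] of `n` residues.
#' @export
make_ideal <- function(kind, n, zones = zone_config()) {
  if (n < 2) stop("need at least 2 residues")
  rep_point <- switch(kind,
                      "R-helix" = zones$representatives$R,
                      "L-helix" = zones$representatives$L,
                      "beta-AB" = zones$representatives$AB,
                      "extended" = c(180, 180),
                      stop(sprintf("unknown ideal kind: %s", kind)))
  dihedral_series(seq_len(n), rep(rep_point[1], n), rep(rep_point[2], n))
}

#' Motif series from a structural-code string
#'
#' One residue per code token, placed at the token's representative
#' (Phi, Psi) from the zone configuration. Tokens follow the coarse
#' alphabet (`AB`, `R`, `L`, `B`, `M`) plus the beta sub-codes `E` and
#' `F`; numeric position prefixes in the source notation (e.g.
#' "AB-17L-18R-AB") are accepted and ignored.
#'
#' @param spec motif string, tokens separated by `-` (e.g. "AB-L-AB").
#' @param zones a [zone_config()].
#' @return A [dihedral_series()] with one residue per token and the
#'   clean token vector attached as attribute `codes`.
#' @export
make_motif <- function(spec, zones = zone_config()) {
  if (is.null(spec) || !nzchar(spec)) stop("empty motif spec")
  toks <- strsplit(spec, "-", fixed = TRUE)[[1]]
  toks <- sub("^[0-9]+", "", toks)
  if (any(!nzchar(toks))) stop("malformed motif spec (empty token)")
  unknown <- setdiff(toks, names(zones$representatives))
  if (length(unknown))
    stop(sprintf("unknown motif token(s): %s", paste(unknown, collapse = ",")))
  pts <- do.call(rbind, zones$representatives[toks])
  d <- dihedral_series(seq_along(toks), pts[, 1], pts[, 2])
  attr(d, "codes") <- toks
  d
}

#' Add seeded Gaussian jitter to a dihedral series
#'
#' Defined angles receive independent Gaussian noise of standard
#' deviation `sigma` degrees and are wrapped back into (-180, 180];
#' undefined angles stay undefined. Reproducible for a fixed seed.
#'
#' @param d a [dihedral_series()].
#' @param sigma noise standard deviation in degrees, >= 0.
#' @param seed integer seed.
#' @return A jittered `dihedral_series`.
#' @export
make_noisy <- function(d, sigma, seed) {
  stopifnot(sigma >= 0)
  out <- d
  if (sigma == 0) return(out)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (col in c("phi", "psi")) {
    ok <- !is.na(out[[col]])
    out[[col]][ok] <- wrap_angle(out[[col]][ok] + stats::rnorm(sum(ok), 0, sigma))
  }
  out
}

#' Synthetic native-like and amyloid-like structure pair
#'
#' A stand-in pair of dihedral series emulating the dispersion contrast
#' between a native globular chain and a flat amyloid chain: the amyloid
#' stand-in concentrates tightly on the Psi = -Phi line with a few
#' single R/L residues (the flat-twist motifs), while the native
#' stand-in scatters broadly over helical and beta basins. Purely
#' synthetic — it reproduces the qualitative class structure, not any
#' particular deposited structure.
#'
#' @param n residue count.
#' @param seed integer seed.
#' @param zones a [zone_config()].
#' @return list with elements `native` and `amyloid`
#'   ([dihedral_series()] objects sharing residue numbering).
#' @export
make_synthetic_pair <- function(n = 100, seed = 1, zones = zone_config()) {
  stopifnot(n >= 20)
  base <- rep("AB", n)
  slots <- seq(10, n - 5, by = 12)
  base[slots] <- rep(c("L", "R"), length.out = length(slots))
  amyloid <- make_motif(paste(base, collapse = "-"), zones)
  amyloid <- make_noisy(amyloid, sigma = 6, seed = seed)
  native_codes <- rep(c("R", "B", "M", "B"), length.out = n)
  native <- make_motif(paste(native_codes, collapse = "-"), zones)
  native <- make_noisy(native, sigma = 18, seed = seed + 1)
  list(native = native, amyloid = amyloid)
}
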
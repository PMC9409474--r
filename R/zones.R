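#' Zone configuration of the Ramachandran structural-code alphabet
#'
#' The structural codes used for amyloid chains — AB (on/near the
#' Psi = -Phi line with Phi < 0, Psi > 0), R and L (right/left-handed
#' helical basins), B (beta field, split into the rectilinear E band and
#' the twisted F remainder) and M (the region between the helical and
#' beta basins) — are defined by explicit polygon vertex lists plus band
#' tolerances. Zones are only drawn pictorially in the source literature,
#' so the polygons are shipped as versioned, inspectable configuration
#' rather than hard-coded rules; fixtures and the classifier read the
#' same representative points so they can never drift apart.
#'
#' @param path YAML file; default is the configuration shipped with the
#'   package.
#' @return A list of class `zone_config` with elements `polygons`
#'   (named list of n x 2 vertex matrices), `representatives` (named list
#'   of (phi, psi) points), `ab_tolerance`, `e_band`, `zone_tolerance`.
#' @export
zone_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "zones-default.yaml", package = "espath",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  cfg$polygons <- lapply(cfg$polygons, function(p)
    matrix(unlist(p), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("phi", "psi"))))
  cfg$representatives <- lapply(cfg$representatives, as.numeric)
  class(cfg) <- "zone_config"
  cfg
}

#' @export
print.zone_config <- function(x, ...) {
  cat(sprintf("zone_config v%s: polygons %s; ab_tolerance %g, e_band %g\n",
              x$version, paste(names(x$polygons), collapse = ","),
              x$ab_tolerance, x$e_band))
  invisible(x)
}

#' Point-in-polygon test (even-odd rule, vectorised over points)
#' @noRd
in_polygon <- function(phi, psi, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(phi))
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    crosses <- ((yi > psi) != (yj > psi)) &
      (phi < (xj - xi) * (psi - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Low-energy mask predicate from a zone config
#'
#' Union of the broad helical and beta basins, used to restrict the
#' parabola fit of lnR on V to relaxed conformations.
#' @param zones a [zone_config()].
#' @return `function(phi, psi) -> logical`.
#' @export
low_energy_mask <- function(zones = zone_config()) {
  polys <- zones$polygons[zones$low_energy]
  function(phi, psi) {
    hit <- rep(FALSE, length(phi))
    for (p in polys) hit <- hit | in_polygon(phi, psi, p)
    hit
  }
}

#' Perpendicular distance to the amyloid line Psi = -Phi
#'
#' The dispersion measure of the beta-structural area: the Euclidean
#' distance in degrees from (Phi, Psi) to the line Psi = -Phi, i.e.
#' |Phi + Psi| / sqrt(2).
#'
#' @param phi,psi degrees (vectorised).
#' @return distance in degrees, >= 0.
#' @export
dist_to_antidiagonal <- function(phi, psi) {
  abs(phi + psi) / sqrt(2)
}

#' Classify a conformation into the structural-code alphabet
#'
#' Codes, in precedence order (most specific first):
#' \itemize{
#'   \item `AB` — inside the beta field with Phi < 0, Psi > 0 and within
#'     `ab_tolerance` of the Psi = -Phi line: the amyloid beta form;
#'   \item `R` / `L` — right/left-handed helical basin;
#'   \item `E` — remaining beta field within `e_band` of the line
#'     (rectilinearly propagating beta);
#'   \item `F` — remaining beta field (twisted/bent beta, terminating
#'     propagation);
#'   \item `M` — the region between the helical and beta basins;
#'   \item `other` — anything else (including undefined angles, returned
#'     as `NA`).
#' }
#'
#' @param phi,psi degrees (vectorised).
#' @param zones a [zone_config()].
#' @return character vector of fine codes
#'   (`AB`,`R`,`L`,`E`,`F`,`M`,`other`). Use [code_group()] to collapse
#'   E/F (and near-line AB) into the coarse Table-style alphabet.
#' @export
classify <- function(phi, psi, zones = zone_config()) {
  n <- length(phi)
  out <- rep(NA_character_, n)
  ok <- !is.na(phi) & !is.na(psi)
  if (!any(ok)) return(out)
  p <- phi[ok]; s <- psi[ok]
  code <- rep("other", length(p))
  inR <- in_polygon(p, s, zones$polygons$R)
  inL <- in_polygon(p, s, zones$polygons$L)
  inB <- in_polygon(p, s, zones$polygons$beta)
  inM <- in_polygon(p, s, zones$polygons$M)
  dline <- dist_to_antidiagonal(p, s)
  code[inM] <- "M"
  code[inB & dline > zones$e_band] <- "F"
  code[inB & dline <= zones$e_band] <- "E"
  code[inR] <- "R"
  code[inL] <- "L"
  code[inB & p < 0 & s > 0 & dline <= zones$ab_tolerance] <- "AB"
  out[ok] <- code
  out
}

#' Collapse fine codes to the coarse structural alphabet
#'
#' Maps E and F to B; all other codes are unchanged. This is the
#' five-letter alphabet (AB, R, L, B, M) used in motif notation.
#' @param code character vector of fine codes from [classify()].
#' @export
code_group <- function(code) {
  ifelse(code %in% c("E", "F"), "B", code)
}

#' Dispersion statistics of the structural classes
#'
#' For the R- and L-helical classes the dispersion is the mean Euclidean
#' distance of member (Phi, Psi) points to the class centroid (computed
#' from the members of the structure itself). For the beta-structural
#' area the dispersion is the mean distance to the Psi = -Phi line; the
#' E band (which includes the AB core) and the F remainder are reported
#' separately and jointly, with `count(E+F) = count(E) + count(F)` by
#' construction. Tight R/L/E dispersions are the signature of the flat
#' amyloid chain.
#'
#' @param d a [dihedral_series()].
#' @param zones a [zone_config()].
#' @return data frame of class `dispersion_report` with columns `class`,
#'   `mean_distance` (degrees; `NA` when the class is empty) and `count`.
#' @export
dispersion_report <- function(d, zones = zone_config()) {
  ok <- !is.na(d$phi) & !is.na(d$psi)
  if (!any(ok)) stop("no residues with defined (phi, psi)")
  phi <- d$phi[ok]; psi <- d$psi[ok]
  code <- classify(phi, psi, zones)
  helix_stat <- function(cl) {
    m <- code == cl
    if (!any(m)) return(c(NA_real_, 0))
    cen <- c(mean(phi[m]), mean(psi[m]))
    c(mean(sqrt((phi[m] - cen[1])^2 + (psi[m] - cen[2])^2)), sum(m))
  }
  beta <- code %in% c("AB", "E", "F")
  dl <- dist_to_antidiagonal(phi, psi)
  eMember <- beta & dl <= zones$e_band
  fMember <- beta & dl > zones$e_band
  beta_stat <- function(m) if (!any(m)) c(NA_real_, 0) else c(mean(dl[m]), sum(m))
  rows <- rbind(
    `R-helix` = helix_stat("R"),
    `L-helix` = helix_stat("L"),
    `E+F` = beta_stat(beta),
    E = beta_stat(eMember),
    F = beta_stat(fMember))
  out <- data.frame(class = rownames(rows), mean_distance = rows[, 1],
                    count = as.integer(rows[, 2]), row.names = NULL)
  class(out) <- c("dispersion_report", "data.frame")
  out
}

#' Compare per-residue conformations of two structures
#'
#' Pairs residues of a native and an amyloid (or any two) dihedral series
#' by author residue number and insertion code; residues present in only
#' one structure are skipped and reported in the `skipped` attribute.
#'
#' @param native,amyloid [dihedral_series()] objects.
#' @param zones a [zone_config()].
#' @param mode `"all"` for every common residue; `"L_in_amyloid"` for
#'   residues L-coded in the amyloid (reporting their native positions);
#'   `"R_in_native"` for residues R-coded in the native structure
#'   (reporting their amyloid positions).
#' @return data frame of migration records: res_number, native_phi/psi,
#'   amyloid_phi/psi, native_code, amyloid_code.
#' @export
compare_structures <- function(native, amyloid, zones = zone_config(),
                               mode = c("all", "L_in_amyloid", "R_in_native")) {
  mode <- match.arg(mode)
  kn <- paste(native$res_number, native$icode, sep = "|")
  ka <- paste(amyloid$res_number, amyloid$icode, sep = "|")
  common <- intersect(kn, ka)
  if (length(common) == 0) stop("structures share no residue numbers")
  i <- match(common, kn); j <- match(common, ka)
  rec <- data.frame(
    res_number = native$res_number[i],
    icode = native$icode[i],
    native_phi = native$phi[i], native_psi = native$psi[i],
    amyloid_phi = amyloid$phi[j], amyloid_psi = amyloid$psi[j])
  rec$native_code <- classify(rec$native_phi, rec$native_psi, zones)
  rec$amyloid_code <- classify(rec$amyloid_phi, rec$amyloid_psi, zones)
  keep <- switch(mode,
                 all = rep(TRUE, nrow(rec)),
                 L_in_amyloid = !is.na(rec$amyloid_code) & rec$amyloid_code == "L",
                 R_in_native = !is.na(rec$native_code) & rec$native_code == "R")
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- list(native_only = setdiff(kn, ka),
                               amyloid_only = setdiff(ka, kn))
  out
}

#' Count sequence mutations between two chains
#'
#' Positions are matched by author residue number and insertion code;
#' matched positions whose 3-letter residue names differ are counted.
#' Unmatched positions are excluded and reported in the `unmatched`
#' attribute.
#'
#' @param a,b [backbone_chain()] objects.
#' @return integer count with attribute `unmatched`.
#' @export
count_mutations <- function(a, b) {
  kaa <- paste(a$res_number, a$icode, sep = "|")
  kbb <- paste(b$res_number, b$icode, sep = "|")
  common <- intersect(kaa, kbb)
  if (length(common) == 0) stop("chains share no residue positions")
  i <- match(common, kaa); j <- match(common, kbb)
  n <- sum(a$res_name[i] != b$res_name[j])
  attr(n, "unmatched") <- list(a_only = setdiff(kaa, kbb),
                               b_only = setdiff(kbb, kaa))
  n
}
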
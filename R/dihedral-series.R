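#' Per-residue backbone dihedral angles
#'
#' A data frame of Phi/Psi/omega torsions in degrees, the coordinate system
#' of the Ramachandran plot and of the whole early-stage model. Angles are
#' kept in (-180, 180]; `NA` marks an undefined torsion (Phi at the chain
#' start, Psi/omega at the chain end, or a flanking atom missing).
#'
#' @param res_number integer author residue numbers.
#' @param phi,psi,omega numeric vectors in degrees (`NA` where undefined).
#' @param res_name optional 3-letter codes (defaults to alanine, the
#'   reference residue of the model's pentapeptide constructs).
#' @param icode optional insertion codes.
#' @return A data frame with class `dihedral_series`.
#' @export
dihedral_series <- function(res_number, phi, psi, omega = NULL,
                            res_name = NULL, icode = NULL) {
  n <- length(res_number)
  if (is.null(omega)) omega <- rep(180, n)
  if (is.null(res_name)) res_name <- rep("ALA", n)
  if (is.null(icode)) icode <- rep("", n)
  chk <- function(a) {
    a <- as.numeric(a)
    bad <- !is.na(a) & (a <= -180 | a > 180)
    if (any(bad)) a[bad] <- wrap_angle(a[bad])
    a
  }
  out <- data.frame(res_number = as.integer(res_number),
                    res_name = as.character(res_name),
                    icode = as.character(icode),
                    phi = chk(phi), psi = chk(psi), omega = chk(omega),
                    stringsAsFactors = FALSE)
  class(out) <- c("dihedral_series", "data.frame")
  out
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("dihedral_series: %d residues (%d with defined phi & psi)\n",
              nrow(x), sum(!is.na(x$phi) & !is.na(x$psi))))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat(sprintf("  ... %d more residues\n", nrow(x) - 8))
  invisible(x)
}

#' Write a dihedral series to TSV
#'
#' Columns res_number, res_name, phi, psi, omega, with a commented header
#' carrying provenance so every downstream table is auditable.
#'
#' @param d a `dihedral_series`.
#' @param path output file.
#' @param comment extra provenance lines (character vector), written as
#'   `# `-prefixed comments.
#' @export
write_dihedral_tsv <- function(d, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# espath %s dihedral series (degrees)",
                       as.character(utils::packageVersion("espath"))),
               paste0("# ", comment)), con)
  utils::write.table(
    data.frame(res_number = d$res_number, res_name = d$res_name,
               phi = round(d$phi, 4), psi = round(d$psi, 4),
               omega = round(d$omega, 4)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a dihedral series from TSV (the format written by
#' [write_dihedral_tsv()])
#' @param path TSV file with columns res_number, res_name, phi, psi, omega.
#' @return A `dihedral_series`.
#' @export
read_dihedral_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  dihedral_series(tab$res_number, tab$phi, tab$psi,
                  omega = if ("omega" %in% names(tab)) tab$omega else NULL,
                  res_name = if ("res_name" %in% names(tab)) tab$res_name else NULL)
}
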
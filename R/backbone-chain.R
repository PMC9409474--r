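#' Backbone chain container
#'
#' An ordered set of residues, each carrying the four backbone heavy atoms
#' N, CA, C, O. This is the structural substrate for every dihedral and
#' curvature computation in the package: the early-stage model assumes the
#' backbone alone decides the conformation, so side chains are never stored.
#'
#' @param res_number integer vector of author residue numbers (need not be
#'   strictly increasing; file order is authoritative).
#' @param res_name character vector of 3-letter residue codes.
#' @param N,CA,C,O numeric n x 3 coordinate matrices in Angstrom. Missing
#'   atoms are rows of `NA`; the residue is then flagged incomplete rather
#'   than dropped.
#' @param chain_id single character chain identifier.
#' @param icode insertion codes (default empty strings). Residue identity
#'   for cross-structure matching is the (res_number, icode) pair.
#'
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(res_number, res_name, N, CA, C, O,
                           chain_id = "A", icode = NULL) {
  n <- length(res_number)
  as_m <- function(x, what) {
    x <- as.matrix(x)
    if (n == 1 && length(x) == 3) x <- matrix(as.numeric(x), 1, 3)
    if (nrow(x) != n || ncol(x) != 3)
      stop(sprintf("%s must be an n x 3 coordinate matrix", what))
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
  }
  if (is.null(icode)) icode <- rep("", n)
  obj <- structure(list(
    chain_id = as.character(chain_id)[1],
    res_number = as.integer(res_number),
    res_name = as.character(res_name),
    icode = as.character(icode),
    N = as_m(N, "N"), CA = as_m(CA, "CA"), C = as_m(C, "C"), O = as_m(O, "O")
  ), class = "backbone_chain")
  obj$complete <- stats::complete.cases(cbind(obj$N, obj$CA, obj$C, obj$O))
  obj
}

#' @export
length.backbone_chain <- function(x) length(x$res_number)

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("backbone_chain: chain %s, %d residues (%d complete)\n",
              x$chain_id, length(x), sum(x$complete)))
  rng <- range(x$res_number)
  cat(sprintf("  residue numbers %d..%d; sequence %s...\n", rng[1], rng[2],
              paste(utils::head(x$res_name, 5), collapse = "-")))
  invisible(x)
}

#' Subset a backbone chain by residue positions
#' @param x a `backbone_chain`.
#' @param i positions (file order) to keep.
#' @param ... unused.
#' @export
`[.backbone_chain` <- function(x, i, ...) {
  backbone_chain(x$res_number[i], x$res_name[i],
                 x$N[i, , drop = FALSE], x$CA[i, , drop = FALSE],
                 x$C[i, , drop = FALSE], x$O[i, , drop = FALSE],
                 chain_id = x$chain_id, icode = x$icode[i])
}

#' @export
as.data.frame.backbone_chain <- function(x, ...) {
  n <- length(x)
  atoms <- c("N", "CA", "C", "O")
  xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(x$N[i, ], x$CA[i, ], x$C[i, ], x$O[i, ])))
  xyz <- stats::setNames(as.data.frame(xyz), c("x", "y", "z"))
  data.frame(
    res_number = rep(x$res_number, each = 4L),
    res_name = rep(x$res_name, each = 4L),
    icode = rep(x$icode, each = 4L),
    atom = rep(atoms, n),
    xyz,
    stringsAsFactors = FALSE
  )
}

#' Apply a rigid-body transform to a chain
#' @param x a `backbone_chain`.
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation applied after rotation.
#' @return the transformed chain.
#' @export
transform_chain <- function(x, R = diag(3), t = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% t(R), 2, -t)
  backbone_chain(x$res_number, x$res_name,
                 tr(x$N), tr(x$CA), tr(x$C), tr(x$O),
                 chain_id = x$chain_id, icode = x$icode)
}
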
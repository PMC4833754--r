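#' Atomic structure container
#'
#' A `trxss_structure` is a data frame of atoms with one row per atom and
#' columns `element` (upper-case element symbol), `elety` (atom name, e.g.
#' `"CA"`), `resid` (residue name), `resno` (residue number), `chain`
#' (chain identifier), `x`, `y`, `z` (coordinates, Angstrom), `type`
#' (`"ATOM"` or `"HETATM"`), `body` (rigid-body tag, `NA` until assigned),
#' `is_water` (logical, marks explicit water oxygens) and `h_count`
#' (number of hydrogens absorbed into this atom's form factor; 0 for plain
#' atoms).
#'
#' @param atoms data frame with at least `element`, `resno`, `chain`,
#'   `x`, `y`, `z`. Missing optional columns are filled with defaults.
#' @return object of class `trxss_structure`.
#' @export
structure_from_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(atoms$elety)) atoms$elety <- atoms$element
  if (is.null(atoms$resid)) atoms$resid <- "UNK"
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$body)) atoms$body <- NA_character_
  if (is.null(atoms$is_water)) atoms$is_water <- atoms$resid %in% c("HOH", "WAT")
  if (is.null(atoms$h_count)) atoms$h_count <- 0
  atoms$element <- toupper(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  atoms <- atoms[, c("type", "elety", "resid", "chain", "resno",
                     "x", "y", "z", "element", "body", "is_water", "h_count")]
  rownames(atoms) <- NULL
  class(atoms) <- c("trxss_structure", "data.frame")
  atoms
}

#' @export
print.trxss_structure <- function(x, ...) {
  cat(sprintf("<trxss_structure> %d atoms, chains: %s\n",
              nrow(x), paste(sort(unique(x$chain)), collapse = ", ")))
  nw <- sum(x$is_water)
  if (nw > 0) cat(sprintf("  %d explicit water oxygen(s)\n", nw))
  if (any(!is.na(x$body))) {
    cat(sprintf("  %d rigid bodies assigned\n", length(unique(stats::na.omit(x$body)))))
  }
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure a `trxss_structure`
#' @param idx optional row (atom) indices
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(structure, idx = NULL) {
  m <- as.matrix(as.data.frame(structure)[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace coordinates of (a subset of) atoms
#'
#' @inheritParams coords
#' @param xyz replacement n x 3 matrix
#' @return modified structure
#' @export
set_coords <- function(structure, xyz, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(structure))
  stopifnot(nrow(xyz) == length(idx))
  structure$x[idx] <- xyz[, 1]
  structure$y[idx] <- xyz[, 2]
  structure$z[idx] <- xyz[, 3]
  structure
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; `axis` need not be normalised.
#'
#' @param axis length-3 vector
#' @param angle rotation angle in degrees
#' @return 3x3 proper rotation matrix
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a subset of atoms
#'
#' Rotates the selected atoms about `center` by `rot` and then translates
#' them; all other atoms are untouched. Intra-subset distances are exactly
#' preserved (up to floating point).
#'
#' @param structure a `trxss_structure`
#' @param idx atom indices to move
#' @param rot 3x3 rotation matrix (default identity)
#' @param center 3-vector, rotation origin (default centroid of the subset)
#' @param translation 3-vector added after rotation (default zero)
#' @return modified structure
#' @export
transform_atoms <- function(structure, idx, rot = diag(3), center = NULL,
                            translation = c(0, 0, 0)) {
  xyz <- coords(structure, idx)
  if (is.null(center)) center <- colMeans(xyz)
  moved <- sweep(xyz, 2, center) %*% t(rot)
  moved <- sweep(moved, 2, center + translation, FUN = "+")
  set_coords(structure, moved, idx)
}

# centroid of a set of atoms
atom_centroid <- function(structure, idx) colMeans(coords(structure, idx))
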
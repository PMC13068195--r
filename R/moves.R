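# Rigid-body and torsional moves. All angles in degrees in the public API.

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th); C <- 1 - c
  matrix(c(a[1]^2 * C + c,        a[1]*a[2]*C - a[3]*s,  a[1]*a[3]*C + a[2]*s,
           a[1]*a[2]*C + a[3]*s,  a[2]^2 * C + c,        a[2]*a[3]*C - a[1]*s,
           a[1]*a[3]*C - a[2]*s,  a[2]*a[3]*C + a[1]*s,  a[3]^2 * C + c),
         3, 3, byrow = TRUE)
}

#' Apply a translation, rigid rotation, or torsion rotation
#'
#' Translations and rotations are rigid (all interatomic distances
#' preserved); rotations are about the heavy-atom centroid. A torsion move
#' rotates only the atoms distal to the rotated bond, about the bond axis.
#'
#' @param mol A [new_molecule()].
#' @param move One of "translate", "rotate", "torsion".
#' @param delta For "translate", a length-3 displacement (A). For "rotate", a
#'   rotation angle (degrees); `axis` gives the axis. For "torsion", the
#'   rotation angle (degrees); `torsion` selects which rotatable torsion.
#' @param axis Rotation axis for "rotate" (default random is not drawn here;
#'   supply explicitly).
#' @param torsion Index into [rotatable_torsions()] for "torsion" moves.
#' @return The molecule with updated coordinates.
#' @export
apply_move <- function(mol, move = c("translate", "rotate", "torsion"),
                       delta, axis = c(0, 0, 1), torsion = 1L) {
  move <- match.arg(move)
  if (move == "translate") {
    stopifnot(length(delta) == 3)
    mol$xyz <- sweep(mol$xyz, 2, as.numeric(delta), "+")
  } else if (move == "rotate") {
    ctr <- colMeans(mol$xyz)
    R <- rotation_matrix(as.numeric(axis), delta)
    mol$xyz <- sweep(sweep(mol$xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  } else {
    tors <- rotatable_torsions(mol)
    if (nrow(tors) == 0) stop("torsion move requested on a rigid molecule")
    if (torsion < 1 || torsion > nrow(tors)) stop("torsion index out of range")
    b <- tors[torsion, "b"]; c_ <- tors[torsion, "c"]
    moving <- distal_atoms(mol, b, c_)
    axis_v <- mol$xyz[c_, ] - mol$xyz[b, ]
    R <- rotation_matrix(axis_v, delta)
    pivot <- mol$xyz[b, ]
    mol$xyz[moving, ] <- sweep(sweep(mol$xyz[moving, , drop = FALSE], 2, pivot) %*% t(R),
                               2, pivot, "+")
  }
  mol
}

#' Draw one random MC move within stated limits
#'
#' One move type is chosen uniformly at random among translation, rigid
#' rotation and (when the molecule has rotatable torsions) torsion rotation;
#' the magnitude is uniform in (0, max]. Uses R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param mol A [new_molecule()].
#' @param max_translate,max_rotate,max_torsion Move limits (A, deg, deg).
#' @return The moved molecule.
#' @export
random_move <- function(mol, max_translate, max_rotate, max_torsion) {
  has_tors <- nrow(rotatable_torsions(mol)) > 0
  kind <- sample.int(if (has_tors) 3L else 2L, 1L)
  if (kind == 1L) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, max_translate)
    apply_move(mol, "translate", v)
  } else if (kind == 2L) {
    ax <- stats::rnorm(3)
    apply_move(mol, "rotate", stats::runif(1, -max_rotate, max_rotate), axis = ax)
  } else {
    k <- sample.int(nrow(rotatable_torsions(mol)), 1L)
    apply_move(mol, "torsion", stats::runif(1, -max_torsion, max_torsion),
               torsion = k)
  }
}
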
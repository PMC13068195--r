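# Reduced intramolecular energy: generic torsional term plus nonbonded
# Lennard-Jones and Coulomb over atom pairs separated by three or more
# bonds, with the distance-dependent dielectric eps(r) = 4r. This keeps the
# stated dielectric treatment while staying analytic; rigid molecules have a
# conformation-independent value, which all oracle tests exploit.

# generic per-element LJ parameters (Rmin/2 in A, epsilon in kcal/mol)
.LJ_PARAMS <- list(
  C = c(rmin2 = 2.00, eps = 0.070),
  N = c(rmin2 = 1.85, eps = 0.170),
  O = c(rmin2 = 1.70, eps = 0.120),
  S = c(rmin2 = 2.00, eps = 0.450),
  default = c(rmin2 = 1.90, eps = 0.100)
)

lj_params_for <- function(elements) {
  known <- toupper(elements) %in% names(.LJ_PARAMS)
  p <- lapply(toupper(elements), function(e)
    if (e %in% names(.LJ_PARAMS)) .LJ_PARAMS[[e]] else .LJ_PARAMS$default)
  list(rmin2 = vapply(p, `[[`, 0, "rmin2"), eps = vapply(p, `[[`, 0, "eps"),
       fallback = !all(known))
}

# precompute the nonbonded pair list (graph separation >= 3 bonds)
nonbonded_pairs <- function(mol) {
  n <- n_atoms(mol)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- bond_distances(mol)
  idx <- which(upper.tri(d) & d >= 3, arr.ind = TRUE)
  unname(idx)
}

#' Reduced intramolecular energy of a ligand conformation
#'
#' Sum of a generic threefold torsional term over the rotatable torsions,
#' plus Lennard-Jones and Coulomb terms over heavy-atom pairs separated by
#' at least three bonds. The Coulomb term uses the distance-dependent
#' dielectric eps(r) = 4r, i.e. `332.06 * qi*qj / (4 r^2)` kcal/mol.
#' Deterministic for fixed coordinates, and invariant under rigid-body
#' moves.
#'
#' @param mol A [new_molecule()]; partial charges come from `mol$pcharges`.
#' @param components If TRUE return a list with `torsion`, `lj`, `coulomb`,
#'   `total`; otherwise the total (kcal/mol).
#' @param torsion_barrier Barrier height of the generic threefold torsional
#'   term (kcal/mol, default 0.2).
#' @return Energy in kcal/mol (or component list).
#' @export
intramolecular_energy <- function(mol, components = FALSE, torsion_barrier = 0.2) {
  pairs <- if (!is.null(mol$nb_pairs)) mol$nb_pairs else nonbonded_pairs(mol)
  lj <- 0; coul <- 0
  if (nrow(pairs) > 0) {
    dvec <- mol$xyz[pairs[, 1], , drop = FALSE] - mol$xyz[pairs[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    p <- lj_params_for(mol$elements)
    rmin <- p$rmin2[pairs[, 1]] + p$rmin2[pairs[, 2]]
    eps <- sqrt(p$eps[pairs[, 1]] * p$eps[pairs[, 2]])
    sr6 <- (rmin / r)^6
    lj <- sum(eps * (sr6^2 - 2 * sr6))
    q <- mol$pcharges
    coul <- sum(.COULOMB_KCAL * q[pairs[, 1]] * q[pairs[, 2]] / (4 * r^2))
  }
  tors_e <- 0
  tors <- rotatable_torsions(mol)
  if (nrow(tors) > 0) {
    phi <- vapply(seq_len(nrow(tors)), function(k)
      dihedral_angle(mol$xyz[tors[k, 1], ], mol$xyz[tors[k, 2], ],
                     mol$xyz[tors[k, 3], ], mol$xyz[tors[k, 4], ]), 0)
    tors_e <- sum(torsion_barrier * (1 + cos(3 * phi)))
  }
  total <- tors_e + lj + coul
  if (components) list(torsion = tors_e, lj = lj, coulomb = coul, total = total)
  else total
}

# dihedral angle in radians
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2]*b2[3] - b1[3]*b2[2], b1[3]*b2[1] - b1[1]*b2[3], b1[1]*b2[2] - b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3] - b2[3]*b3[2], b2[3]*b3[1] - b2[1]*b3[3], b2[1]*b3[2] - b2[2]*b3[1])
  m1 <- c(n1[2]*b2[3] - n1[3]*b2[2], n1[3]*b2[1] - n1[1]*b2[3], n1[1]*b2[2] - n1[2]*b2[1])
  b2n <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / b2n, sum(n1 * n2))
}
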
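#' Assign FragMap classes to ligand atoms
#'
#' Every heavy atom receives exactly one class from [fragmap_classes()] plus
#' `"none"`, by walking a priority rule table:
#' positive > negative > donor > acceptor > aromatic > aliphatic.
#' Positively/negatively charged atoms are those carrying formal charge
#' (quaternary/protonated nitrogens, carboxylate oxygens, guanidinium
#' nitrogens); donors are N/O with at least one attached hydrogen; acceptors
#' are any other N/O; aromatic atoms carry the aromatic flag; aliphatic
#' atoms are the remaining carbons. Atoms matching no rule (halogens,
#' phosphorus, non-acceptor sulfur) are classed `"none"`.
#'
#' The assignment is deterministic and invariant to atom order.
#'
#' @param mol A [new_molecule()].
#' @return Character vector, one class per heavy atom.
#' @export
classify_atoms <- function(mol) {
  n <- n_atoms(mol)
  cls <- rep("none", n)
  el <- toupper(mol$elements)
  pick <- function(current, rule, label) ifelse(current == "none" & rule, label, current)
  cls <- pick(cls, mol$charges > 0, "positive")
  cls <- pick(cls, mol$charges < 0, "negative")
  cls <- pick(cls, el %in% c("N", "O") & mol$nH >= 1, "donor")
  cls <- pick(cls, el %in% c("N", "O"), "acceptor")
  cls <- pick(cls, mol$aromatic, "aromatic")
  cls <- pick(cls, el == "C", "aliphatic")
  cls
}

# classes for LGFE: use cached assignment when present
atom_classes <- function(mol) {
  if (!is.null(mol$classes)) {
    cl <- mol$classes
    if (anyNA(cl)) cl[is.na(cl)] <- classify_atoms(mol)[is.na(cl)]
    cl
  } else classify_atoms(mol)
}
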
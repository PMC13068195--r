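#' Drug-likeness descriptors
#'
#' Molecular weight (standard atomic masses, implicit hydrogens included),
#' Crippen-style atom-contribution logP, hydrogen-bond donor count (N-H/O-H
#' groups) and acceptor count (N + O atoms, the classical rule-of-five
#' definition). Weight, logP and HBD come from OpenBabel's descriptor
#' engine on the record's SMILES; HBA is counted from the element list.
#'
#' @param mol A [new_molecule()] with a `smiles` field, or a SMILES string.
#' @return One-row data frame: `id`, `mw` (Da), `logp` (2 decimals), `hbd`,
#'   `hba`.
#' @export
compute_descriptors <- function(mol) {
  if (is.character(mol)) mol <- list(id = mol, smiles = mol, elements = NULL)
  if (is.null(mol$smiles)) stop("molecule has no SMILES record")
  d <- descriptor_table(stats::setNames(mol$smiles, mol$id))
  if (!is.null(mol$elements) && is.na(d$hba))
    d$hba <- sum(toupper(mol$elements) %in% c("N", "O"))
  d
}

#' Descriptor table for a set of SMILES
#'
#' Vectorized form of [compute_descriptors()].
#'
#' @param smiles Named character vector of SMILES (names become ids).
#' @return Data frame with columns `id`, `mw`, `logp`, `hbd`, `hba`.
#' @export
descriptor_table <- function(smiles) {
  ids <- if (is.null(names(smiles))) paste0("m", seq_along(smiles)) else names(smiles)
  input <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  props <- ChemmineOB::prop_OB(mols)
  # N+O acceptor count from the molecular formula
  hba <- vapply(props$formula, function(f) {
    count_elem <- function(sym) {
      m <- regmatches(f, gregexpr(paste0(sym, "(?![a-z])([0-9]*)"), f, perl = TRUE))[[1]]
      if (!length(m)) return(0L)
      sum(vapply(m, function(x) {
        k <- sub(paste0("^", sym), "", x)
        if (nzchar(k)) as.integer(k) else 1L
      }, integer(1)))
    }
    count_elem("N") + count_elem("O")
  }, integer(1), USE.NAMES = FALSE)
  data.frame(id = ids[as.integer(props$title)],
             mw = props$MW, logp = round(props$logP, 2),
             hbd = as.integer(props$HBD), hba = as.integer(hba),
             row.names = NULL)[order(as.integer(props$title)), , drop = FALSE]
}
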
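# Physical constants used across the package (kcal/mol unit system, Angstroms)
.GAS_CONSTANT_KCAL <- 1.9872042586e-3  # kcal mol^-1 K^-1
.AVOGADRO <- 6.02214076e23             # mol^-1
.COULOMB_KCAL <- 332.06                # kcal A mol^-1 e^-2, conventional MM constant

#' FragMap functional-group classes
#'
#' The six generic functional-group map classes carried by a
#' [fragmap_set()]: aromatic, aliphatic, hydrogen-bond donor, hydrogen-bond
#' acceptor, positively charged, negatively charged. Solute probes used in
#' occupancy sampling (benzene, propane, formamide, methanol, dimethyl
#' ether, imidazole, acetate, methylammonium) are representative of these
#' classes; the default solute-to-class table is [default_solute_classes()].
#'
#' @return Character vector of the six class labels.
#' @export
fragmap_classes <- function() {
  c("aromatic", "aliphatic", "donor", "acceptor", "positive", "negative")
}

#' Default solute-to-map-class table
#'
#' Maps the eight standard solute probes onto the six generic map classes.
#' Users running their own occupancy sampling can supply a different table.
#'
#' @return Named character vector: names are solute names, values are map
#'   classes from [fragmap_classes()].
#' @export
default_solute_classes <- function() {
  c(benzene = "aromatic", propane = "aliphatic",
    formamide = "donor", methanol = "donor",
    `dimethyl ether` = "acceptor", imidazole = "acceptor",
    acetate = "negative", methylammonium = "positive")
}
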
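## Physical constants and bundled amino-acid tables.

#' @importFrom utils read.csv write.csv head
NULL

## Monoisotopic residue masses (Da) for the 20 standard amino acids.
## Residue mass = amino acid minus water, i.e. the mass contributed inside a
## peptide chain.
.AA <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

.PROTON_MASS <- 1.007276
.WATER_MASS <- 18.010565

## Null residue symbol used to pad the sequence window at peptide edges.
.NULL_RESIDUE <- "_"

## The four predicted fragment-ion series: singly and doubly protonated
## b and y ions. Column order is fixed package-wide.
.ION_SERIES <- c("b", "y", "b2", "y2")

#' Mass constants used throughout the package
#'
#' Returns the immutable monoisotopic mass table: the 20 standard residue
#' masses, the proton mass used for charging, and the mass of water.
#'
#' @return A list with elements `residues` (named numeric vector of 20
#'   monoisotopic residue masses in Da), `proton` (Da) and `water` (Da).
#' @examples
#' massConstants()$residues[["G"]]
#' @export
massConstants <- function() {
  list(residues = .RESIDUE_MASS, proton = .PROTON_MASS, water = .WATER_MASS)
}

#' Read an amino-acid property table
#'
#' Loads the per-residue physicochemical scales (basicity, hydrophobicity,
#' helicity, isoelectric point) used by the feature encoder. The table is
#' bundled as a plain CSV so alternative scales can be swapped in without
#' code changes.
#'
#' @param path Path to a CSV with columns `residue`, `basicity`,
#'   `hydrophobicity`, `helicity`, `pI`. Defaults to the bundled table.
#' @return A 20-row data.frame, one row per standard residue, with the four
#'   numeric scales; row names are the residue letters.
#' @export
readPropertyTable <- function(path = system.file("extdata",
                                                 "property_scales.csv",
                                                 package = "ms2forest")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "basicity", "hydrophobicity", "helicity", "pI")
  if (!all(need %in% names(tab)))
    stop("property table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(tab$residue, .AA))
    stop("property table must cover exactly the 20 standard residues")
  rownames(tab) <- tab$residue
  tab <- tab[.AA, ]
  for (col in need[-1])
    if (any(!is.finite(tab[[col]]))) stop("non-finite value in scale ", col)
  tab
}

## cached default property table (loaded once per session)
.pkg_cache <- new.env(parent = emptyenv())

.defaultPropertyTable <- function() {
  if (is.null(.pkg_cache$props)) .pkg_cache$props <- readPropertyTable()
  .pkg_cache$props
}
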
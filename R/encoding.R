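## Feature encoding: (peptide, precursor charge, cleavage site) -> fixed-
## length numeric vector (schema v1).
##
## The schema deliberately encodes a modification as "present + how heavy"
## (summed mass shifts, modification counts/indicators) and never the PTM
## identity, so models generalize across modification types. Vector length
## is independent of peptide length, so no length window is imposed.

.SCHEMA_VERSION <- "v1"
.PROP_SCALES <- c("basicity", "hydrophobicity", "helicity", "pI")
.WINDOW_POS <- c("m1", "p0", "p1", "p2")  # site-1, site, site+1, site+2

.featureNames <- function() {
  c("pep_len", "rel_pos", "prec_charge",
    as.vector(t(outer(.PROP_SCALES, c("full", "pre", "suf"), paste,
                      sep = "_"))),
    as.vector(t(outer(.WINDOW_POS, c(.AA, "null"), function(a, b)
      paste0("id_", a, "_", b)))),
    paste0("cnt_pre_", .AA), paste0("cnt_suf_", .AA),
    "ptm_mass_pre", "ptm_mass_suf", "n_mod_pre", "n_mod_suf",
    "mod_at_site", "mod_at_next")
}

#' Names of the schema v1 feature vector
#'
#' @return character vector of feature names, in encoding order.
#' @export
featureNames <- function() .featureNames()

#' Encode every cleavage site of a peptide
#'
#' Computes the full (L-1) x p feature matrix for a peptide at a given
#' precursor charge, one row per cleavage site. Features (schema v1):
#' peptide length; relative site position; precursor charge; mean
#' basicity/hydrophobicity/helicity/pI over the full peptide, the prefix
#' and the suffix; one-hot residue identity at site-1, site, site+1 and
#' site+2 (null-padded at the edges); counts of the 20 residues in prefix
#' and suffix; summed PTM mass shift in prefix and suffix (terminal
#' modifications count toward their side); number of modified residues per
#' side; and modified-residue indicators at the site and the next position.
#'
#' @param p a \linkS4class{Peptide}
#' @param registry a \linkS4class{PTMRegistry}
#' @param precursorCharge 2 or 3
#' @param propTable amino-acid property table (defaults to the bundled one)
#' @return numeric matrix, rows = sites 1..L-1, columns = [featureNames()]
#' @export
encodePeptide <- function(p, registry, precursorCharge,
                          propTable = NULL) {
  if (is.null(propTable)) propTable <- .defaultPropertyTable()
  seqv <- strsplit(p@sequence, "")[[1]]
  L <- length(seqv)
  nS <- L - 1L
  sites <- seq_len(nS)
  ri <- match(seqv, .AA)

  ## residue indicator and cumulative composition
  M <- matrix(0, L, 20L)
  M[cbind(seq_len(L), ri)] <- 1
  cumCnt <- apply(M, 2L, cumsum)
  preCnt <- cumCnt[sites, , drop = FALSE]
  totCnt <- matrix(cumCnt[L, ], nS, 20L, byrow = TRUE)
  sufCnt <- totCnt - preCnt

  ## property means
  P <- as.matrix(propTable[seqv, .PROP_SCALES])
  cumP <- apply(P, 2L, cumsum)
  fullMean <- matrix(cumP[L, ] / L, nS, 4L, byrow = TRUE)
  preMean <- cumP[sites, , drop = FALSE] / sites
  sufMean <- (matrix(cumP[L, ], nS, 4L, byrow = TRUE) -
                cumP[sites, , drop = FALSE]) / (L - sites)
  propBlock <- matrix(0, nS, 12L)
  for (k in seq_len(4L))
    propBlock[, (k - 1L) * 3L + 1:3] <-
      cbind(fullMean[, k], preMean[, k], sufMean[, k])

  ## one-hot identity window (21 symbols incl. null padding)
  pv <- c(21L, ri, 21L, 21L)  # residue j sits at pv[j + 1]
  oneHot <- matrix(0, nS, 84L)
  for (w in seq_len(4L)) {      # window offsets -1, 0, +1, +2
    symb <- pv[sites + w - 1L]  # residue (site + w - 2) sits at pv[site+w-1]
    oneHot[cbind(sites, (w - 1L) * 21L + symb)] <- 1
  }

  ## PTM-derived features
  sh <- numeric(L)
  modFlag <- numeric(L)
  if (length(p@residueMods)) {
    pos <- as.integer(names(p@residueMods))
    sh[pos] <- vapply(p@residueMods, function(s) ptmShift(registry, s),
                      numeric(1))
    modFlag[pos] <- 1
  }
  ntermShift <- if (p@nTerm != "H-") ptmShift(registry, p@nTerm) else 0
  ctermShift <- if (p@cTerm != "-OH") ptmShift(registry, p@cTerm) else 0
  cumSh <- cumsum(sh)
  cumMod <- cumsum(modFlag)
  ptmPre <- cumSh[sites] + ntermShift
  ptmSuf <- (cumSh[L] - cumSh[sites]) + ctermShift
  nModPre <- cumMod[sites]
  nModSuf <- cumMod[L] - cumMod[sites]

  X <- cbind(L, sites / nS, as.integer(precursorCharge), propBlock, oneHot,
             preCnt, sufCnt, ptmPre, ptmSuf, nModPre, nModSuf,
             modFlag[sites], modFlag[sites + 1L])
  colnames(X) <- .featureNames()
  X
}

#' Encode a single cleavage site
#'
#' Convenience wrapper around [encodePeptide()] returning one row.
#'
#' @inheritParams encodePeptide
#' @param site cleavage site, 1..L-1 (between residues `site` and `site+1`)
#' @return named numeric vector of length `length(featureNames())`
#' @export
encodeSite <- function(p, registry, precursorCharge, site,
                       propTable = NULL) {
  L <- peptideLength(p)
  if (site < 1L || site > L - 1L)
    stop(sprintf("site out of range [1, %d]", L - 1L))
  encodePeptide(p, registry, precursorCharge, propTable)[site, ]
}
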
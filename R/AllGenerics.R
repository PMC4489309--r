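## Generics and accessors. Slots are never touched outside the package.

#' @describeIn Peptide the plain residue sequence
#' @param x,object a \linkS4class{Peptide}
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @describeIn Peptide named character vector of residue modifications
#'   (names are 1-based positions)
#' @export
setGeneric("residueMods", function(x) standardGeneric("residueMods"))

#' @describeIn Peptide the N-terminal symbol (default `"H-"`)
#' @export
setGeneric("nTerm", function(x) standardGeneric("nTerm"))

#' @describeIn Peptide the C-terminal symbol (default `"-OH"`)
#' @export
setGeneric("cTerm", function(x) standardGeneric("cTerm"))

#' Precursor charge of a spectrum, training set or model
#' @param x an \linkS4class{ObservedSpectrum}, \linkS4class{TrainingSet} or
#'   \linkS4class{IntensityModel}
#' @return integer(1)
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

#' Peak matrix of a spectrum
#' @param x an \linkS4class{ObservedSpectrum}
#' @return two-column numeric matrix (`mz`, `intensity`)
#' @export
setGeneric("peakMatrix", function(x) standardGeneric("peakMatrix"))

#' Spectrum title
#' @param x an \linkS4class{ObservedSpectrum}
#' @export
setGeneric("spectrumTitle", function(x) standardGeneric("spectrumTitle"))

#' Target matrix of a TargetVector
#' @param x a \linkS4class{TargetVector}
#' @return numeric matrix (L-1) x 4, columns `b`, `y`, `b2`, `y2`
#' @export
setGeneric("intensityTargets", function(x) standardGeneric("intensityTargets"))

#' Which target entries were matched to an observed peak
#' @param x a \linkS4class{TargetVector}
#' @export
setGeneric("matchedFlags", function(x) standardGeneric("matchedFlags"))

#' Fragmentation method label of a training set or model
#' @param x a \linkS4class{TrainingSet} or \linkS4class{IntensityModel}
#' @export
setGeneric("fragMethod", function(x) standardGeneric("fragMethod"))

#' Feature schema version of a training set or model
#' @param x a \linkS4class{TrainingSet} or \linkS4class{IntensityModel}
#' @export
setGeneric("schemaVersion", function(x) standardGeneric("schemaVersion"))

setMethod("peptideSequence", "Peptide", function(x) x@sequence)
setMethod("residueMods", "Peptide", function(x) x@residueMods)
setMethod("nTerm", "Peptide", function(x) x@nTerm)
setMethod("cTerm", "Peptide", function(x) x@cTerm)

#' Number of residues in a peptide
#' @param p a \linkS4class{Peptide}
#' @return integer(1)
#' @export
peptideLength <- function(p) nchar(p@sequence)

setMethod("precursorCharge", "ObservedSpectrum", function(x) x@precursorCharge)
setMethod("precursorCharge", "TrainingSet", function(x) x@precursorCharge)
setMethod("precursorCharge", "IntensityModel", function(x) x@precursorCharge)
setMethod("peakMatrix", "ObservedSpectrum", function(x) x@peaks)
setMethod("spectrumTitle", "ObservedSpectrum", function(x) x@title)
setMethod("intensityTargets", "TargetVector", function(x) x@targets)
setMethod("matchedFlags", "TargetVector", function(x) x@matched)
setMethod("fragMethod", "TrainingSet", function(x) x@method)
setMethod("fragMethod", "IntensityModel", function(x) x@method)
setMethod("schemaVersion", "TrainingSet", function(x) x@schemaVersion)
setMethod("schemaVersion", "IntensityModel", function(x) x@schemaVersion)

#' Training configuration of a fitted model
#' @param m an \linkS4class{IntensityModel}
#' @return list of training settings (trees, seed, normalization id, sizes)
#' @export
trainingConfig <- function(m) m@trainingConfig

setMethod("show", "Peptide", function(object) {
  nm <- length(object@residueMods)
  cat(sprintf("Peptide: %s (%d residues, %d modification%s)\n",
              renderPeptide(object), peptideLength(object), nm,
              if (nm == 1) "" else "s"))
})

setMethod("show", "PTMRegistry", function(object) {
  cat(sprintf("PTMRegistry with %d symbol%s (cap %d):\n",
              nrow(object@table), if (nrow(object@table) == 1) "" else "s",
              object@maxEntries))
  if (nrow(object@table))
    print(object@table[, c("symbol", "name", "mass_shift", "residues")],
          row.names = FALSE)
})

setMethod("show", "ObservedSpectrum", function(object) {
  cat(sprintf("ObservedSpectrum '%s': charge %d+, pepmass %.4f, %d peaks\n",
              object@title, object@precursorCharge, object@pepmass,
              nrow(object@peaks)))
})

setMethod("show", "TargetVector", function(object) {
  cat(sprintf(
    "TargetVector: %d sites x 4 series, %d/%d matched, eps = %.3g (%s)\n",
    nrow(object@targets), sum(object@matched), length(object@matched),
    object@epsilon, object@normalization))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf(
    "TrainingSet [%s, charge %d+]: %d sites from %d PSMs, schema %s\n",
    object@method, object@precursorCharge, nrow(object@features),
    length(unique(object@psm)), object@schemaVersion))
})

setMethod("show", "IntensityModel", function(object) {
  cfg <- object@trainingConfig
  cat(sprintf(
    "IntensityModel [%s, charge %d+]: 4 forests (%s trees, seed %s), schema %s\n",
    object@method, object@precursorCharge,
    if (is.null(cfg$num.trees)) "?" else cfg$num.trees,
    if (is.null(cfg$seed)) "?" else cfg$seed, object@schemaVersion))
})

setMethod("show", "FragmentationParams", function(object) {
  cat(sprintf(
    "FragmentationParams '%s': base b/y/b2/y2 = %s; sigma %.2f, dropout %.2f, decoy %.2f\n",
    object@name, paste(format(object@basePeak), collapse = "/"),
    object@noiseSigma, object@dropout, object@decoyRate))
})
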
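#' @import methods
NULL

## ---------------------------------------------------------------------------
## PTMRegistry
## ---------------------------------------------------------------------------

#' Registry of post-translational modification definitions
#'
#' Holds the lowercase PTM symbols a run understands, each with a display
#' name, a monoisotopic mass shift (Da) and the set of residues (or the
#' terminal markers `n-term` / `c-term`) it may annotate. Internal (residue)
#' symbols contain no dash; N-terminal symbols end in `-` (e.g. `ace-`),
#' C-terminal symbols start with `-` (e.g. `-am`). At most `maxEntries`
#' symbols are accepted per run unless the loader is told otherwise.
#'
#' @slot table data.frame with columns `symbol`, `name`, `mass_shift`,
#'   `residues` (comma-separated scope).
#' @slot maxEntries integer cap on the number of symbols.
#' @aliases PTMRegistry
#' @exportClass PTMRegistry
setClass("PTMRegistry",
         representation(table = "data.frame", maxEntries = "integer"))

setValidity("PTMRegistry", function(object) {
  tab <- object@table
  need <- c("symbol", "name", "mass_shift", "residues")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tab) == 0) return(TRUE)
  sym <- tab$symbol
  if (anyDuplicated(sym)) return("duplicate PTM symbols")
  if (any(!nzchar(sym))) return("empty PTM symbol")
  if (any(grepl("[^a-z-]", sym))) return("PTM symbols must be lowercase letters")
  internal <- !grepl("-$", sym) & !grepl("^-", sym)
  if (any(grepl("-", sym[internal])))
    return("internal PTM symbols may not contain '-'")
  if (any(!is.finite(tab$mass_shift))) return("non-finite mass shift")
  nterm <- grepl("-$", sym)
  cterm <- grepl("^-", sym)
  scope <- strsplit(tab$residues, ",[ ]*")
  for (i in seq_along(sym)) {
    if (nterm[i] && !identical(scope[[i]], "n-term"))
      return(sprintf("N-terminal symbol '%s' must have scope 'n-term'", sym[i]))
    if (cterm[i] && !identical(scope[[i]], "c-term"))
      return(sprintf("C-terminal symbol '%s' must have scope 'c-term'", sym[i]))
    if (!nterm[i] && !cterm[i] && !all(scope[[i]] %in% .AA))
      return(sprintf("symbol '%s' has a non-standard residue in its scope",
                     sym[i]))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Peptide
## ---------------------------------------------------------------------------

#' A parsed peptide with positioned modifications and termini
#'
#' The canonical in-memory form of an `H-P-OH` peptide string: the plain
#' residue sequence in capital one-letter codes, a map from 1-based residue
#' position to the PTM symbol sitting there (at most one per position), and
#' the two terminal symbols (`H-` and `-OH` by default).
#'
#' @slot sequence character(1), capital one-letter residue codes, length >= 2.
#' @slot residueMods named character vector; names are 1-based positions.
#' @slot nTerm character(1), `"H-"` or a registered N-terminal symbol.
#' @slot cTerm character(1), `"-OH"` or a registered C-terminal symbol.
#' @aliases Peptide
#' @exportClass Peptide
setClass("Peptide",
         representation(sequence = "character", residueMods = "character",
                        nTerm = "character", cTerm = "character"),
         prototype(residueMods = character(0), nTerm = "H-", cTerm = "-OH"))

setValidity("Peptide", function(object) {
  s <- object@sequence
  if (length(s) != 1L || nchar(s) < 2L) return("sequence must have length >= 2")
  if (grepl(sprintf("[^%s]", paste(.AA, collapse = "")), s))
    return("sequence contains a non-standard residue code")
  mods <- object@residueMods
  if (length(mods)) {
    pos <- suppressWarnings(as.integer(names(mods)))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > nchar(s)))
      return("modification position out of range")
    if (anyDuplicated(pos)) return("more than one modification on a residue")
  }
  if (!grepl("-$", object@nTerm)) return("nTerm symbol must end in '-'")
  if (!grepl("^-", object@cTerm)) return("cTerm symbol must start with '-'")
  TRUE
})

## ---------------------------------------------------------------------------
## ObservedSpectrum
## ---------------------------------------------------------------------------

#' An observed (or simulated) MS2 spectrum
#'
#' One MGF block: a title, the precursor charge (2 or 3), the precursor m/z
#' (PEPMASS) and a peak list sorted by ascending m/z.
#'
#' @slot title character(1).
#' @slot precursorCharge integer(1), 2 or 3.
#' @slot pepmass numeric(1), precursor m/z in Th.
#' @slot peaks two-column numeric matrix (`mz`, `intensity`), mz ascending.
#' @aliases ObservedSpectrum
#' @exportClass ObservedSpectrum
setClass("ObservedSpectrum",
         representation(title = "character", precursorCharge = "integer",
                        pepmass = "numeric", peaks = "matrix"))

setValidity("ObservedSpectrum", function(object) {
  if (!object@precursorCharge %in% c(2L, 3L))
    return("precursor charge must be 2 or 3")
  pk <- object@peaks
  if (ncol(pk) != 2L) return("peaks must have two columns (mz, intensity)")
  if (nrow(pk)) {
    if (any(pk[, 2] < 0)) return("negative peak intensity")
    if (is.unsorted(pk[, 1])) return("peaks must be sorted by ascending mz")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## TargetVector
## ---------------------------------------------------------------------------

#' Normalized regression targets for one peptide-spectrum match
#'
#' For each of the four ion series (b+, y+, b++, y++) a vector of length
#' L-1 of TIC-normalized, log2-transformed intensities, indexed by ion
#' index (row i holds b_i, y_i, b_i++, y_i++). Entries with no observed
#' peak within tolerance hold the baseline `log2(epsilon)`.
#'
#' @slot targets numeric matrix, (L-1) x 4, columns `b`, `y`, `b2`, `y2`.
#' @slot matched logical matrix of the same shape.
#' @slot epsilon numeric(1), the additive constant inside the log2.
#' @slot normalization character(1) identifier of the transform.
#' @aliases TargetVector
#' @exportClass TargetVector
setClass("TargetVector",
         representation(targets = "matrix", matched = "matrix",
                        epsilon = "numeric", normalization = "character"))

setValidity("TargetVector", function(object) {
  t <- object@targets
  if (!identical(colnames(t), .ION_SERIES))
    return("target columns must be b, y, b2, y2")
  if (!identical(dim(t), dim(object@matched)))
    return("targets and matched must have identical shape")
  if (any(!is.finite(t))) return("non-finite target")
  TRUE
})

## ---------------------------------------------------------------------------
## TrainingSet
## ---------------------------------------------------------------------------

#' Feature/target pairs for one fragmentation method and precursor charge
#'
#' One row per cleavage site of every contributing PSM; the feature matrix
#' is shared across the four ion series, whose targets sit in the four
#' columns of `targets`.
#'
#' @slot features numeric matrix, one row per cleavage site.
#' @slot targets numeric matrix, same rows, columns `b`, `y`, `b2`, `y2`.
#' @slot method character(1), e.g. `"CID"` or `"HCD"`.
#' @slot precursorCharge integer(1).
#' @slot schemaVersion character(1), must match the encoder.
#' @slot psm integer vector mapping rows to input PSM indices.
#' @slot epsilons numeric vector, per-PSM annotation epsilon (one entry per
#'   contributing PSM, in input order).
#' @aliases TrainingSet
#' @exportClass TrainingSet
setClass("TrainingSet",
         representation(features = "matrix", targets = "matrix",
                        method = "character", precursorCharge = "integer",
                        schemaVersion = "character", psm = "integer",
                        epsilons = "numeric"))

setValidity("TrainingSet", function(object) {
  if (nrow(object@features) != nrow(object@targets))
    return("features and targets must have the same number of rows")
  if (!identical(colnames(object@targets), .ION_SERIES))
    return("target columns must be b, y, b2, y2")
  if (any(!is.finite(object@targets))) return("non-finite target")
  TRUE
})

## ---------------------------------------------------------------------------
## IntensityModel
## ---------------------------------------------------------------------------

#' A trained intensity prediction model
#'
#' Bundle of four random-forest regressors (one per ion series), fixed at
#' training time to one fragmentation method and one precursor charge, plus
#' the feature-schema version and the training configuration needed to
#' reproduce it.
#'
#' @slot method character(1).
#' @slot precursorCharge integer(1), 2 or 3.
#' @slot forests named list of four fitted ranger regressors (`b`, `y`,
#'   `b2`, `y2`).
#' @slot schemaVersion character(1).
#' @slot trainingConfig list (num.trees, seed, normalization id, n PSMs...).
#' @slot epsilonRef numeric(1): reference epsilon for the inverse transform.
#' @aliases IntensityModel
#' @exportClass IntensityModel
setClass("IntensityModel",
         representation(method = "character", precursorCharge = "integer",
                        forests = "list", schemaVersion = "character",
                        trainingConfig = "list", epsilonRef = "numeric"))

setValidity("IntensityModel", function(object) {
  if (!identical(sort(names(object@forests)), sort(.ION_SERIES)))
    return("model must hold exactly the four series forests b, y, b2, y2")
  if (!object@precursorCharge %in% c(2L, 3L))
    return("precursor charge must be 2 or 3")
  TRUE
})

## ---------------------------------------------------------------------------
## FragmentationParams
## ---------------------------------------------------------------------------

#' Parameters of the synthetic fragmentation rule
#'
#' Defines the deterministic ground-truth intensity rule of the simulator
#' plus its noise model. Two bundled presets (`"methodA"`, `"methodB"`)
#' parameterize two distinct fragmentation behaviours, emulating the
#' contrast between collision-induced and beam-type dissociation.
#'
#' @slot name character(1) preset label.
#' @slot basePeak named numeric(4): base level per series (b, y, b2, y2).
#' @slot posDecay,posCenter numeric(1): Gaussian positional profile
#'   `exp(-posDecay * (x - posCenter)^2)` over relative site position x.
#' @slot prolineY,prolineB numeric(1): multipliers when the residue C-terminal
#'   to the cleavage site is proline.
#' @slot glycineB numeric(1): b-ion multiplier when the site residue is glycine.
#' @slot basicSingle,basicDouble numeric(1): per basic residue (R/K/H) in the
#'   fragment, multiplier for singly / doubly charged ions.
#' @slot mobileFactor numeric(1): global damping when precursor protons do not
#'   outnumber basic residues (non-mobile regime).
#' @slot ptmDamping numeric(1): Da scale of intensity damping per unit of
#'   absolute PTM mass in the fragment.
#' @slot noiseSigma numeric(1): sd of multiplicative log-normal peak noise.
#' @slot dropout numeric(1): probability a true peak is missing.
#' @slot decoyRate numeric(1): expected decoy peaks per true ion.
#' @aliases FragmentationParams
#' @exportClass FragmentationParams
setClass("FragmentationParams",
         representation(name = "character", basePeak = "numeric",
                        posDecay = "numeric", posCenter = "numeric",
                        prolineY = "numeric", prolineB = "numeric",
                        glycineB = "numeric", basicSingle = "numeric",
                        basicDouble = "numeric", mobileFactor = "numeric",
                        ptmDamping = "numeric", noiseSigma = "numeric",
                        dropout = "numeric", decoyRate = "numeric"))

setValidity("FragmentationParams", function(object) {
  if (!identical(names(object@basePeak), .ION_SERIES))
    return("basePeak must be named b, y, b2, y2")
  if (any(object@basePeak <= 0)) return("base peak levels must be positive")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@dropout < 0 || object@dropout > 1)
    return("dropout must be in [0, 1]")
  if (object@decoyRate < 0) return("decoyRate must be >= 0")
  TRUE
})
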
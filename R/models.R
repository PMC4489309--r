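## Intensity models: one bundle of four random-forest regressors (b+, y+,
## b++, y++) per fragmentation method and precursor charge.

#' Optional PSM redundancy filter
#'
#' Keeps, for every (rendered peptide, precursor charge) pair, only the PSM
#' whose spectrum has the highest total ion current. This mirrors the usual
#' reduction of large redundant PSM corpora to one representative spectrum
#' per precursor before training.
#'
#' @param psms list of PSMs (lists with `peptide` and `spectrum`).
#' @return the filtered list.
#' @export
dedupePsms <- function(psms) {
  key <- vapply(psms, function(x)
    paste(renderPeptide(x$peptide), precursorCharge(x$spectrum), sep = "/"),
    character(1))
  tic <- vapply(psms, function(x) sum(peakMatrix(x$spectrum)[, 2]),
                numeric(1))
  keep <- unlist(lapply(split(seq_along(psms), key),
                        function(i) i[which.max(tic[i])]))
  psms[sort(keep)]
}

#' Build per-charge training sets from annotated PSMs
#'
#' For every PSM and every cleavage site this emits one feature row (shared
#' by the four ion series) and the four series targets from
#' [annotateSpectrum()]: site i pairs with ions b_i, b_i++, y_(L-i) and
#' y_(L-i)++. PSMs are partitioned by precursor charge, since models are
#' trained per charge.
#'
#' @param psms nonempty list of PSMs: lists with `peptide`
#'   (\linkS4class{Peptide}) and `spectrum` (\linkS4class{ObservedSpectrum}).
#' @param method fragmentation method label stored in the result (e.g.
#'   `"CID"`, `"HCD"`, or a simulator preset name).
#' @param registry a \linkS4class{PTMRegistry}.
#' @param tol match tolerance in Da for [annotateSpectrum()].
#' @return named list of \linkS4class{TrainingSet}, one per precursor charge
#'   present in `psms` (names `"2"`, `"3"`).
#' @export
buildTrainingSet <- function(psms, method, registry, tol = .DEFAULT_TOL) {
  if (!length(psms)) stop("empty PSM list")
  charges <- vapply(psms, function(x) precursorCharge(x$spectrum), integer(1))
  out <- list()
  for (z in sort(unique(charges))) {
    idx <- which(charges == z)
    feats <- vector("list", length(idx))
    targs <- vector("list", length(idx))
    psmIds <- vector("list", length(idx))
    epsv <- numeric(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      p <- psms[[i]]$peptide
      tv <- annotateSpectrum(p, psms[[i]]$spectrum, registry, tol = tol)
      t <- intensityTargets(tv)
      L1 <- nrow(t)
      feats[[k]] <- encodePeptide(p, registry, z)
      targs[[k]] <- cbind(b = t[, "b"], y = rev(t[, "y"]),
                          b2 = t[, "b2"], y2 = rev(t[, "y2"]))
      psmIds[[k]] <- rep(i, L1)
      epsv[k] <- tv@epsilon
    }
    out[[as.character(z)]] <-
      new("TrainingSet", features = do.call(rbind, feats),
          targets = do.call(rbind, targs), method = method,
          precursorCharge = as.integer(z),
          schemaVersion = .SCHEMA_VERSION,
          psm = unlist(psmIds), epsilons = epsv)
  }
  out
}

#' Permute the targets of a training set (label-permutation null)
#'
#' Shuffles the target values jointly across cleavage sites and ion series
#' while leaving the features untouched, destroying every feature-target
#' association (including per-series intensity levels). A model trained on
#' the permuted set is the negative control for learning: its held-out
#' correlations should scatter around zero.
#'
#' @param ts a \linkS4class{TrainingSet}
#' @param seed integer seed for the permutation.
#' @return a \linkS4class{TrainingSet} with permuted targets.
#' @export
permuteTargets <- function(ts, seed = 1L) {
  flat <- as.vector(ts@targets)
  perm <- withr::with_seed(seed, sample(flat))
  new("TrainingSet", features = ts@features,
      targets = matrix(perm, nrow(ts@targets), ncol(ts@targets),
                       dimnames = dimnames(ts@targets)),
      method = ts@method, precursorCharge = ts@precursorCharge,
      schemaVersion = ts@schemaVersion, psm = ts@psm,
      epsilons = ts@epsilons)
}

#' Train an intensity model
#'
#' Fits one random-forest regressor per ion series on a
#' \linkS4class{TrainingSet}. Training is reproducible: the same seed gives
#' bit-identical forests and hence bit-identical predictions.
#'
#' @param ts a \linkS4class{TrainingSet} (one method, one precursor charge).
#' @param numTrees trees per forest; the default 50 keeps ensemble variance
#'   negligible for median-correlation evaluation at desk scale.
#' @param seed integer seed for the forest construction.
#' @param mtry features tried per split; `NULL` = ranger's default.
#' @param numThreads threads used by ranger (1 by default).
#' @return an \linkS4class{IntensityModel}
#' @export
trainModel <- function(ts, numTrees = 50L, seed = 1L, mtry = NULL,
                       numThreads = 1L) {
  if (!nrow(ts@features)) stop("empty training set")
  if (!identical(ts@schemaVersion, .SCHEMA_VERSION))
    stop(sprintf("training set schema '%s' does not match encoder schema '%s'",
                 ts@schemaVersion, .SCHEMA_VERSION))
  forests <- lapply(.ION_SERIES, function(series) {
    ranger::ranger(x = ts@features, y = ts@targets[, series],
                   num.trees = numTrees, mtry = mtry, seed = seed,
                   num.threads = numThreads, verbose = FALSE)
  })
  names(forests) <- .ION_SERIES
  cfg <- list(num.trees = as.integer(numTrees), seed = as.integer(seed),
              mtry = mtry, normalization = .NORMALIZATION_ID,
              n_psms = length(unique(ts@psm)), n_sites = nrow(ts@features))
  new("IntensityModel", method = ts@method,
      precursorCharge = ts@precursorCharge, forests = forests,
      schemaVersion = ts@schemaVersion, trainingConfig = cfg,
      epsilonRef = stats::median(ts@epsilons))
}

## predicted log2 targets in site layout, (L-1) x 4
.predictTargets <- function(m, p, registry, precursorCharge) {
  X <- encodePeptide(p, registry, precursorCharge)
  pred <- vapply(.ION_SERIES, function(series)
    stats::predict(m@forests[[series]], data = X, num.threads = 1L,
                   verbose = FALSE)$predictions,
    numeric(nrow(X)))
  if (is.null(dim(pred))) pred <- matrix(pred, 1L, 4L)
  colnames(pred) <- .ION_SERIES
  pred
}

## site layout -> ion-index layout (reverse the y columns)
.siteToIonLayout <- function(mat) {
  cbind(b = mat[, "b"], y = rev(mat[, "y"]),
        b2 = mat[, "b2"], y2 = rev(mat[, "y2"]))
}

#' Predict the MS2 spectrum of a peptide
#'
#' Applies a trained model to one peptide, producing the full four-series
#' ion set with predicted intensities. Intensities are inverse-transformed
#' from the model's log2 scale (`2^pred - epsilonRef`) and floored at zero.
#' Any peptide length >= 2 is accepted.
#'
#' @param m an \linkS4class{IntensityModel}
#' @param p a \linkS4class{Peptide}
#' @param registry a \linkS4class{PTMRegistry}
#' @param precursorCharge must equal the model's charge.
#' @return data.frame with columns `series`, `ionCharge`, `index`, `mz`,
#'   `intensity` (sorted by m/z), 4 x (L-1) rows.
#' @export
predictSpectrum <- function(m, p, registry, precursorCharge) {
  if (as.integer(precursorCharge) != m@precursorCharge)
    stop(sprintf("model is for precursor charge %d+, got %d+",
                 m@precursorCharge, as.integer(precursorCharge)))
  if (!identical(m@schemaVersion, .SCHEMA_VERSION))
    stop(sprintf("model schema '%s' does not match encoder schema '%s'",
                 m@schemaVersion, .SCHEMA_VERSION))
  predIon <- .siteToIonLayout(.predictTargets(m, p, registry,
                                              precursorCharge))
  ions <- theoreticalSpectrum(p, registry)
  col <- ifelse(ions$ionCharge == 1L, ions$series, paste0(ions$series, "2"))
  ions$intensity <- pmax(2^predIon[cbind(ions$index,
                                         match(col, .ION_SERIES))] -
                           m@epsilonRef, 0)
  ions
}

#' Save a trained model bundle
#'
#' Writes a single-file archive holding the four serialized forests plus
#' metadata (method, charge, schema version, training configuration).
#'
#' @param m an \linkS4class{IntensityModel}
#' @param path output file path (conventionally `.rds`).
#' @return invisibly, `path`.
#' @export
saveModel <- function(m, path) {
  saveRDS(list(format = "ms2forest-model-1",
               method = m@method, precursor_charge = m@precursorCharge,
               schema_version = m@schemaVersion,
               training_config = m@trainingConfig,
               epsilon_ref = m@epsilonRef, forests = m@forests),
          path)
  invisible(path)
}

#' Load a trained model bundle
#'
#' Refuses to load a bundle whose feature-schema version does not match the
#' running encoder, so stale models cannot silently be applied to a changed
#' feature layout.
#'
#' @param path file written by [saveModel()].
#' @return an \linkS4class{IntensityModel}
#' @export
loadModel <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable model file: ", path))
  if (!is.list(x) || !identical(x$format, "ms2forest-model-1"))
    stop("corrupt model file: ", path)
  if (!identical(x$schema_version, .SCHEMA_VERSION))
    stop(sprintf(
      "model schema version '%s' does not match encoder schema '%s'; refusing to load",
      x$schema_version, .SCHEMA_VERSION))
  new("IntensityModel", method = x$method,
      precursorCharge = as.integer(x$precursor_charge), forests = x$forests,
      schemaVersion = x$schema_version, trainingConfig = x$training_config,
      epsilonRef = x$epsilon_ref)
}
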
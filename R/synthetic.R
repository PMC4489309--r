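## Synthetic data: peptides, ground-truth fragment intensities and noisy
## observed spectra with known structure.
##
## The ground-truth rule is a deliberately simple caricature of peptide
## fragmentation chemistry: a per-series base level, a Gaussian positional
## profile along the backbone, enhanced y / suppressed b cleavage N-terminal
## to proline, weakened b cleavage at glycine, charge-dependent effects of
## basic residues (R/K/H), a mobile-proton damping term, and damping by PTM
## mass in the fragment. Every term is a function of information visible to
## the schema v1 features, so a correctly wired learner can recover the rule
## almost perfectly; the two presets differ enough in their parameters to
## emulate the contrast between two fragmentation methods.

#' Fragmentation parameter presets for the simulator
#'
#' @param name `"methodA"` or `"methodB"`, or any label when all parameters
#'   are supplied explicitly via `...`.
#' @param ... named overrides for any \linkS4class{FragmentationParams} slot
#'   (e.g. `noiseSigma = 0`, `dropout = 0`, `decoyRate = 0`).
#' @return a \linkS4class{FragmentationParams}
#' @examples
#' fragmentationParams("methodA", noiseSigma = 0, dropout = 0, decoyRate = 0)
#' @export
fragmentationParams <- function(name = c("methodA", "methodB"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    methodA = list(
      basePeak = c(b = 1.0, y = 1.2, b2 = 0.25, y2 = 0.3),
      posDecay = 3, posCenter = 0.45, prolineY = 4, prolineB = 0.3,
      glycineB = 0.6, basicSingle = 0.75, basicDouble = 1.6,
      mobileFactor = 0.5, ptmDamping = 300),
    methodB = list(
      basePeak = c(b = 0.35, y = 1.6, b2 = 0.15, y2 = 0.7),
      posDecay = 1.5, posCenter = 0.8, prolineY = 1.3, prolineB = 0.8,
      glycineB = 0.95, basicSingle = 0.9, basicDouble = 1.25,
      mobileFactor = 0.75, ptmDamping = 300))
  preset <- c(preset,
              list(noiseSigma = 0.2, dropout = 0.05, decoyRate = 0.1))
  dots <- list(...)
  for (nm in names(dots)) preset[[nm]] <- dots[[nm]]
  do.call(new, c(list("FragmentationParams", name = name), preset))
}

#' Generate random peptides
#'
#' Residues are drawn uniformly from the 20 standard amino acids; lengths
#' uniformly from `lengthRange`. Each residue independently receives a PTM
#' with probability `ptmRate`, drawn uniformly among the registry's internal
#' symbols whose scope allows that residue (residues with no applicable
#' symbol stay unmodified).
#'
#' @param n number of peptides (> 0).
#' @param registry a \linkS4class{PTMRegistry}.
#' @param lengthRange integer(2) inclusive length range; the default 15-16
#'   mirrors a typical synthesized proteotypic-peptide evaluation pool.
#' @param ptmRate per-residue modification probability.
#' @param seed integer seed; same seed, same list.
#' @return list of \linkS4class{Peptide}
#' @export
genPeptides <- function(n, registry, lengthRange = c(15L, 16L),
                        ptmRate = 0.05, seed = 1L) {
  stopifnot(n > 0, length(lengthRange) == 2L,
            lengthRange[1] >= 2L, lengthRange[1] <= lengthRange[2])
  tab <- registry@table
  internal <- if (nrow(tab))
    tab$symbol[!grepl("^-|-$", tab$symbol)] else character(0)
  scopeOf <- lapply(internal, function(s) .ptmScope(registry, s))
  lens <- seq(lengthRange[1], lengthRange[2])
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      L <- lens[sample.int(length(lens), 1L)]
      seqv <- sample(.AA, L, replace = TRUE)
      mods <- character(0)
      if (ptmRate > 0 && length(internal)) {
        hit <- stats::runif(L) < ptmRate
        for (j in which(hit)) {
          ok <- internal[vapply(scopeOf, function(sc) seqv[j] %in% sc,
                                logical(1))]
          if (length(ok)) mods[as.character(j)] <- sample(ok, 1L)
        }
      }
      Peptide(paste(seqv, collapse = ""), mods, registry = registry)
    })
  })
}

## ground-truth raw intensities, (L-1) x 4 in ion-index layout
## (row i = b_i, y_i, b_i++, y_i++)
.groundTruthRaw <- function(p, charge, params, registry) {
  seqv <- strsplit(p@sequence, "")[[1]]
  L <- length(seqv)
  sites <- seq_len(L - 1L)
  x <- sites / (L - 1L)
  pos <- exp(-params@posDecay * (x - params@posCenter)^2)
  pro <- seqv[sites + 1L] == "P"
  gly <- seqv[sites] == "G"
  basic <- as.numeric(seqv %in% c("R", "K", "H"))
  nBasPre <- cumsum(basic)[sites]
  nBasTot <- sum(basic)
  nBasSuf <- nBasTot - nBasPre

  sh <- numeric(L)
  if (length(p@residueMods)) {
    posm <- as.integer(names(p@residueMods))
    sh[posm] <- abs(vapply(p@residueMods,
                           function(s) ptmShift(registry, s), numeric(1)))
  }
  ntermShift <- if (p@nTerm != "H-") abs(ptmShift(registry, p@nTerm)) else 0
  ctermShift <- if (p@cTerm != "-OH") abs(ptmShift(registry, p@cTerm)) else 0
  ptmPre <- cumsum(sh)[sites] + ntermShift
  ptmSuf <- (sum(sh) - cumsum(sh)[sites]) + ctermShift

  mobile <- if (charge - nBasTot >= 1) 1 else params@mobileFactor
  proB <- ifelse(pro, params@prolineB, 1)
  proY <- ifelse(pro, params@prolineY, 1)
  glyB <- ifelse(gly, params@glycineB, 1)
  dampPre <- exp(-ptmPre / params@ptmDamping)
  dampSuf <- exp(-ptmSuf / params@ptmDamping)

  bSite <- params@basePeak[["b"]] * pos * proB * glyB *
    params@basicSingle^nBasPre * dampPre
  ySite <- params@basePeak[["y"]] * pos * proY *
    params@basicSingle^nBasSuf * dampSuf
  b2Site <- params@basePeak[["b2"]] * pos * proB * glyB *
    params@basicDouble^nBasPre * dampPre
  y2Site <- params@basePeak[["y2"]] * pos * proY *
    params@basicDouble^nBasSuf * dampSuf

  ## site i produces b_i and y_(L-i): re-index y columns by ion index
  cbind(b = bSite * mobile, y = rev(ySite) * mobile,
        b2 = b2Site * mobile, y2 = rev(y2Site) * mobile)
}

.SIM_SCALE <- 1e4  # arbitrary counts scale for simulated raw intensities

#' Simulate one peptide-spectrum match
#'
#' The ground-truth intensity of every theoretical ion is a deterministic
#' function of the peptide, the precursor charge and `params`. The observed
#' spectrum multiplies each true peak by log-normal noise
#' (`exp(N(0, noiseSigma^2))`), drops peaks with probability `dropout`, and
#' adds decoy peaks at uniform random m/z. The returned ground truth is the
#' \linkS4class{TargetVector} obtained by annotating the noiseless spectrum,
#' i.e. exactly what a perfect observation would yield.
#'
#' @param p a \linkS4class{Peptide}
#' @param charge precursor charge, 2 or 3.
#' @param params a \linkS4class{FragmentationParams}
#' @param registry a \linkS4class{PTMRegistry}
#' @param seed integer seed; same seed, same spectrum.
#' @param tol match tolerance passed to [annotateSpectrum()] for the
#'   ground-truth annotation.
#' @return list with elements `peptide`, `spectrum`
#'   (\linkS4class{ObservedSpectrum}), `truth` (\linkS4class{TargetVector}),
#'   `method` (the preset name) and `charge`.
#' @export
simulatePsm <- function(p, charge, params, registry, seed = 1L,
                        tol = .DEFAULT_TOL) {
  stopifnot(charge %in% c(2L, 3L))
  raw <- .groundTruthRaw(p, charge, params, registry) * .SIM_SCALE
  theo <- .theoreticalMzMatrix(p, registry)
  mz <- as.vector(theo)
  int <- as.vector(raw)
  pepmz <- (peptideMass(p, registry) + charge * .PROTON_MASS) / charge
  title <- renderPeptide(p)

  truthSpec <- ObservedSpectrum(title, charge, pepmz, cbind(mz, int))
  truth <- annotateSpectrum(p, truthSpec, registry, tol = tol)

  obs <- withr::with_seed(seed, {
    noisy <- int * exp(stats::rnorm(length(int), 0, params@noiseSigma))
    keep <- stats::runif(length(int)) >= params@dropout
    omz <- mz[keep]; oint <- noisy[keep]
    nDecoy <- stats::rpois(1L, params@decoyRate * length(int))
    if (nDecoy > 0L && length(oint)) {
      dmz <- stats::runif(nDecoy, 0.9 * min(mz), 1.1 * max(mz))
      dint <- sample(oint, nDecoy, replace = TRUE) *
        exp(stats::rnorm(nDecoy, 0, params@noiseSigma + 0.5))
      omz <- c(omz, dmz); oint <- c(oint, dint)
    }
    ObservedSpectrum(title, charge, pepmz, cbind(omz, oint))
  })
  list(peptide = p, spectrum = obs, truth = truth,
       method = params@name, charge = as.integer(charge))
}

#' Simulate a dataset of peptide-spectrum matches
#'
#' @param n number of PSMs.
#' @inheritParams simulatePsm
#' @inheritParams genPeptides
#' @return list of PSMs as returned by [simulatePsm()]
#' @export
simulateDataset <- function(n, charge, params, registry, seed = 1L,
                            lengthRange = c(15L, 16L), ptmRate = 0.05,
                            tol = .DEFAULT_TOL) {
  peps <- genPeptides(n, registry, lengthRange = lengthRange,
                      ptmRate = ptmRate, seed = seed)
  lapply(seq_len(n), function(i)
    simulatePsm(peps[[i]], charge, params, registry,
                seed = (seed + 7919L * i) %% .Machine$integer.max,
                tol = tol))
}

#' Write a simulated dataset to MGF plus a ground-truth CSV
#'
#' The MGF carries the observed (noisy) spectra with the rendered peptide
#' string as `TITLE`; the side CSV holds the ground-truth normalized
#' log2 targets, one row per (PSM, ion index) with four series columns.
#'
#' @param psms list from [simulateDataset()]
#' @param mgfPath output MGF path.
#' @param truthPath optional output CSV path for the ground truth.
#' @return invisibly, `mgfPath`.
#' @export
writeSimulatedDataset <- function(psms, mgfPath, truthPath = NULL) {
  con <- file(mgfPath, open = "wt", encoding = "UTF-8")
  for (psm in psms) {
    s <- psm$spectrum
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s@title),
                 sprintf("PEPMASS=%.6f", s@pepmass),
                 sprintf("CHARGE=%d+", s@precursorCharge),
                 sprintf("%.6f %.8g", s@peaks[, 1], s@peaks[, 2]),
                 "END IONS", ""), con)
  }
  close(con)
  if (!is.null(truthPath)) {
    rows <- lapply(seq_along(psms), function(i) {
      t <- psms[[i]]$truth@targets
      data.frame(psm = i, peptide = psms[[i]]$spectrum@title,
                 precursor_charge = psms[[i]]$charge,
                 index = seq_len(nrow(t)), b = t[, "b"], y = t[, "y"],
                 b2 = t[, "b2"], y2 = t[, "y2"])
    })
    write.csv(do.call(rbind, rows), truthPath, row.names = FALSE)
  }
  invisible(mgfPath)
}
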
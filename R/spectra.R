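## MGF and CSV I/O, and conversion of an observed spectrum into normalized
## regression targets.
##
## MGF dialect: BEGIN IONS / TITLE= / PEPMASS= / CHARGE=<n>+ /
## "mz intensity" peak lines / END IONS, UTF-8. Only precursor charges 2+
## and 3+ are modelled; blocks with other charges are skipped with a
## warning that reports the count.

.NORMALIZATION_ID <- "tic-log2-v1"
.DEFAULT_TOL <- 0.02        # Da, absolute; de-isotoped high-resolution data
.EPSILON_FRACTION <- 0.001  # epsilon = this fraction of the median nonzero
                            # TIC-normalized peak intensity

#' Construct an observed spectrum
#'
#' @param title spectrum title string.
#' @param precursorCharge 2 or 3.
#' @param pepmass precursor m/z (Th).
#' @param peaks two-column matrix or data.frame of (mz, intensity); rows are
#'   re-sorted by ascending mz.
#' @return an \linkS4class{ObservedSpectrum}
#' @export
ObservedSpectrum <- function(title, precursorCharge, pepmass, peaks) {
  pk <- as.matrix(peaks)
  if (length(pk) == 0) pk <- matrix(numeric(0), 0, 2)
  colnames(pk) <- c("mz", "intensity")
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  new("ObservedSpectrum", title = as.character(title),
      precursorCharge = as.integer(precursorCharge),
      pepmass = as.numeric(pepmass), peaks = pk)
}

#' Read a Mascot Generic Format file
#'
#' Parses every `BEGIN IONS`/`END IONS` block into an
#' \linkS4class{ObservedSpectrum}. Blocks whose `CHARGE` is not `2+` or
#' `3+` are skipped; a single warning reports how many were dropped.
#' Malformed blocks raise an error naming the offending line number.
#'
#' @param path path to an MGF file.
#' @return list of \linkS4class{ObservedSpectrum}
#' @export
readMGF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  skipped <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    if (line != "BEGIN IONS")
      stop(sprintf("malformed MGF at line %d: expected BEGIN IONS, got '%s'",
                   i, line))
    start <- i
    i <- i + 1L
    title <- ""; charge <- NA_integer_; pepmass <- NA_real_
    mzs <- numeric(0); ints <- numeric(0)
    ended <- FALSE
    while (i <= n) {
      line <- trimws(lines[i])
      if (line == "END IONS") { ended <- TRUE; i <- i + 1L; break }
      if (line == "") { i <- i + 1L; next }
      if (grepl("^TITLE=", line)) {
        title <- sub("^TITLE=", "", line)
      } else if (grepl("^PEPMASS=", line)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line),
                                       "[ \t]+")[[1]][1])
        if (is.na(pepmass))
          stop(sprintf("malformed MGF at line %d: bad PEPMASS", i))
      } else if (grepl("^CHARGE=", line)) {
        chtxt <- sub("^CHARGE=", "", line)
        if (!grepl("^[0-9]+\\+$", chtxt))
          stop(sprintf("malformed MGF at line %d: bad CHARGE '%s'", i, chtxt))
        charge <- as.integer(sub("\\+$", "", chtxt))
      } else if (grepl("^[A-Z]+=", line)) {
        ## unknown header key: tolerated
      } else {
        vals <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
        if (length(vals) < 2L || any(is.na(vals[1:2])))
          stop(sprintf("malformed MGF at line %d: bad peak line '%s'",
                       i, line))
        mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
      }
      i <- i + 1L
    }
    if (!ended)
      stop(sprintf("malformed MGF: block at line %d has no END IONS", start))
    if (is.na(charge) || !charge %in% c(2L, 3L)) {
      skipped <- skipped + 1L
    } else {
      spectra[[length(spectra) + 1L]] <-
        ObservedSpectrum(title, charge,
                         if (is.na(pepmass)) 0 else pepmass,
                         cbind(mzs, ints))
    }
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d spectra with unsupported precursor charge",
                    skipped))
  spectra
}

#' Write predicted spectra to Mascot Generic Format
#'
#' Each prediction becomes one MGF block whose `TITLE` is the rendered
#' `H-P-OH` peptide string and whose `CHARGE` is the precursor charge as
#' `<n>+`. Peaks are written sorted by ascending m/z.
#'
#' @param predictions list of predictions; each element is a list with
#'   `peptide` (\linkS4class{Peptide}), `charge` (2 or 3), and `ions`
#'   (data.frame from [predictSpectrum()], with an `intensity` column).
#' @param path output file.
#' @param registry \linkS4class{PTMRegistry}, used for the PEPMASS line.
#' @param keepZeros if `FALSE`, ions with zero predicted intensity are
#'   pruned from the peak list.
#' @return invisibly, the path.
#' @export
writeMGF <- function(predictions, path, registry, keepZeros = TRUE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (pr in predictions) {
    ions <- pr$ions
    if (is.null(ions$intensity) || any(is.na(ions$intensity)))
      stop("all ions must carry an intensity before MGF export")
    if (!keepZeros) ions <- ions[ions$intensity > 0, , drop = FALSE]
    ions <- ions[order(ions$mz), , drop = FALSE]
    z <- as.integer(pr$charge)
    pepmz <- (peptideMass(pr$peptide, registry) + z * .PROTON_MASS) / z
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", renderPeptide(pr$peptide)),
                 sprintf("PEPMASS=%.6f", pepmz),
                 sprintf("CHARGE=%d+", z),
                 sprintf("%.6f %.8g", ions$mz, ions$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Write predictions to CSV
#'
#' One row per predicted ion: peptide string (identical to the MGF
#' `TITLE`), precursor charge, series, ion charge, ion index, m/z and
#' predicted intensity, at full float precision.
#'
#' @inheritParams writeMGF
#' @return invisibly, the path.
#' @export
writePredictionsCSV <- function(predictions, path) {
  rows <- lapply(predictions, function(pr) {
    ions <- pr$ions
    if (is.null(ions$intensity)) stop("predictions must carry intensities")
    data.frame(peptide = renderPeptide(pr$peptide),
               precursor_charge = as.integer(pr$charge),
               series = ions$series, ion_charge = ions$ionCharge,
               index = ions$index, mz = ions$mz,
               intensity = ions$intensity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Convert an observed spectrum into normalized regression targets
#'
#' Every theoretical ion of the peptide (b+, y+, b++, y++ at indices
#' 1..L-1) takes the intensity of the most intense observed peak within
#' `tol` Da of its m/z. Matched raw intensities are divided by the total
#' ion current of the whole spectrum and transformed `x -> log2(x + eps)`,
#' with `eps` = 0.001 of the median nonzero TIC-normalized peak intensity;
#' unmatched ions hold the baseline `log2(eps)`. An observed peak may serve
#' several theoretical ions.
#'
#' @param p a \linkS4class{Peptide}
#' @param s an \linkS4class{ObservedSpectrum}
#' @param registry a \linkS4class{PTMRegistry}
#' @param tol absolute match tolerance in Da (> 0); default 0.02.
#' @return a \linkS4class{TargetVector}
#' @export
annotateSpectrum <- function(p, s, registry, tol = .DEFAULT_TOL) {
  if (tol <= 0) stop("tol must be > 0")
  theo <- .theoreticalMzMatrix(p, registry)
  pk <- s@peaks
  raw <- matrix(0, nrow(theo), 4L, dimnames = list(NULL, .ION_SERIES))
  matched <- matrix(FALSE, nrow(theo), 4L, dimnames = list(NULL, .ION_SERIES))
  if (nrow(pk)) {
    mz <- pk[, 1]; int <- pk[, 2]
    for (j in seq_len(4L)) {
      lo <- findInterval(theo[, j] - tol, mz) + 1L
      hi <- findInterval(theo[, j] + tol, mz)
      for (i in seq_len(nrow(theo))) {
        if (lo[i] <= hi[i]) {
          win <- lo[i]:hi[i]
          raw[i, j] <- max(int[win])
          matched[i, j] <- TRUE
        }
      }
    }
  }
  tic <- sum(pk[, 2])
  if (tic > 0) {
    norm <- raw / tic
    normPeaks <- pk[, 2] / tic
    nz <- normPeaks[normPeaks > 0]
    eps <- if (length(nz)) .EPSILON_FRACTION * stats::median(nz) else 1e-7
  } else {
    norm <- raw
    eps <- 1e-7
  }
  targets <- log2(norm + eps)
  targets[!matched] <- log2(eps)
  new("TargetVector", targets = targets, matched = matched, epsilon = eps,
      normalization = .NORMALIZATION_ID)
}
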
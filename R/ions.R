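## Theoretical fragment ions: the four predicted series b+, y+, b++, y++.
##
## b_i is the N-terminal fragment holding residues 1..i (neutral mass =
## residue sum + N-terminal and in-range PTM shifts); y_i is the C-terminal
## fragment holding the last i residues plus water (+ C-terminal and
## in-range PTM shifts). m/z = (neutral + z * proton) / z with the proton
## mass, monoisotopic throughout.

## per-residue mass vector including residue PTM shifts; attr gives termini
.residueMassVector <- function(p, registry) {
  seqv <- strsplit(p@sequence, "")[[1]]
  m <- unname(.RESIDUE_MASS[seqv])
  if (length(p@residueMods)) {
    pos <- as.integer(names(p@residueMods))
    shifts <- vapply(p@residueMods, function(s) ptmShift(registry, s),
                     numeric(1))
    m[pos] <- m[pos] + shifts
  }
  ntermShift <- if (p@nTerm != "H-") ptmShift(registry, p@nTerm) else 0
  ctermShift <- if (p@cTerm != "-OH") ptmShift(registry, p@cTerm) else 0
  list(residues = m, nterm = ntermShift, cterm = ctermShift)
}

## neutral masses of all b_i and y_i, i = 1..L-1
.fragmentNeutralMasses <- function(p, registry) {
  mv <- .residueMassVector(p, registry)
  L <- length(mv$residues)
  b <- cumsum(mv$residues)[-L] + mv$nterm
  ## y_i = sum of the last i residues + water (+ C-terminal shift)
  y <- cumsum(rev(mv$residues))[-L] + .WATER_MASS + mv$cterm
  list(b = unname(b), y = unname(y))
}

#' Theoretical m/z of one fragment ion
#'
#' @param p a \linkS4class{Peptide}
#' @param registry a \linkS4class{PTMRegistry}
#' @param series `"b"` or `"y"`
#' @param index ion index, 1..L-1
#' @param ionCharge 1 or 2
#' @return m/z in Th
#' @examples
#' reg <- readPTMTable()
#' gg <- parsePeptide("H-GG-OH", reg)
#' fragmentMz(gg, reg, "b", 1, 1)  # 58.02874
#' @export
fragmentMz <- function(p, registry, series = c("b", "y"), index,
                       ionCharge = 1L) {
  series <- match.arg(series)
  L <- peptideLength(p)
  if (any(index < 1L) || any(index > L - 1L))
    stop(sprintf("ion index out of range [1, %d]", L - 1L))
  if (!all(ionCharge %in% c(1L, 2L))) stop("ion charge must be 1 or 2")
  neutral <- .fragmentNeutralMasses(p, registry)[[series]][index]
  (neutral + ionCharge * .PROTON_MASS) / ionCharge
}

#' All theoretical fragment ions of a peptide
#'
#' Generates the complete four-series ion set (b+, y+, b++, y++ at every
#' index 1..L-1), 4 x (L-1) ions in total, sorted by ascending m/z.
#'
#' @inheritParams fragmentMz
#' @return data.frame with columns `series` ("b"/"y"), `ionCharge` (1/2),
#'   `index`, `mz`, sorted by `mz`
#' @export
theoreticalSpectrum <- function(p, registry) {
  L <- peptideLength(p)
  neutral <- .fragmentNeutralMasses(p, registry)
  idx <- seq_len(L - 1L)
  ions <- data.frame(
    series = rep(c("b", "y", "b", "y"), each = L - 1L),
    ionCharge = rep(c(1L, 1L, 2L, 2L), each = L - 1L),
    index = rep(idx, 4L),
    mz = c((neutral$b + .PROTON_MASS),
           (neutral$y + .PROTON_MASS),
           (neutral$b + 2 * .PROTON_MASS) / 2,
           (neutral$y + 2 * .PROTON_MASS) / 2),
    stringsAsFactors = FALSE)
  ions[order(ions$mz), , drop = FALSE]
}

## theoretical mz in TargetVector layout: (L-1) x 4 matrix, row i = ion
## index i, columns b, y, b2, y2
.theoreticalMzMatrix <- function(p, registry) {
  neutral <- .fragmentNeutralMasses(p, registry)
  cbind(b = neutral$b + .PROTON_MASS,
        y = neutral$y + .PROTON_MASS,
        b2 = (neutral$b + 2 * .PROTON_MASS) / 2,
        y2 = (neutral$y + 2 * .PROTON_MASS) / 2)
}
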
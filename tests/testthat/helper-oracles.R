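## Independent oracles: straightforward loop-based summations and a naive
## feature-schema re-implementation, kept deliberately separate from the
## package's vectorized code paths.

ORACLE_RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
ORACLE_PROTON <- 1.007276
ORACLE_WATER <- 18.010565

## per-residue shifts (numeric vector length L) + terminal shifts for a
## Peptide against a registry, computed by plain lookup
oracleShifts <- function(p, reg) {
  tab <- reg@table
  L <- peptideLength(p)
  sh <- numeric(L)
  mods <- residueMods(p)
  for (k in seq_along(mods)) {
    pos <- as.integer(names(mods)[k])
    sh[pos] <- tab$mass_shift[tab$symbol == mods[[k]]]
  }
  nt <- if (nTerm(p) == "H-") 0 else tab$mass_shift[tab$symbol == nTerm(p)]
  ct <- if (cTerm(p) == "-OH") 0 else tab$mass_shift[tab$symbol == cTerm(p)]
  list(res = sh, nterm = nt, cterm = ct)
}

oraclePeptideMass <- function(p, reg) {
  seqv <- strsplit(peptideSequence(p), "")[[1]]
  sh <- oracleShifts(p, reg)
  total <- ORACLE_WATER + sh$nterm + sh$cterm
  for (i in seq_along(seqv))
    total <- total + ORACLE_RESIDUE_MASS[[seqv[i]]] + sh$res[i]
  total
}

oracleFragmentMz <- function(p, reg, series, index, ionCharge) {
  seqv <- strsplit(peptideSequence(p), "")[[1]]
  L <- length(seqv)
  sh <- oracleShifts(p, reg)
  if (series == "b") {
    neutral <- sh$nterm
    for (i in seq_len(index))
      neutral <- neutral + ORACLE_RESIDUE_MASS[[seqv[i]]] + sh$res[i]
  } else {
    neutral <- ORACLE_WATER + sh$cterm
    for (i in seq(L - index + 1L, L))
      neutral <- neutral + ORACLE_RESIDUE_MASS[[seqv[i]]] + sh$res[i]
  }
  (neutral + ionCharge * ORACLE_PROTON) / ionCharge
}

## naive, loop-based re-computation of the schema v1 feature vector
naiveEncodeSite <- function(p, reg, charge, site,
                            props = readPropertyTable()) {
  seqv <- strsplit(peptideSequence(p), "")[[1]]
  L <- length(seqv)
  aa <- names(ORACLE_RESIDUE_MASS)
  pre <- seqv[1:site]
  suf <- seqv[(site + 1):L]
  scales <- c("basicity", "hydrophobicity", "helicity", "pI")
  propBlock <- numeric(0)
  for (sc in scales) {
    v <- props[seqv, sc]
    propBlock <- c(propBlock, mean(v), mean(props[pre, sc]),
                   mean(props[suf, sc]))
  }
  oneHot <- numeric(0)
  for (off in c(-1L, 0L, 1L, 2L)) {
    j <- site + off
    vec <- numeric(21)
    if (j >= 1L && j <= L) vec[match(seqv[j], aa)] <- 1 else vec[21] <- 1
    oneHot <- c(oneHot, vec)
  }
  cnt <- c(vapply(aa, function(a) sum(pre == a), numeric(1)),
           vapply(aa, function(a) sum(suf == a), numeric(1)))
  sh <- oracleShifts(p, reg)
  modFlag <- as.numeric(sh$res != 0)
  out <- c(L, site / (L - 1), charge, propBlock, oneHot, cnt,
           sum(sh$res[1:site]) + sh$nterm,
           sum(sh$res[(site + 1):L]) + sh$cterm,
           sum(modFlag[1:site]), sum(modFlag[(site + 1):L]),
           modFlag[site], modFlag[site + 1])
  names(out) <- featureNames()
  out
}

## Pearson by the textbook formula, independent of stats::cor
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
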
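## Peptide grammar: parse, render, mass.
##
## Peptides are written 'H-P-OH': 'H-' is the (default, unmodified) amino
## terminus, '-OH' the carboxyl terminus, and P the residue sequence in
## capital one-letter codes. A run of lowercase letters immediately before a
## capital marks a PTM on that residue ('H-SAoxMPLE-OH' carries 'ox' on the
## M at position 3). Terminal PTMs replace 'H-'/'-OH' and keep their dash:
## 'ace-SAMPLE-OH'.

.DEFAULT_MAX_PTMS <- 8L

#' Build a PTM registry from definitions
#'
#' @param table data.frame with columns `symbol`, `name`, `mass_shift`,
#'   `residues` (comma-separated residue scope, or `n-term` / `c-term` for
#'   terminal symbols).
#' @param maxEntries cap on the number of distinct symbols per run.
#' @param allowExtra if `TRUE`, more than `maxEntries` symbols are accepted.
#' @return a \linkS4class{PTMRegistry}
#' @examples
#' reg <- PTMRegistry(data.frame(symbol = "ox", name = "Oxidation",
#'                               mass_shift = 15.994915, residues = "M"))
#' @export
PTMRegistry <- function(table = data.frame(symbol = character(0),
                                           name = character(0),
                                           mass_shift = numeric(0),
                                           residues = character(0)),
                        maxEntries = .DEFAULT_MAX_PTMS, allowExtra = FALSE) {
  if (!allowExtra && nrow(table) > maxEntries)
    stop(sprintf("PTM table has %d symbols but at most %d are supported %s",
                 nrow(table), maxEntries,
                 "(use allowExtra = TRUE to override)"))
  new("PTMRegistry", table = as.data.frame(table),
      maxEntries = as.integer(maxEntries))
}

#' Read a PTM definition table from CSV
#'
#' One record per symbol: `symbol`, `name`, `mass_shift` (monoisotopic Da),
#' `residues` (comma-separated scope). The default table bundles common
#' modifications (oxidation, carbamidomethylation, N-terminal acetylation,
#' phosphorylation, ...). At most eight symbols are accepted per run unless
#' `allowExtra = TRUE`.
#'
#' @param path CSV path; defaults to the bundled table.
#' @inheritParams PTMRegistry
#' @return a \linkS4class{PTMRegistry}
#' @export
readPTMTable <- function(path = system.file("extdata", "ptm_table.csv",
                                            package = "ms2forest"),
                         maxEntries = .DEFAULT_MAX_PTMS, allowExtra = FALSE) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("symbol", "name", "mass_shift", "residues")
  if (!all(need %in% names(tab)))
    stop("PTM table must have columns: ", paste(need, collapse = ", "))
  PTMRegistry(tab[, need], maxEntries = maxEntries, allowExtra = allowExtra)
}

#' Number of symbols in a registry
#' @param registry a \linkS4class{PTMRegistry}
#' @return integer(1)
#' @export
ptmCount <- function(registry) nrow(registry@table)

## internal lookups -----------------------------------------------------------

.ptmRow <- function(registry, symbol) {
  i <- match(symbol, registry@table$symbol)
  if (is.na(i)) stop(sprintf("unregistered symbol '%s'", symbol))
  registry@table[i, ]
}

#' Mass shift of a registered PTM symbol
#' @param registry a \linkS4class{PTMRegistry}
#' @param symbol the lowercase symbol, with its dash for terminal PTMs
#' @return monoisotopic mass shift in Da
#' @export
ptmShift <- function(registry, symbol) .ptmRow(registry, symbol)$mass_shift

.ptmScope <- function(registry, symbol)
  strsplit(.ptmRow(registry, symbol)$residues, ",[ ]*")[[1]]

## ---------------------------------------------------------------------------
## Peptide construction and parsing
## ---------------------------------------------------------------------------

#' Construct a peptide programmatically
#'
#' @param sequence residue string in capital one-letter codes (length >= 2).
#' @param residueMods named character vector of PTM symbols, names are the
#'   1-based residue positions (e.g. `c("3" = "ox")`).
#' @param nTerm N-terminal symbol; `"H-"` means unmodified.
#' @param cTerm C-terminal symbol; `"-OH"` means unmodified.
#' @param registry optional \linkS4class{PTMRegistry}; when given, every
#'   non-default symbol is checked for existence and residue scope.
#' @return a \linkS4class{Peptide}
#' @examples
#' reg <- readPTMTable()
#' Peptide("SAMPLE", c("3" = "ox"), registry = reg)
#' @export
Peptide <- function(sequence, residueMods = character(0), nTerm = "H-",
                    cTerm = "-OH", registry = NULL) {
  if (length(residueMods) && is.null(names(residueMods)))
    stop("residueMods must be named by 1-based position")
  mods <- as.character(residueMods)
  names(mods) <- names(residueMods)
  p <- new("Peptide", sequence = as.character(sequence), residueMods = mods,
           nTerm = nTerm, cTerm = cTerm)
  if (!is.null(registry)) .checkPeptideMods(p, registry)
  p
}

.checkPeptideMods <- function(p, registry) {
  seqv <- strsplit(p@sequence, "")[[1]]
  for (i in seq_along(p@residueMods)) {
    pos <- as.integer(names(p@residueMods)[i])
    sym <- p@residueMods[[i]]
    scope <- .ptmScope(registry, sym)
    if (!seqv[pos] %in% scope)
      stop(sprintf("PTM '%s' is not allowed on residue %s (position %d)",
                   sym, seqv[pos], pos))
  }
  if (p@nTerm != "H-") {
    if (!identical(.ptmScope(registry, p@nTerm), "n-term"))
      stop(sprintf("'%s' is not an N-terminal symbol", p@nTerm))
  }
  if (p@cTerm != "-OH") {
    if (!identical(.ptmScope(registry, p@cTerm), "c-term"))
      stop(sprintf("'%s' is not a C-terminal symbol", p@cTerm))
  }
  invisible(TRUE)
}

#' Parse an 'H-P-OH' peptide string
#'
#' Splits the string into N-terminal symbol, residue body and C-terminal
#' symbol, then walks the body attaching each lowercase run to the capital
#' letter that follows it. Unknown symbols, stray characters, lowercase runs
#' with no following residue and PTMs outside their residue scope are
#' rejected with specific errors. No upper peptide-length limit is enforced.
#'
#' @param text the peptide string, e.g. `"H-SAoxMPLE-OH"`.
#' @param registry a \linkS4class{PTMRegistry} resolving the symbols.
#' @return a \linkS4class{Peptide}
#' @examples
#' reg <- readPTMTable()
#' parsePeptide("H-SAoxMPLE-OH", reg)
#' parsePeptide("ace-SAMPLE-OH", reg)
#' @export
parsePeptide <- function(text, registry) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("peptide text must be a nonempty string")
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L || any(!nzchar(parts)))
    stop(sprintf("grammar error in '%s': expected '<nterm>-<peptide>-<cterm>'",
                 text))
  ntermTok <- parts[1]; body <- parts[2]; ctermTok <- parts[3]

  nterm <- if (ntermTok == "H") "H-" else paste0(ntermTok, "-")
  if (nterm != "H-") {
    if (grepl("[^a-z]", ntermTok))
      stop(sprintf("grammar error: invalid N-terminal token '%s'", ntermTok))
    .ptmRow(registry, nterm)  # errors if unregistered
  }
  cterm <- if (ctermTok == "OH") "-OH" else paste0("-", ctermTok)
  if (cterm != "-OH") {
    if (grepl("[^a-z]", ctermTok))
      stop(sprintf("grammar error: invalid C-terminal token '%s'", ctermTok))
    .ptmRow(registry, cterm)
  }

  if (grepl("[^A-Za-z]", body))
    stop(sprintf("grammar error: invalid character in peptide body '%s'", body))
  if (!grepl("^([a-z]*[A-Z])+$", body))
    stop(sprintf(
      "grammar error in '%s': lowercase run must precede a residue", body))

  ## tokens: one optional lowercase run glued to each capital
  toks <- regmatches(body, gregexpr("[a-z]*[A-Z]", body))[[1]]
  seqv <- substr(toks, nchar(toks), nchar(toks))
  runs <- substr(toks, 1L, nchar(toks) - 1L)
  bad <- !seqv %in% .AA
  if (any(bad))
    stop(sprintf("grammar error: '%s' is not a standard residue code",
                 seqv[which(bad)[1]]))
  mods <- character(0)
  for (i in which(nzchar(runs))) {
    .ptmRow(registry, runs[i])  # unregistered symbol error
    mods[as.character(i)] <- runs[i]
  }
  Peptide(paste(seqv, collapse = ""), mods, nTerm = nterm, cTerm = cterm,
          registry = registry)
}

#' Render a peptide back to its 'H-P-OH' string
#'
#' Inverse of [parsePeptide()]: `parsePeptide(renderPeptide(p), reg)`
#' reproduces `p` exactly.
#'
#' @param p a \linkS4class{Peptide}
#' @return character(1)
#' @export
renderPeptide <- function(p) {
  seqv <- strsplit(p@sequence, "")[[1]]
  if (length(p@residueMods)) {
    pos <- as.integer(names(p@residueMods))
    seqv[pos] <- paste0(p@residueMods, seqv[pos])
  }
  paste0(p@nTerm, paste(seqv, collapse = ""),
         p@cTerm)
}

#' Monoisotopic neutral mass of a (modified) peptide
#'
#' Sum of the residue masses plus one water (the default `H-`/`-OH` termini)
#' plus the mass shifts of every residue and terminal modification.
#'
#' @param p a \linkS4class{Peptide}
#' @param registry a \linkS4class{PTMRegistry} with every symbol `p` uses
#' @return neutral monoisotopic mass in Da
#' @examples
#' reg <- readPTMTable()
#' peptideMass(parsePeptide("H-GG-OH", reg), reg)  # 132.05349
#' @export
peptideMass <- function(p, registry) {
  seqv <- strsplit(p@sequence, "")[[1]]
  m <- sum(.RESIDUE_MASS[seqv]) + .WATER_MASS
  for (sym in p@residueMods) m <- m + ptmShift(registry, sym)
  if (p@nTerm != "H-") m <- m + ptmShift(registry, p@nTerm)
  if (p@cTerm != "-OH") m <- m + ptmShift(registry, p@cTerm)
  unname(m)
}
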
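## Random valid peptides (with modifications and non-default termini drawn
## from the default registry) for property-style tests.

randomPeptide <- function(reg, lengthRange = c(5L, 20L), modRate = 0.15,
                          termRate = 0.3) {
  lens <- seq(lengthRange[1], lengthRange[2])
  L <- lens[sample.int(length(lens), 1L)]
  aa <- names(ORACLE_RESIDUE_MASS)
  seqv <- sample(aa, L, replace = TRUE)
  tab <- reg@table
  internal <- tab$symbol[!grepl("^-|-$", tab$symbol)]
  mods <- character(0)
  for (j in seq_len(L)) {
    if (runif(1) < modRate) {
      ok <- internal[vapply(internal, function(s)
        seqv[j] %in% strsplit(tab$residues[tab$symbol == s], ",")[[1]],
        logical(1))]
      if (length(ok)) mods[as.character(j)] <- sample(ok, 1L)
    }
  }
  ntOpts <- tab$symbol[grepl("-$", tab$symbol)]
  ctOpts <- tab$symbol[grepl("^-", tab$symbol)]
  nt <- if (length(ntOpts) && runif(1) < termRate) sample(ntOpts, 1L) else "H-"
  ct <- if (length(ctOpts) && runif(1) < termRate) sample(ctOpts, 1L) else "-OH"
  Peptide(paste(seqv, collapse = ""), mods, nTerm = nt, cTerm = ct,
          registry = reg)
}
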
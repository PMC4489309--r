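## Evaluation: per-PSM Pearson correlation between predicted and observed
## normalized intensities, pooled over the four ion series, plus grouped
## boxplot-style distribution summaries.

#' Pearson correlation between predicted and observed intensities
#'
#' Standard Pearson formula on two equal-length vectors (for a PSM these
#' are the concatenation of the four series' intensities). If either vector
#' has zero variance the correlation is undefined; `NA` is returned and the
#' caller flags the PSM as degenerate.
#'
#' @param pred,obs numeric vectors of equal length >= 3.
#' @return numeric(1) in [-1, 1], or `NA` for zero-variance input.
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))  # 0.98198
#' @export
pearsonR <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 points")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)
}

## PTM class of a peptide: no_ptm, mox (only methionine oxidation),
## cmm (only carbamidomethyl cysteine), other
.ptmClass <- function(p, registry) {
  if (!length(p@residueMods) && p@nTerm == "H-" && p@cTerm == "-OH")
    return("no_ptm")
  if (p@nTerm != "H-" || p@cTerm != "-OH") return("other")
  nms <- vapply(p@residueMods, function(s) .ptmRow(registry, s)$name,
                character(1))
  if (all(nms == "Oxidation")) return("mox")
  if (all(nms == "Carbamidomethyl")) return("cmm")
  "other"
}

#' Evaluate a model on annotated PSMs
#'
#' Predicts each PSM's spectrum with the model, annotates the observed
#' spectrum, and computes one pooled Pearson R per PSM over the
#' concatenated b+, y+, b++ and y++ normalized log2 intensities.
#' Cross-method evaluation is simply passing PSMs whose `method` tag
#' differs from the model's. Input PSMs are assumed to be
#' identification-filtered upstream.
#'
#' @param m an \linkS4class{IntensityModel}
#' @param psms list of PSMs: lists with `peptide`, `spectrum`, and
#'   optionally `method` (spectrum fragmentation method label).
#' @param registry a \linkS4class{PTMRegistry}
#' @param tol match tolerance in Da.
#' @param perSeries if `TRUE`, adds one R column per ion series next to the
#'   pooled R.
#' @return data.frame of evaluation records: `psm_id`, `r`, `degenerate`,
#'   `spectrum_method`, `model_method`, `precursor_charge`, `ptm_class`
#'   (and `r_b`, `r_y`, `r_b2`, `r_y2` when `perSeries`).
#' @export
evaluateModel <- function(m, psms, registry, tol = .DEFAULT_TOL,
                          perSeries = FALSE) {
  charges <- vapply(psms, function(x) precursorCharge(x$spectrum),
                    integer(1))
  bad <- which(charges != m@precursorCharge)
  if (length(bad))
    stop(sprintf("PSM %d has charge %d+ not covered by this model (%d+)",
                 bad[1], charges[bad[1]], m@precursorCharge))
  featList <- lapply(psms, function(psm)
    encodePeptide(psm$peptide, registry, m@precursorCharge))
  obsList <- lapply(psms, function(psm)
    intensityTargets(annotateSpectrum(psm$peptide, psm$spectrum, registry,
                                      tol = tol)))
  ## one forest pass per series over all PSMs, then split per PSM
  X <- do.call(rbind, featList)
  predAll <- vapply(.ION_SERIES, function(series)
    stats::predict(m@forests[[series]], data = X, num.threads = 1L,
                   verbose = FALSE)$predictions,
    numeric(nrow(X)))
  offsets <- c(0L, cumsum(vapply(featList, nrow, integer(1))))
  recs <- lapply(seq_along(psms), function(i) {
    psm <- psms[[i]]
    predSite <- predAll[(offsets[i] + 1L):offsets[i + 1L], , drop = FALSE]
    pred <- .siteToIonLayout(predSite)
    obs <- obsList[[i]]
    r <- pearsonR(as.vector(pred), as.vector(obs))
    rec <- data.frame(
      psm_id = i, r = r, degenerate = is.na(r),
      spectrum_method = if (is.null(psm$method)) NA_character_ else
        psm$method,
      model_method = m@method, precursor_charge = m@precursorCharge,
      ptm_class = .ptmClass(psm$peptide, registry),
      stringsAsFactors = FALSE)
    if (perSeries)
      for (series in .ION_SERIES)
        rec[[paste0("r_", series)]] <- pearsonR(pred[, series],
                                                obs[, series])
    rec
  })
  do.call(rbind, recs)
}

#' Boxplot-style distribution summaries of evaluation records
#'
#' Summarizes the Pearson-R distribution per group: n, mean, quartiles by
#' linear interpolation, and Tukey whiskers (most extreme datum within
#' 1.5 x IQR of the box). Degenerate records are excluded and counted;
#' empty groups are omitted with a warning.
#'
#' @param records data.frame from [evaluateModel()] (possibly several
#'   row-bound evaluations).
#' @param groupBy character vector of record columns to group on, e.g.
#'   `c("precursor_charge", "model_method")`.
#' @param value name of the summarized column (default `"r"`).
#' @return data.frame with one row per group: the grouping columns plus
#'   `n`, `n_degenerate`, `mean`, `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`.
#' @export
summarizeRecords <- function(records, groupBy = character(0), value = "r") {
  if (!nrow(records)) stop("no records to summarize")
  if (length(groupBy)) {
    keys <- interaction(records[groupBy], drop = TRUE, sep = "|")
  } else {
    keys <- factor(rep("all", nrow(records)))
  }
  out <- lapply(levels(keys), function(k) {
    grp <- records[keys == k, , drop = FALSE]
    v <- grp[[value]]
    nDeg <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning(sprintf("group '%s' has no non-degenerate records; omitted", k))
      return(NULL)
    }
    q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    res <- data.frame(n = length(v), n_degenerate = nDeg, mean = mean(v),
                      q1 = q[1], median = q[2], q3 = q[3],
                      whisker_low = lo, whisker_high = hi)
    if (length(groupBy))
      res <- cbind(grp[1, groupBy, drop = FALSE], res, row.names = NULL)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Boxplots of per-PSM correlations by group
#'
#' Draws the grouped R distributions the way method-comparison figures
#' usually do: one box per group, whiskers at the Tukey convention.
#'
#' @inheritParams summarizeRecords
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
plotCorrelationBoxes <- function(records, groupBy = "model_method",
                                 value = "r", ...) {
  keep <- !is.na(records[[value]])
  grp <- interaction(records[keep, groupBy, drop = FALSE], drop = TRUE,
                     sep = "/")
  graphics::boxplot(records[[value]][keep] ~ grp, range = 1.5,
                    xlab = paste(groupBy, collapse = " / "),
                    ylab = "Pearson R", ...)
}
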
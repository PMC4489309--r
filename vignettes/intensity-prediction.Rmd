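---
title: "Predicting MS2 fragment-ion intensities with ms2forest"
author: "ms2forest authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MS2 fragment-ion intensities with ms2forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a protonated peptide is fragmented in a tandem mass spectrometer, the
resulting MS2 spectrum is far from uniform: some backbone cleavages produce
intense peaks, others barely register. Which fragments light up depends on
the residues flanking the cleavage site (proline and glycine are the classic
examples), the position along the backbone, the precursor charge relative to
the number of basic residues (the mobile-proton picture), and the
fragmentation method — collision-induced dissociation (CID) and beam-type
higher-energy collisional dissociation (HCD) produce visibly different
intensity patterns from the same peptide. Accurate *in silico* intensity
predictions are useful for validating important identifications by eye, for
building spectral libraries, and for choosing transitions in targeted
proteomics.

`ms2forest` treats intensity prediction as supervised regression: for every
backbone cleavage site of a peptide we predict the normalized intensities of
the four most common fragment ions — b+, y+, b++ and y++ — with one random
forest per ion series, trained separately per fragmentation method and per
precursor charge (2+ and 3+). The package covers the full cycle: parsing
modified peptides, computing theoretical fragment m/z, turning annotated
spectra into regression targets, training, predicting to MGF/CSV, and
evaluating predictions by per-spectrum Pearson correlation.

## Peptide grammar and modifications

Peptides are written `H-P-OH`: `H-` is the unmodified amino terminus, `-OH`
the carboxyl terminus, and `P` the residue sequence in capital one-letter
codes. A run of lowercase letters immediately before a capital marks a
post-translational modification (PTM) on that residue: `H-SAoxMPLE-OH`
carries `ox` on the methionine at position 3. Terminal modifications replace
the default terminal symbols and keep their dash (`ace-SAMPLE-OH`,
`H-SAMPLE-am`). Symbols are resolved against a local registry table
(symbol, name, monoisotopic mass shift, residue scope) loaded from CSV; at
most eight symbols are accepted per run unless explicitly overridden, and a
residue can carry at most one symbol — the grammar gives stacked symbols no
unambiguous reading, so they are rejected rather than guessed. The parser
imposes no upper length limit; any peptide of two or more standard residues
is accepted.

Masses are monoisotopic throughout, and m/z uses the proton mass
(1.007276 Da), not the hydrogen atom mass: the b\(_i\) ion is the sum of the
first *i* residue masses (plus any N-terminal and in-range modification
shifts) plus one proton per charge; y\(_i\) adds water and the C-terminal
shifts to the last *i* residues. These conventions make the b/y
complementarity identity exact: neutral(b\(_i\)) + neutral(y\(_{L-i}\))
equals the peptide's neutral mass for every site, which the test suite
verifies against an independent summation oracle to below a nano-dalton.

## From observed spectra to regression targets

Training data are peptide-spectrum matches (PSMs): a peptide, a precursor
charge, and an observed MGF spectrum. Each theoretical ion takes the
intensity of the most intense observed peak within ±0.02 Da of its m/z
(absolute tolerance, configurable; appropriate for de-isotoped
high-resolution data — the package deliberately does not do ppm matching or
de-isotoping, which belong upstream). Matched intensities are divided by
the spectrum's total ion current (TIC) and transformed
\(x \mapsto \log_2(x + \varepsilon)\), where \(\varepsilon\) is 0.001 of
the median nonzero TIC-normalized peak intensity of that spectrum.
Unmatched ions receive the baseline \(\log_2 \varepsilon\): models learn
"absent" as the lowest intensity rather than dropping the example. The
transform is strictly monotone, so within-spectrum rank order survives
annotation; the normalization identifier is stored in every trained model
so predictions and evaluations are internally consistent. A single observed
peak may serve several theoretical ions — exclusive assignment would only
matter for near-isobaric fragments and would make annotation
order-dependent.

## Feature schema (v1)

Each training example encodes one (peptide, precursor charge, cleavage
site) triple as a fixed-length vector: peptide length; relative site
position; precursor charge; means of four bundled residue property scales
(gas-phase basicity, Kyte–Doolittle hydrophobicity, Chou–Fasman helicity,
isoelectric point) over the full peptide, the prefix and the suffix;
one-hot residue identity in a window of two residues either side of the
cleavage site (null-padded at the edges — the window half-width captures
the local proline/glycine effects that dominate cleavage propensity);
per-residue composition counts of prefix and suffix; and the
modification features. Modifications are encoded as *presence plus mass* —
summed mass shifts per side, modified-residue counts and site indicators —
never as PTM identity, so a model generalizes to any modification of
similar mass without retraining. The schema version is written into every
trained model, and `loadModel()` refuses a bundle whose schema does not
match the running encoder. Vector length is independent of peptide length,
which is what removes any length window on predictions.

## Models

One `IntensityModel` holds four `ranger` random-forest regressors (b+, y+,
b++, y++) plus metadata: fragmentation method, precursor charge, schema
version, training configuration and the reference \(\varepsilon\) used to
invert the log2 transform when writing spectra (predicted intensities are
floored at zero; MGF cannot carry negatives). Defaults: 50 trees per
forest, unlimited depth, `ranger`'s regression defaults for per-split
feature subsampling, seed 1. Fifty trees is a deliberate speed/accuracy
choice: median-correlation evaluation is insensitive to ensemble variance
well below this size, while training cost scales linearly in trees; the
tree count is recorded in the model metadata and trivially raised. One
regressor per ion series (rather than a multi-output model) mirrors the
per-series structure of the targets and keeps each regression
homoscedastic. Training is reproducible: a fixed seed yields bit-identical
predictions.

An optional redundancy filter (`dedupePsms()`) keeps the highest-TIC
spectrum per (peptide, charge) — large real PSM corpora are heavily
redundant, and how exactly such corpora are reduced before training is a
choice we make explicit rather than hard-code.

## Evaluation

For each PSM we compute one pooled Pearson *R* between the predicted and
observed normalized log2 intensities, concatenated across the four ion
series — pooling matches the one-number-per-spectrum reading of the usual
boxplot comparisons, and per-series correlations are available behind a
flag. Zero-variance vectors make Pearson undefined; such PSMs are flagged
degenerate, excluded from summaries and counted. Grouped summaries report
quartiles by linear interpolation and whiskers at the Tukey convention
(most extreme datum within 1.5 × IQR of the box) — stated explicitly
because figure captions in the literature are often ambiguous on this
point. Identification confidence (e.g. q-value filtering) is upstream: the
evaluator trusts its input PSMs.

## The synthetic-data module

No external corpus ships with the package; instead the simulator defines a
known ground truth so every claim about the pipeline is checkable. The
ground-truth intensity of each ion is a deterministic function of exactly
the information the feature schema can see: a per-series base level, a
Gaussian positional profile along the backbone, proline
enhancement/suppression at the following residue, glycine damping of b
ions, per-basic-residue (R/K/H) multipliers that differ between singly and
doubly charged fragments, a global non-mobile-proton damping when basic
residues are not outnumbered by protons, and exponential damping by
modification mass in the fragment. Because the rule is schema-visible, the
recovery ceiling for a correctly wired learner is near 1, so a recovery
failure indicts the implementation rather than the generator.

The observed spectrum multiplies each true peak by log-normal noise
(sd 0.2 on the natural-log scale by default), drops peaks with probability
0.05, and adds decoy peaks at ~0.1 per true ion at uniform random m/z —
roughly emulating the missing fragments and chemical noise of real spectra.
Generated peptides default to 15–16 residues, matching the synthesized
proteotypic-peptide pools typically used for independent evaluation, with
a 5% per-residue modification rate. Two presets, `methodA` and `methodB`,
differ in base levels, positional profile and proline/basic parameters;
they stand in for the CID/HCD contrast, and their intensity rank orders
differ for well over 30% of ions on random peptides.

What the simulator does *not* emulate: physically accurate mobile-proton
chemistry, neutral losses, isotope envelopes, retention time, or the
long-tailed intensity error structure of real instruments. Passing the
synthetic benchmarks therefore demonstrates that the pipeline is correctly
wired and that the learner recovers a learnable rule — not that predictions
on real spectra will reach any particular accuracy.

## Verified properties and problem sizes

The acceptance suite, and `scripts/acceptance.R`, recompute from scratch:

* grammar round-trips on 500 random modified peptides;
* fragment m/z against an independent summation oracle (1000 peptides,
  all four series, < 1e-9 Da) plus the b/y complementarity identity;
* parameter recovery: forests trained on 5,000 noiseless synthetic PSMs
  (charge 2+, preset `methodA`, seed 1) reach held-out median pooled
  *R* ≥ 0.95 on 500 PSMs; the label-permutation control — targets shuffled
  jointly across sites *and* series, which also destroys per-series
  intensity levels — trained on 1,000 PSMs stays within |*R*| < 0.15 of
  zero (the null is size-independent, so the control set is kept small);
* the matched-vs-crossed contrast: models trained on 400 PSMs per
  (preset × charge) cell under the default noise model, evaluated on 150
  held-out PSMs per cell; matched-method median *R* exceeds the
  cross-applied median by at least 0.1 in all four off-diagonal
  comparisons;
* the no-length-restriction contract (5-mer and 31-mer), the MGF
  TITLE/CHARGE round trip, and the 1000-peptide / 8-PTM input caps.

These sizes are the package's chosen desk-scale study conditions; the same
code runs unchanged at larger sizes.

## Numerical choices and degenerate inputs

* Quartiles use R's default type-7 linear interpolation.
* Peak matching uses a half-open binary search (`findInterval`) over the
  sorted peak list; ties between equally intense peaks resolve to the
  first, deterministically.
* An empty peak list annotates to an all-baseline target vector with a
  fallback \(\varepsilon = 10^{-7}\) (no TIC to scale by) rather than
  erroring: empty spectra are legal MGF.
* Dropped (unmatched) ions sit at a hard floor several log2 units below
  real peaks; under peak dropout this floor dominates squared deviations
  and is the main driver of correlation loss — visible in the noise
  decomposition of the test suite.
* Seeds: every stochastic stage takes an explicit integer seed, and
  per-PSM seeds are derived linearly from the dataset seed, so datasets
  are reproducible element-wise, not just as a whole.

## Known limitations

Only b/y ions at charges 1–2 are modelled — no a/c/x/z series, neutral
losses or precursor peaks. Only precursor charges 2+ and 3+ are accepted,
matching the training regime. The PTM registry is a local table, not a
live modification-database client, and isotope-label shifts must be given
numerically. The bundled property scales are one reasonable choice among
several; they are data files precisely so alternates can be swapped in
without touching code.
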
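---
title: "Mapping protein-protein interactions from SEC-MS co-fractionation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein-protein interactions from SEC-MS co-fractionation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofrac)
```

## The measurement and the inference problem

In size-exclusion chromatography coupled to mass spectrometry (SEC-MS), a
native cell lysate is separated on a sizing column, the eluate is collected
as a series of fractions (72 in the design this package mirrors), and every
fraction is quantified by data-independent acquisition MS. Each protein
then has an *elution profile* - its intensity across fractions - and
proteins that are part of the same complex co-elute: their profiles share
peak positions and shapes. The analysis problem is to turn thousands of
noisy, peptide-level traces into (i) a protein-protein interaction network
with a controlled false-discovery rate, (ii) apparent molecular weights
for elution peaks, (iii) per-protein scores for *differential* elution
between biological conditions (for instance phage-infected versus control
bacteria), and (iv) summary statistics of the resulting interactome.

`cofrac` implements that pipeline end to end, together with a synthetic
data generator that plants known complexes so that every stage can be
validated against ground truth.

## Protein profiles from peptide evidence

Peptide-level quantities are collapsed to protein traces by the
*sibling-peptide correlation* strategy: among a protein's peptides, the
unordered pair with the highest Pearson correlation - computed on traces
concatenated across all conditions and replicates, so the same two
peptides represent the protein everywhere - is averaged. With one or two
peptides the trace (or plain mean) is used. Ties are broken towards the
lexicographically first peptide pair so the choice is deterministic.
Undetected (peptide, fraction) cells count as zero, matching how DIA
reports omit undetected precursors and keeping every trace dense.

Each trace is then smoothed with a Savitzky-Golay filter and min-max
rescaled to [0, 1]. We use window 5 and polynomial order 2: the smallest
quadratic-preserving window, which suppresses fraction-to-fraction
quantification noise without flattening genuine peaks at 72-fraction
resolution. Negative filter output is clipped before rescaling, and
all-zero traces stay all-zero. Smoothing is applied per replicate and the
processed replicates are then averaged (and re-rescaled) into one profile
per protein and condition; smoothing first keeps each replicate's peak
positions visible to the average rather than smearing a pre-averaged
compromise trace. Peaks are called on the processed profile as local
maxima with topographic prominence at least 0.1 and width at half
prominence of at least 2 fractions; the peak count per protein is a
direct proxy for the number of assemblies the protein participates in.

## Molecular-weight calibration

A standards table (a commercial protein mixture, optionally extended with
a purified large species such as a 70S ribosome to anchor the high-mass
end) is fitted by least squares as log10(MW) on apex fraction - the SEC
convention, since elution volume is linear in log hydrodynamic size over
the column's resolving range. Queries outside the fraction span of the
standards are answered but flagged as extrapolated, because estimates
beyond the external calibration curve carry additional error. Monomeric
(sequence) masses use average residue masses plus one water. A peak is
called *assembled* when its apparent MW is at least twice the monomeric
mass, boundary inclusive; a protein is assembled if any peak is.

## Candidate pairs, features, and the neural classifier

Within one condition, all unordered protein pairs with squared Pearson
profile correlation of at least 0.3 become scoring candidates. Each
candidate is described by a 147-value feature vector (for F = 72; in
general 2F + 3):

* positions 1-72: sliding-window (q = 6, centred, edge-truncated)
  Pearson correlation, one value per fraction;
* positions 73-144: per-fraction absolute intensity difference;
* positions 145-147: the absolute shift between the primary
  (highest-prominence) peak apexes, the Euclidean distance between the
  traces, and the contrast angle (arccosine of the normalised dot
  product, radians).

Windows with zero variance in either trace contribute correlation 0 (no
evidence of co-movement), and a pair where either profile has no
qualifying peak reports shift 0.

The classifier is a fully connected network - input 147, hidden layers of
100 and 72 ReLU units, dropout 0.2 after the first hidden layer, one
sigmoid output - trained with Adam (learning rate 0.001, minibatch 32) on
binary cross-entropy for up to 100 epochs with early stopping (patience
20) and restoration of the best-validation weights; 22,145 trainable
parameters in total. It is implemented directly as matrix code in the
package (verified against finite-difference gradients in the test suite),
which keeps training fully deterministic under a single integer seed
covering initialization, the validation split, shuffling and dropout
masks. Feature columns are z-scored with training-set statistics that
travel with the model, since the feature blocks live on very different
numeric scales.

Two training-protocol choices matter far more than any architecture
detail, because the per-fraction feature blocks are *positional*:

1. **Train across several elution layouts.** A network trained on
   candidate pairs from a single dataset memorizes *where* that dataset's
   complexes elute and transfers poorly. Training pools candidates from
   ten independently simulated datasets (published co-fractionation
   classifiers train across many experiments for exactly this reason).
2. **Hold out whole datasets for early stopping, and augment by common
   shifts.** A random pair-level validation split shares layouts with the
   training half and cannot see memorization happening; the validation
   set is therefore composed of complete held-out datasets. In addition,
   every training pair contributes two copies in which both traces are
   circularly rolled by one common random offset (up to 20 fractions) -
   co-elution geometry is preserved while absolute positions are
   scrambled.

## Decoys and FDR control

To control for randomly co-eluting proteins, an equal number of decoy
pairs is sampled uniformly without replacement from the pairs that did
*not* pass the candidate screen, and scored by the same trained network on
their real featurized profiles. The estimated FDR at probability
threshold t is `#(decoys >= t) / max(1, #(targets >= t))`; each target's
q-value is the minimum estimated FDR over thresholds at or below its
score, which makes q monotone in the score, with ties sharing the worse
value. The final interaction set keeps targets with q <= 0.05 *and*
classifier probability >= 0.75. Scoring and q-values are computed per
condition; the combined network keeps, for each pair retained in any
condition, its best-probability row. Interactions are typed host-host,
host-phage or phage-phage from a per-protein organism map.

## Differential SEC analysis

For each protein present in two conditions, the package reports a
differential score in [0, 1]: a Bayesian comparison of H0 ("both profiles
are noisy copies of one shared latent profile") against H1 ("independent
latent profiles") with fraction-wise Gaussian noise of scale `noise_sd`, a
shared Gaussian latent prior, and equal prior odds. Both marginal
likelihoods are available in closed form (bivariate versus independent
normals after integrating the latent value out), so the score is exact;
the test suite checks it against direct numeric integration. Identical
profiles always score below 0.5; peak-position changes and relative
intensity (stoichiometry) changes both move fraction values and hence the
score. The score is unsigned; a signed apex-shift diagnostic accompanies
it.

`noise_sd` defaults to a plug-in estimate: the median absolute
fraction-wise difference between replicate profiles over *active*
fractions (either replicate above 10% of peak height). Restricting to
active fractions is essential - the flat baseline that dominates a
72-fraction trace would otherwise drag the estimate toward zero, and the
score would confidently flag the sub-fraction elution jitter that
unchanged proteins show between any two runs.

Whole-proteome abundance is treated as an independent axis: log2 fold
change of mean per-protein summed intensities with a two-sided t-test on
log2 intensities across replicates and Benjamini-Hochberg adjustment. A
protein is classed `assembly_only` (SEC score >= 0.5), `abundance_only`
(|log2FC| >= 2 and q <= 0.01), `both`, or `none`. A pure, uniform
abundance change is invisible to the SEC score by construction - 0-1
rescaling removes it - and is exactly what the abundance arm detects;
this is why the two thresholds are combined rather than folded into one
statistic.

## Network statistics

The retained interactions form a simple undirected graph. The package
reports: edge counts partitioned by interaction type; the log-log
least-squares fit of degree frequency against degree (the line drawn
through scale-free degree histograms - deliberately this regression, not
a maximum-likelihood power-law fit, with the caveat that the regression
is biased on raw heavy-tailed degree sequences); start-to-start genomic
distances in kb for phage-phage pairs on a linear genome; ROC sweeps with
trapezoid AUC and Youden-point threshold selection (ties towards the
stricter threshold) for virion-enrichment analysis; enrichment log2 fold
changes with a half-minimum pseudocount; and neighbourhood queries at a
configurable probability cut.

## The synthetic data generator

`simulate_dataset()` emulates the experimental design: 72 fractions, 2
replicates, a control and an infected condition. Its defaults are the
package's study conditions:

* 10 planted complexes of 3-5 members and 30 monomers. Each complex
  draws a target total mass log-uniformly over 150 kDa-3 MDa (the range
  real assemblies span on such columns) and realizes it with integer
  subunit copy numbers; its members share one Gaussian elution peak
  whose apex is placed by inverting the generator's log-linear column
  law at the realized stoichiometric mass. Monomers (15-300 kDa,
  log-uniform) elute at their monomeric mass. 30% of complex members
  additionally show a smaller (0.4 relative amplitude) monomeric peak.
* Peak standard deviations are drawn from 1.0-2.5 fractions - the
  generator's engineering choice for peak width, not a measured value.
* Replicates jitter apex positions with SD 0.5 fractions (complexes as a
  unit, so co-elution is preserved within a replicate), comfortably
  within the 1-2 fraction agreement real replicates show.
* Peptides (3-6 per protein) carry log-uniform response factors in
  [0.2, 1] - so top-2 selection is non-trivial - and multiplicative
  log-normal noise with unit mean and CV 0.1.
* In the infected condition, 20% of proteins are perturbed: an elution
  shift of 10 fractions (direction random, reflected if it would run off
  the column), a 2^2-fold abundance change, or both.
* Calibration standards are emitted noiselessly on the column law (a
  noise toggle exists), and ground truth records complexes, within-complex
  pairs, perturbation types, organism tags and virion labels.

What the generator does *not* emulate: retention-time drift between runs,
chimeric or shared peptides, missing-value structure beyond
zero-intensity, detector saturation, and a realistic proteome density
(thousands of proteins in 72 fractions). Passing tests therefore show the
pipeline's statistics behave as designed when their assumptions hold, not
that real data meet those assumptions.

## Validation protocol and problem sizes

The acceptance analysis trains the classifier once on ten simulated
datasets (two held out for early stopping, shift augmentation on) and
evaluates on twenty fresh datasets: candidate selection, featurization,
scoring, decoy competition and the q <= 0.05 / probability >= 0.75
filter, measuring the fraction of retained pairs that are not planted
co-complex pairs. With the default conditions this empirical FDR averages
a few percent with recall near 0.9. Differential-score validation uses
the shift-perturbed proteins as positives and unperturbed proteins as
negatives (abundance-only perturbations are excluded from the positive
set because their elution shape is unchanged by construction - they are
the abundance arm's job). These problem sizes (roughly 70 proteins per
dataset, 30 datasets end to end) keep the whole validation run in a few
minutes on one CPU while leaving every statistic estimable.

## Numerical and design notes

* Correlation over zero-variance windows or traces is defined as 0; an
  identical window pair is exactly 1 by definition (bypassing float
  cancellation in near-flat Gaussian tails).
* The dropout specification "0.2" is a rate of 20%; a literal 0.2% would
  make the layer inert.
* The candidate screen interprets the profile dot-product matrix as
  squared Pearson correlation - a raw dot product has no natural 0.3
  threshold on rescaled profiles.
* Decoys are scored on their true featurized profiles, not permuted
  traces, so the null represents real non-co-eluting biology.
* The q-value estimator is the standard decoy/target count ratio with
  step-down monotonisation; the assembled-state boundary (2x monomer) is
  inclusive; the 70S-type anchor standard is regressed together with the
  protein mixture rather than anchored separately.
* `sample.int()` is used for all range sampling so degenerate ranges
  (e.g. complexes of exactly 3 members) do not fall into R's scalar
  `sample()` trap.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1))

# train on independent layouts, then score the dataset of interest
train_sims <- lapply(901:910, function(s) simulate_dataset(sim_config(seed = s)))
model <- train_on_simulation(train_sims, holdout_sims = 2, augment_shifts = 2)

res <- score_interactions(sim, model, decoy_seed = 1,
                          organisms = sim$truth$organisms)
res$network

# how many retained pairs are real?
mean(planted_pair_labels(sim$truth, res$network) == 1)

# differential analysis between conditions
prof <- res$profiles
raw  <- smooth_and_rescale(infer_protein_profiles(sim$peptides))
diffs <- sec_differential(prof, "control", "infected",
                          noise_sd = estimate_noise_sd(raw))
```

## Known limitations

* The differential score's two-hypothesis Gaussian model is a documented
  stand-in for the richer Bayesian machinery of complex-centric profiling
  tools; it preserves the [0, 1] contract and 0.5 decision boundary but
  does not decompose the change into named modes.
* The log-log degree regression is faithful to how interactome figures
  draw the fit but is a biased estimator of the exponent on raw
  heavy-tailed degree sequences; recovery tests use graphs with planted
  power-law degree *frequencies*, where the regression is consistent.
* Training the classifier on one elution layout silently overfits; the
  multi-dataset protocol above is not optional in practice.
* The pipeline assumes fractions are aligned across runs; there is no
  retention-time alignment step.
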
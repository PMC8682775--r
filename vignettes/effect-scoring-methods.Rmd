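---
title: "Scoring synonymous variants from observation status: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring synonymous variants from observation status: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Synonymous single-nucleotide variants (sSNVs) change a codon without
changing the protein, yet they can act through codon usage, translation
kinetics, mRNA structure, splicing and regulatory motifs. Supervised effect
predictors for sSNVs are starved of labels: experimentally validated effect
variants number in the dozens, and "pathogenic" is not the same thing as
"functional effect". `synev` instead learns from *observation status*: which
of the possible sSNVs in a transcript set have ever been reported in
population sequencing (observed in two or more individuals, or a singleton),
and which never have (the *generated* set). No conservation track and no
disease label enters the model at any stage.

The working assumptions are the population-genetic ones: variants carrying a
large deleterious effect are unlikely to ever be observed, and are
essentially never common; common variants are depleted in effect. The model
stack turns those assumptions into labels in three steps.

## The three stages

**1. Positive-unlabeled learning (PUL).** Observed variants are positives;
generated variants are unlabeled. Each epoch trains a gradient-boosted tree
classifier (100 trees, depth 5, 30% column and 30% row subsampling --
deliberately conservative) on the positives versus an equal-sized sample of
the unlabeled pool, scores the entire remaining pool, and moves everything
scoring below 0.5 (observed-like) into the *not-seen* set. Sampling of
unlabeled variants is *transcript-balanced*: a generated variant is drawn
with probability proportional to the number of observed sSNVs on its
transcript, so the classifier cannot simply memorise variant-rich
transcripts. At convergence the residual pool is the *unobservable* set.
Scores exactly equal to 0.5 stay unlabeled (strict inequalities throughout).

Convergence: the loop stops when an epoch reclassifies fewer than 0.1% of
the original unlabeled pool, or at `max_epochs` (100). A fraction (10%) of
observed variants is held out before the first epoch; the run aims to end
with under 5% of them misclassified. Because the held-out set is small at
desk scale (about 150 variants), its error estimate fluctuates by several
percent between epochs; the abort guard therefore fires only when the error
has first reached the target and later climbs *significantly* above it
(one-sided binomial test at the 5% level), not on a noise bounce. The error
shrinks as the pool purifies, so in practice the reclassification criterion
is the one that triggers.

One property worth knowing: the procedure scores *all* unlabeled variants
with the epoch model, including those just used as class-1 training
examples. Boosted trees partially memorise their training rows, so even
when the unlabeled pool is statistically identical to the positives a noise
floor of roughly 15-20% of the pool resists absorption into not-seen. Under
planted separable structure this floor is irrelevant (recovery of a planted
unobservable set exceeds 95% in the bundled tests), but the unobservable
fraction should never be read as a calibrated probability.

**2. Intermediate model and relabeling cutoffs.** A second boosted-tree
model discriminates observed (class 0) from not-seen (class 1) variants,
with 9:0.5:0.5 train/validation/test splits per class, validation and test
balanced by down-sampling the majority class, training balanced by
up-sampling the minority with replacement, and hyperparameters chosen by
maximising validation F1 over a declared grid (trees 100/300, depth 4/6,
learning rate 0.1/0.3 by default). Two score sets that never touch any
training split anchor the relabeling: a 10% held-out sample of *common*
variants (MAF > 0.01; assumed depleted in effect) and the *curated-effect*
variants (experimentally supported effects). The median intermediate score
of the held-out common set becomes the lower cutoff `c_lo`; the median of
the curated-effect set becomes `c_hi` (even-sized sets use the
mean-of-middle-two median; `c_lo >= c_hi` is a hard error since labeling
would be impossible). Variants scoring below `c_lo` are labelled
*no-effect*, above `c_hi` *effect*; the band in between (cutoff ties
included) stays unlabeled, is dropped from final training, and is still
scored at prediction time.

**3. Final model.** The same training scheme, effect versus no-effect. The
emitted score in [0, 1] is the per-variant effect score; the binary call
puts scores at or above 0.5 into the effect class.

Curated-effect and held-out common variants are excluded from *every*
training stage, including PUL and the feature encoders.

## The 35 variant features

Six groups, frozen in `inst/extdata/feature_schema.tsv` so matrices are
column-stable:

* **Codon bias and autocorrelation (10)** -- CAI plus the
  mutant-minus-wild-type delta forms of CAI, fracOpt, CUB, ICDI, SCUO, tAI
  and TPI, and the variant-specific CAM and CF (below).
* **Protein structure (3)** -- secondary-structure class, solvent
  accessibility, disorder at the variant's residue, consumed from
  precomputed per-residue tracks.
* **mRNA stability (8)** -- per-transcript folding summaries (MFE-structure
  frequency, centroid free energy, ensemble distance), the local pairing
  category at the variant base, and four per-variant structure-change
  records (local/global dissimilarity and their p-values). The structure
  predictors themselves are never invoked; their outputs are consumed as
  tables, and the parameter rule for local structure-change prediction
  (mode 1 / window 100 for length <= 200 nt; mode 1 / 200 for 200-500; mode
  2 / 500 above) is exposed as `rnasnp_params()` for users generating those
  tables.
* **Regulatory distances (4)** -- minimum nucleotide distance to splice
  sites, TFBS, RBP motifs, and exonic splicing regulators, binned into
  `d=0`, `0<d<=3`, `3<d<=5`, `5<d<=10`, `10<d<=20`, `d>20`. The "no site"
  sentinel maps to `d>20`.
* **Expression (3)** -- log10 of the minimum, median and maximum per-tissue
  expression, pseudocount 1e-3 before the log.
* **Miscellaneous (7)** -- the wild-type/mutant codon pair
  (`codon_mutation`), the next and previous codons, the within-codon offset,
  relative position, transcript length in codons, and CDS GC content.

Continuous features are standardised by training-split mean/sd and imputed
with the training median; categorical features are integer-coded against a
lexicographic vocabulary frozen at fit time, with 0 reserved for unseen
categories. Mixed-type feature correlations use Pearson
(continuous-continuous), Cramer's V (categorical-categorical) and the
correlation ratio (mixed); feature importance is the mean split gain of the
boosted trees.

## Codon measures: definitions and design choices

CAI is the geometric mean of relative adaptiveness weights (codon count over
the most frequent synonymous codon's count in the reference set); fracOpt
the fraction of optimal codons; both, like tAI, need a reference built from
the top 1% of transcripts per tissue by expression (ceiling rule, union over
tissues; zero-count codons get a 0.5 pseudo-count so weights stay positive).
CAI, ICDI and SCUO skip methionine, tryptophan and stop codons, the usual
convention for single-codon amino acids.

Several closed forms had to be fixed here as package design choices:

* **CUB** ("amino-acid-frequency-weighted codon bias") is implemented as
  the Karlin-Mrazek usage difference
  \(B = \sum_a p_a \sum_c |f(c\mid a) - f_{ref}(c\mid a)|\).
* **ICDI** uses \(S_a = \sum_i (RSCU_i - 1)^2 / (k(k-1))\) averaged over
  degenerate amino acids: 0 for uniform usage, exactly 1 when one codon per
  family is used exclusively.
* **SCUO** is the Shannon-entropy form
  \(\sum_a F_a (H^{max}_a - H_a)/H^{max}_a\), zero when a family's codons
  are used equally.
* **tAI** is the geometric mean of per-codon tRNA availability weights over
  sense codons. The weights are a user-supplied table; the bundled default
  (`trna_weights_synthetic.tsv`) is a *synthetic* proxy (a seeded draw with
  the family-normalised shape of gene-copy-number weights), suitable for
  testing only -- supply your organism's table for real work.
* **TPI** (codon autocorrelation) is the runs-based form: per isoacceptor
  family, the number of same-codon adjacent pairs `r` is compared with its
  random-permutation expectation, normalised to [-1, 1] as
  \((r - E[r])/(r_{max} - E[r])\), and families are averaged weighted by
  their size minus one. Clustered usage (XXXYYY) scores above interleaved
  usage (XYXYXY) at equal composition; sequences with no repeated family
  return the sentinel 0 so feature vectors stay dense.
* **CAM**, the variant-specific autocorrelation measure, awards a codon the
  credit \(1/d\) where `d` is the codon distance to the nearest other
  occurrence of the same codon (0 if none); CAM is the mutant codon's credit
  minus the wild-type codon's. The inverse-distance kernel was chosen over
  an exponential one for having no extra scale parameter; any strictly
  decreasing kernel preserves the defining property that the impact
  magnitude shrinks as the nearest isoaccepting partner moves away.
* **CF**, the change-of-frequency measure, is the frequency the mutant codon
  will have after the mutation minus the frequency the wild-type codon had
  before: \(((n_{mut}+1) - n_{wt})/N\). Positive values mean the variant
  moves the transcript toward a codon at least as frequent as the one it
  replaces.

All delta forms are mutant minus wild-type; each is checked against an
independently coded brute-force recomputation (tolerance 1e-9), and the
feature pipeline's fast incremental versions are checked against the
one-at-a-time functions.

## Cross-species variation

A human sSNV is a *CSV* of a species when the species' aligned codon (in a
codon-aware ortholog alignment) equals the variant's mutant codon -- a
full-codon match, not a single-base one. Species with a gap codon at the
column are excluded from both CSV calls and codon mutation fraction (CMF)
counts. CMF measures how common the alternative codon is compared with the
reference codon: mutant-codon count over mutant-plus-reference count in the
column, so a column of 10 reference, 5 mutant and 5 other codons gives
5/15 = 0.33. Divergence trends use only species-unique CSVs and report the
per-species median effect score against log2 million years since
divergence, with a Spearman rank correlation; constraint-bin analysis
groups variants by constraint percentile and correlates the observed
fraction and the median observed score against the bin midpoint.

## The synthetic data generator

Everything the pipeline consumes can be generated at desk scale:
valid CDSs (start/stop codons, no internal stop, GC close to target),
regulatory site intervals (splice sites anchored at the CDS ends),
per-residue and per-base structure tracks with fixed vocabularies,
log-normal expression, per-variant structure-change records, and ortholog
rows whose synonymous substitution counts are Poisson with mean
proportional to divergence time.

The planted structure mirrors the modelling assumptions: a latent effect is
drawn from a logistic model over a declared subset of the visible features
(structure-change dissimilarity, CAM, CF, delta-CAI by default); the
probability of a variant ever being reported decreases with that effect,
with the intercept calibrated so about 12% of all possible sSNVs are seen;
allele counts of seen variants are log-normal (count 1 defines singletons,
roughly half of seen variants; MAF above 0.01 defines common variants) and
are drawn *independently* of the latent effect, so effect scores should not
correlate with allele frequency; an *unobservable* subset (20% by default)
is planted by a hard threshold on one feature's upper tail and never
genuinely observed (only sequencing noise, rate 0.005, can make such a
variant a spurious singleton). A synthetic curated-effect set is drawn from
the top of the latent-effect distribution. The hidden truth table is
returned separately and never consumed by the pipeline. The
`strong_signal` preset doubles the effect weights and steepens the
observation slope for end-to-end signal checks; the matching no-signal
control is a label shuffle, not a generator preset.

What the generator does *not* emulate: mutation-rate heterogeneity (CpG
transitions), linkage between variants, realistic allele-frequency spectra,
transcript families sharing sequence, or any correspondence between the
planted effect and real biochemistry. Passing tests on generator output
therefore demonstrate that the machinery recovers planted structure of the
assumed form at desk scale -- not that the scores are accurate on real
genomes, which requires population-scale variant catalogs and real
annotation tracks.

## Problem sizes and numerical choices

The bundled tests and checks run the full pipeline on 200 transcripts of
40-80 codons (about 25,000 possible sSNVs, of which about 3,000 are seen),
a size chosen so every stage -- including about 25 PUL epochs and two
grid-searched model fits -- completes in well under half an hour on a single
CPU while leaving every class populated (about 90 common variants, 40
curated-effect variants). Oracle suites use toy CDSs of 8-16 codons so that
exhaustive enumeration (all single-base substitutions, all family
permutations for the TPI expectation) stays trivial.

Other fixed choices: catalog keys are
`transcript:codon_index:offset:alt_nt` with 1-based codon indices and
1-3 within-codon offsets; site intervals are 0-based half-open,
transcript-local; stop-codon synonymous exchanges (TAA/TAG/TGA) are
excluded unless explicitly enabled; undefined autocorrelation returns 0;
undefined evaluation ratios (zero denominators) return NA; xgboost runs
single-threaded with a per-fit seed so traces are bit-reproducible; all
pipeline randomness flows from one root seed with fixed stage offsets.

## Limitations

Scores are transcript-specific; aggregating across transcripts of a gene is
left to the user. The unobservable set conflates biological and technical
causes and inherits the memorisation floor described above. The relabeling
cutoffs depend on the quality and size of the common and curated-effect
sets; with very small anchor sets the medians are noisy, and the hard
`c_lo < c_hi` check is the only structural protection. F1-optimised model
selection can favour high-recall degenerate solutions when the two classes
are genuinely inseparable; inspect the reported confusion counts, not just
F1.
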
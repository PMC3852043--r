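---
title: "Methods: transcript features and jackknifed greedy regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript features and jackknifed greedy regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters and the design
decisions behind `txpredict`, in the spirit of a methods supplement: what
each component assumes, which choices were genuinely open, and what the
synthetic validation does and does not establish.

## The model

Each gene is a triple of sequence segments (5'UTR, ORF, 3'UTR), with the
ORF a non-empty multiple of 3 nt starting at ATG and ending at a stop codon
(strict mode; permissive mode truncates/warns instead). From the segments
the package computes a catalogue of features; from the features it builds
sparse regressors of five log-scale expression measures (mRNA, PA, RD and
the derived PPR = PA/mRNA and RL = RD × mRNA). The regression model is
deliberately simple — OLS or MARS over a small, greedily selected feature
subset — because the scientific object of interest is *which features
predict, and how robustly*, not the regressor itself.

## Inference procedure

* **Terciles, 100 times.** Genes are partitioned uniformly at random into
  train/test/validation thirds (sizes differ by at most one; the remainder
  goes to train, then test); the partition is repeated `nReplicates` times
  (default 100; the shipped validation experiments use 20 per family to
  keep a full run under a minute per cell at 1000 genes — the statistical
  behaviour is the same, only the prevalence resolution is coarser).
* **Greedy growth, test-set stopping.** Features are added one at a time by
  train-set correlation of the refit model; growth stops the first time the
  test-tercile correlation fails to improve by more than `eps` (default 0),
  or at `maxFeatures` (default 30, consistent with families averaging a few
  to a few dozen features). The first feature is always kept. A variant
  that selects by test correlation is available (`selectBy = "test"`) for
  sensitivity analysis; the default selects by train and uses test only for
  stopping.
* **Ties.** Argmax ties — including floating-point-identical duplicates
  such as a fixed-width window score and its per-nucleotide version — are
  broken by catalogue order, with a 1e-10 tolerance so that bitwise noise
  in the correlation cannot flip the choice. This makes family output a
  deterministic function of (data, config, seed).
* **Scoring.** Pearson correlation on log targets by default (expression
  spans decades); Spearman by configuration. Non-positive target values
  become missing before the log; genes with missing values are excluded
  pairwise; fewer than 3 complete pairs, or constant predictions, give a
  missing score with a warning.
* **Median predictor and prevalence.** The family is summarised by the
  member with the median validation correlation (lower median for even
  family sizes, so the reported predictor is always an actual member) and
  by per-feature selection counts.

## Scheme A vs scheme B

Codon-adaptation indices, the start-context PSSM and the TASEP rates
traditionally require expression data. Scheme A avoids that: tAI weights
come from tRNA gene copy numbers with the standard wobble penalties
(G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68), and the CAI reference set and
PSSM training set are the top `topFraction` (default 0.1, floor of 10
genes) ranked by that tAI — a transcript-only proxy for high expression.
The constructor-level guard is deliberate: scheme-A extraction raises an
error if handed an expression table.

Scheme B re-infers these parameters per jackknife replicate from the train
tercile's mRNA only: deterministic coordinate ascent (step 0.05, fixed
parameter order, sweep cap) on the wobble penalties (tAI) or per-codon
weights (CAI), maximising the Spearman correlation between gene index and
train mRNA; the PSSM is retrained on the top train-tercile genes by mRNA.
Rank correlation was chosen as the objective because the measurement scale
is unknown; determinism (no restarts, fixed order) was preferred over a
stochastic optimizer so that families remain reproducible. By default the
TASEP feature is not re-simulated per replicate (`schemeBTasep = FALSE`):
re-running a stochastic lattice simulation for every gene in every
replicate would dominate the runtime while the scheme-B signal of interest
lives in the adaptation and context parameters; the switch exists for
completeness.

## TASEP

The translation-rate feature is the steady-state current of an open TASEP
with extended particles: a ribosome covers `ell` codon sites (default 9),
initiation at rate `alpha` (default 0.1, the initiation-limited regime)
requires the first `ell` sites free, site-to-site hops need `ell` sites of
clearance, exit at `beta` (default 10). Hop rates are the codon weights
along the ORF rescaled to mean 1, so the current is a dimensionless rate
shaped by codon *order*, not only content. The simulator is a Gillespie
continuous-time chain in compiled code with its own xorshift RNG seeded per
gene (hash of the gene id xor the global seed), so results do not depend on
gene order and never perturb R's RNG stream. The exact 2^n-state stationary
solve (`exactTasepSmall`, n ≤ 10, ell = 1) is shipped as the oracle; the
Monte-Carlo error is a batch-means standard error, and feature extraction
uses a fast profile (2×10³ burn-in, 10⁴ sampled events) whose Monte-Carlo
noise is small relative to the between-gene spread (two independent draws
of the feature correlate at ≈ 0.985 on the standard fixture).

## Folding

The default folding engine is a weighted base-pair maximisation (GC = 3,
AU = 2, GU = 1, minimum hairpin loop 3), a self-contained stand-in for a
thermodynamic folder with the same sign convention (scores are negated so
more structure is more negative); a minimum-free-energy provider can be
plugged in behind the same interface. Window geometry is configuration:
last 40 nt of the 5'UTR, first/last 90 nt of the ORF, first 40 nt of the
3'UTR, and sliding 40-nt windows at step 10 over the first 300 nt of the
ORF. expPARS is interpreted as exp applied per nucleotide and then
averaged over the window; the alternative (exponentiating the window mean)
is a one-line change and monotone-equivalent for ranking.

## Definitional choices in the initiation features

* uORF: an ATG in the 5'UTR with an in-frame stop entirely inside the
  5'UTR; a configuration flag admits stops inside the ORF continuation.
* Shifted ORFs: alternative ATGs at offset > 0; frame = offset mod 3;
  F1/F2 counts require an in-frame stop within the ORF, the F0 count is the
  plain in-frame alternative-ATG count.
* ATG scans are overlapping (step 1); stop codons are TAA/TAG/TGA (the
  standard code; non-standard codes are out of scope).
* Distance features measure nucleotides between the (first) ATG and the
  main START; when a segment has no ATG the sentinel is segment length + 1,
  larger than any realisable distance.
* Context scores use a Kozak-like window of 6 nt upstream and 3 nt
  downstream of the ATG, scored as summed log-odds against the pooled
  background with pseudocount 1; positions outside the transcript
  contribute 0, and relative scores subtract the main-START score.

## The synthetic generator

The generator emulates the statistical shape this analysis assumes:
log-normal segment lengths calibrated to means 82.33 / 1490.8 / 133.62 nt
(5'UTR/ORF/3'UTR), codon sampling biased by tAI weights with a per-gene
bias temperature (creating a tAI/CAI spread) and an independent per-gene GC
preference, independent per-segment UTR GC draws, controlled uORF injection
(0–2 per gene, expected rate 0.3) plus "decoy" ATGs too close to the ORF to
form a uORF, a controlled (scrubbed-then-injected, length-independent)
3'UTR ATG count, and optional PARS profiles correlated with the folding
structure of the fixed windows. Expression is planted: a latent signal
Σ βᵢ·z(featureᵢ) over five features, with independent Gaussian noise per
target calibrated so the planted R² is exactly the configured value
(default 0.5), and PPR/RL derived — never planted — exactly as the real
pipeline derives them.

The planted set (5'UTR length, 3'UTR length, uORF count, 3'UTR ATG count,
folding strength of the first 40 ORF nt) was chosen for *identifiability*:
each
planted feature is the unique best representative of an independent
generator dial. That is a requirement of a parameter-recovery experiment,
not a convenience — when two planted features share a latent cause (e.g.
two segment GC features fed by one GC draw, or two codon-space indices fed
by one bias temperature), catalogue features that aggregate both (whole
transcript GC, CAI) legitimately out-predict either planted feature and
prevalence fragments, telling you about the generator's degeneracy rather
than the selector's correctness. The generator therefore keeps its dials
independent, and the UTR scrubbing/injection ensures uORF and ATG counts
are controlled exactly (a `uorfRate` of 0 means zero uORFs, by
construction) and independent of the segment lengths — a window-truncated
twin (a segment GC and its 30-codon window at r ≈ 0.95) or a
length-coupled count would otherwise make prevalence a coin flip between
near-duplicates.

What the synthetic validation does **not** show: real transcriptomes have
correlated segment properties, phylogenetic structure, composition-length
dependence and measurement error far richer than this generator; passing
recovery here demonstrates the machinery (extraction, leakage-free
jackknife, selection, scoring) is correct, not that the biological
conclusions transfer to any particular organism.

## Numerical choices

* OLS uses an SVD pseudoinverse; rank-deficient designs get the
  minimum-norm solution with a warning (predictions are unaffected).
* MARS: forward pass adds mirrored hinge pairs at observed-quantile knots
  (the p = 0 knot makes an exactly linear basis available on the train
  range, which prevents extrapolation blow-ups on linear truths);
  interaction degree ≤ 2; backward pruning by GCV with effective
  parameters = terms + 3 × (distinct knots). Candidate screening for the
  greedy-MARS combination ranks candidates by residual correlation and
  fits MARS only for the top `screenTop` (default 25).
* Standardisation statistics (feature means/sds) are always train-tercile
  statistics; zero-variance columns are unselectable.
* Coordinate-ascent steps are clamped (s in [0, 0.9999], weights in
  (0, 1]); zero tAI weights are imputed with the geometric mean of the
  non-zero weights so logarithms stay defined.
* Validation experiments in the test suite use 20-replicate families at
  500–1000 genes; these sizes were chosen to make the statistical
  assertions stable while a full suite run stays around a minute.

## Known limitations

* The folding default is a base-pair maximisation, not a thermodynamic
  ensemble; absolute folding-energy scales should not be interpreted.
* The TASEP feature carries Monte-Carlo noise at the fast profile; studies
  of that feature in isolation should raise the horizons.
* Scheme-B CAI optimisation over 61 weights is expensive relative to its
  4-parameter tAI counterpart and is sweep-capped by default.
* The catalogue's pair-frequency families (61×61, 20×20) are sparse for
  short ORFs; their defaults (zero) are shared with genuinely absent pairs.
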
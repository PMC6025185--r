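---
title: "Integrating four evidence channels for domain-level GO annotation"
author: "domannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating four evidence channels for domain-level GO annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domannot)
```

## The problem

Structural domains are the units that actually carry molecular function,
yet GO annotation databases describe whole proteins. Transferring
annotations down to domains requires combining evidence of very different
character — structure-based protein–domain mappings, sequence-signature
databases, profile classifiers, and homology — each incomplete and each
with its own error profile. `domannot` implements the four component
scorers, fuses them with a binned likelihood-ratio naive-Bayes
integrator, and evaluates the result with the CAFA-style Fmax protocol.

## Ontology handling

The OBO parser keeps `is_a` and (by default) `part_of` edges, drops
obsolete terms into a registry, and records `alt_id` remappings.
Annotation sets are closed under the true-path rule before any counting:
an entity annotated with a term is implicitly annotated with all its
ancestors within the same aspect. We propagate over `is_a` + `part_of`
because that is standard GOA practice; `regulates` is never followed, and
the rare cross-aspect `part_of` edges are ignored so that MF/BP/CC remain
independent evaluation universes. Whether upstream counts should use
propagated or direct annotations is a genuine design choice; we propagate
everywhere (scoring, calibration, evaluation), which makes the
parent-score dominance invariants (`P(parent) ≥ P(child)` for every
counting scorer) hold by construction and keeps all stages consistent.

## The four component scorers

**Structural (Str).** Proteins with protein structure distance (PSD)
strictly below 0.1 are a domain's structural neighbors (PSD combines RMSD
with a secondary-structure alignment score; lower is more similar; the
alignment itself is upstream tooling — the package consumes a
precomputed neighbor table). `P1(g|d)` is the fraction of neighbor
proteins carrying `g`. Proteins are counted at PDB-entry granularity
(chain suffixes collapsed) since neighbor lists name proteins, not
chains; a switch retains chains. A `min_support` floor (default 1) is
exposed because one-neighbor fractions are noisy, but no floor is applied
by default.

**InterPro (IPR).** With `n` distinct InterPro accessions hit by the
domain sequence, `P2(g)` is the fraction whose (propagated) InterPro2GO
term set contains `g`. Accessions missing from InterPro2GO stay in the
denominator — the definition divides by the number of InterPro domains
owned by the sequence, not the number of mapped ones — so unmapped hits
dilute rather than inflate the score.

**PSSM classifier (PSSM).** Each PSI-BLAST ASCII profile (first, log-odds
block; the percentage block is ignored, matching common practice) is
compressed by the auto-covariance transform: for each of the 20
descriptor columns and each lag 1..l (default l = 10),
`AC = 1/(DL−lag) Σ (X_i − X̄)(X_{i+lag} − X̄)`. The result is a
fixed-length 200-dimensional vector regardless of sequence length.
Cross-covariance between distinct descriptor columns (the "CC" half of
the ACC family, same normalisation) is available behind a flag but off by
default: the auto-covariance half is the part with an explicit printed
definition, and 200 dimensions train faster and more stably at small n.
One binary SVM (linear kernel by default, for determinism and speed; RBF
available) is trained per GO term with at least 10 positive and 10
negative domains; margins are calibrated to probabilities
`P3 = 1/(1+exp(A·f+B))` with (A, B) fitted by the numerically robust
Newton procedure with prior-smoothed targets. Calibration is fitted on
out-of-fold margins (5-fold, stratified, seeded) rather than training
margins, which would be optimistically separated. After successful
calibration A < 0, so P3 increases with the margin.

**Homolog transfer (Seq).** BLAST hits with query coverage strictly above
0.6 survive (query-relative, because the query is the domain being
annotated; the boundary convention is configurable input, not output).
Each homolog votes with weight `(−log E + b)` normalised over retained
homologs, with `b = log 10` in the same base as the logarithm — which
makes `P4` invariant to the log base, so the natural log is used
internally without loss of generality. E-values printed as 0 are clamped
to 1e-180 upstream; hits with E > 10 would get negative weights and are
dropped.

## The likelihood-ratio integrator

Component scores on labelled calibration pairs are split into 10
equal-width bins over [0,1] (convention `[lo, hi)`, last bin closed;
binning uses `findInterval` on the shared edge vector so boundary scores
land consistently with the serialized edges). Per method and aspect:

```
LR_b = ((pos_b + s) / (neg_b + s)) / ((pos_tot + s) / (neg_tot + s))
```

with additive smoothing s = 1 per cell so no LR is ever 0 or infinite.
Pairs a method produced no score for go to an "absent" pseudo-bin, making
missing evidence itself informative. The calibration universe is the set
of (domain, term) pairs scored by at least one method; an all-pairs
universe is available but is dominated by never-predicted pairs and adds
nothing at great cost. Prior odds are estimated per aspect
(`pos_tot/neg_tot`); a per-term prior is out of scope. At prediction time
the combined LR is the product over the four methods and the posterior is
`prior_odds·LR / (1 + prior_odds·LR)`. The product form assumes the
channels are conditionally independent given the label — the usual
naive-Bayes idealisation; correlated channels (e.g. IPR and Seq both
driven by sequence similarity) will make posteriors overconfident, which
is a known limitation, not a bug. `fit_lr_table()` returns a classed
object with `print`/`summary`/`predict` methods; tables serialize to a
self-describing TSV.

Reported annotations default to posterior ≥ 0.5 (inclusive).

## Evaluation

Domain-centric CAFA-1 averaging: at each threshold, precision is averaged
over domains making at least one prediction at that threshold, recall
over all gold-annotated domains; Fmax maximises the harmonic mean over
the sorted distinct prediction scores (exact, no grid). Aspect-root terms
are excluded from gold and predictions — they are trivially true and
would inflate both precision and recall. Coverage is the fraction of the
domain universe with any prediction. Fmax is invariant to monotone score
rescaling by construction. Train/test decontamination removes test
domains strictly above 90% identity to any training domain, consuming
identities from BLAST-style tables rather than computing alignments
internally (alignment is standard tooling, not this package's method).

## The synthetic benchmark

`generate_fixtures()` emulates the full input layout with known
generating parameters: a random three-aspect DAG (default 60 terms,
depth 4), 60 domains with 2 gold draws per aspect (then true-path
closed), and per channel

* neighbor proteins inheriting each gold term with probability
  `signal["str"]` (default 0.9) plus Binomial(2, noise) spurious terms
  (noise = 0.1), PSD drawn below 0.1 with ~10% decoy rows above it;
* per-domain InterPro entries carrying gold terms at `signal["ipr"]`;
* ASCII PSSMs in which domains positive for designated terms (chosen as
  the terms with enough positives and negatives to train on) receive a
  periodic pattern in one descriptor column at `signal["pssm"]`
  (auto-covariance sees lag structure, not column means, so the signal
  must be periodic rather than a constant shift);
* homologs with log-uniform E-values in [1e-30, 1e-2] (spanning the
  weighting regime without modelling extreme-value statistics) carrying
  gold terms at `signal["seq"]`, 15% of hits pushed below the coverage
  threshold as filter decoys.

Each channel covers a domain only with probability 0.7
(`channel_coverage`). This is the deliberate, realistic feature that
makes integration pay: no single channel sees every domain, so each
component's recall is capped while the fused predictor draws on whichever
channels are present. Sizes (60 domains, 150 proteins, 60 terms, 20
neighbors, 4 InterPro entries, 12 homologs per domain, 60-residue
profiles) were chosen once as a desk-scale caricature of the real
databases: large enough for stable LR bins and trainable classifiers,
small enough that the full pipeline runs in seconds.

What the fixture does **not** emulate: real substitution statistics in
PSSMs, sequence evolution linking homology to structure, correlated
errors between channels, and the extreme class imbalance of a full GO
term universe. Passing tests therefore demonstrate correctness of the
computations and the directional benefit of integration, not real-data
performance figures.

In the noiseless limit (signal 1, noise 0) the three counting scorers are
exactly 1 on every covered gold pair; the PSSM channel approaches but
never reaches 1, because a calibrated sigmoid maps finite margins into
(0, 1).

## Numerical choices and degenerate inputs

* Strict `<` at the PSD boundary, strict `>` at the coverage and identity
  boundaries, inclusive `≥` at the posterior cutoff.
* Zero-variance descriptor columns give AC exactly 0; profiles no longer
  than the lag raise an error naming the domain.
* Standardisation guards zero-variance features (sd set to 1); sigmoid
  fitting uses the log1p-based stable cross-entropy and backtracking line
  search, with a tiny ridge (1e-12) on the Hessian.
* Duplicate neighbor/homolog records collapse to min PSD / min E-value;
  readers reject malformed rows with line provenance rather than
  coercing.
* Empty inputs (no neighbors, no homologs, no positives) yield empty
  outputs or explicit errors, never silent zeros; terms below the
  classifier class floor are skipped with a logged reason.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the pipeline at the default
60-domain fixture, validate the counting scorers against nested-loop
oracles at ≤ 50 domains × ≤ 100 terms, recover sigmoid parameters from
2 000 draws and binned LRs from 100 000, all comfortably within a few
minutes on one core — sizes picked as the smallest at which the
statistical recoveries are stable.

## Known limitations

Conditional-independence overconfidence (above); per-aspect rather than
per-term priors; the PSSM channel only models terms with enough training
examples (rare terms rely on the other three channels); predictions are
not re-closed under the true-path rule after fusion (the counting
channels emit closed score sets, but PSSM-only predictions can lack
ancestors); and PSD computation, InterProScan, and PSI-BLAST runs are
explicitly out of scope — their outputs are inputs here.
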
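# domannot

Probabilistic Gene Ontology (GO) annotation of protein structural domains.

A structural domain (a SCOP-style unit such as `d1te0a2`) is the natural
carrier of molecular function, but most annotation resources describe
full-length proteins. `domannot` assigns GO terms to individual domains by
combining four independent evidence channels and reporting, for every
(domain, term) pair, the probability that the annotation is correct. It is
aimed at structural bioinformaticians who have run the standard upstream
tools (structure alignment, InterProScan, PSI-BLAST) and want calibrated
domain-level annotations plus an evaluation harness.

## The model

Four component scorers each produce a probability-like score per
(domain *d*, term *g*):

* **Str** — structural neighbors. Proteins whose structure aligns to the
  domain with protein structure distance PSD < 0.1 are its neighbors;
  `P1(g|d) = P(d,g) / P(d)`, the fraction of neighbor proteins annotated
  with *g*.
* **IPR** — InterPro mapping. With *n* distinct InterPro entries hit by the
  domain sequence, `P2(g) = (1/n) Σᵢ Iᵢ(g)`, the fraction whose
  InterPro2GO entry carries *g*.
* **PSSM** — sequence profile classifier. PSI-BLAST PSSM profiles are
  compressed to fixed-length auto-covariance vectors,
  `AC(j, lag) = 1/(DL−lag) Σᵢ (Xᵢ−X̄)(Xᵢ₊ₗₐ𝓰−X̄)` with lag = 1…10 per
  descriptor column, an SVM is trained per term, and margins are mapped to
  probabilities `P3(g) = 1/(1+exp(A·f(g)+B))` with (A, B) fitted by robust
  sigmoid calibration on out-of-fold margins.
* **Seq** — homolog transfer. Homologs with query coverage > 60% vote with
  weights `wᵢ = (−log Eᵢ + log 10) / Σⱼ(−log Eⱼ + log 10)`;
  `P4(g) = Σᵢ wᵢ Iᵢ(g)`.

The channels are fused by a binned likelihood-ratio naive-Bayes
integrator: per method and GO aspect, scores on labelled calibration pairs
are split into 10 equal-width bins; each bin's likelihood ratio is its
annotation odds over the prior odds (with additive smoothing, and an
"absent" pseudo-bin for pairs the method did not score); at prediction
time `LR = Πᵢ LR_{fᵢ}` and the posterior is
`prior_odds·LR / (1 + prior_odds·LR)`. Evaluation follows the CAFA-style
domain-centric protocol: precision–recall over all score thresholds,
maximum F-measure (Fmax), and coverage of the domain universe, with
optional removal of test domains > 90% identical to training domains.

A synthetic-fixture generator (`generate_fixtures()`) builds a random GO
DAG plus all five input file types with known ground-truth parameters, so
the whole pipeline runs and is tested at desk scale without any database
downloads.

## Worked example

```r
library(domannot)

fx  <- generate_fixtures(fixture_config(seed = 1), "bench")
tr  <- run_train("bench", "bench/models")
summary(tr$tables)
ann <- run_annotate("bench", "bench/models", "bench/annotations.tsv",
                    cutoff = 0)
run_evaluate("bench/annotations.tsv", "bench")
```

prints (abridged):

```
Binned likelihood-ratio table: 4 methods x 3 aspects, 10 bins (+absent), smoothing 1
  MF: prior odds 0.643 (389 pos / 605 neg)
  IPR: LR range 0.0818 - 328 across scored bins
  Str: LR range 0.0152 - 4.04 across scored bins
MF: Fmax = 0.9814 at t = 0.7990; coverage = 1.0000 (60 domains, 132 thresholds)
BP: Fmax = 0.9839 at t = 0.7063; coverage = 1.0000 (60 domains, 137 thresholds)
CC: Fmax = 0.9967 at t = 0.6427; coverage = 1.0000 (60 domains, 132 thresholds)
```

The LR ranges show how informative each channel's bins are (a score in
IPR's top bin multiplies the annotation odds ~328-fold on this fixture);
the per-aspect lines give the integrated annotator's maximum F-measure,
the threshold attaining it, and the fraction of domains receiving any
annotation. The first rows of `bench/annotations.tsv` carry the fused
posterior next to each channel's raw score (NA where a channel had no
evidence):

```
  domain_id       term aspect posterior score_Str score_IPR score_PSSM score_Seq
1   d0001a1 GO:0000045     CC 0.9520220      1.00        NA  0.6219164        NA
2   d0001a1 GO:0000023     BP 0.9370555      0.95        NA  0.9539989        NA
```

A command-line front-end with the same four stages
(`simulate`, `train`, `annotate`, `evaluate`) lives at
`inst/cli/domannot.R`.

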
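---
title: "Classifying LPS-tolerance phenotypes and predicting their regulatory motifs"
author: "MotifTriad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying LPS-tolerance phenotypes and predicting their regulatory motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotifTriad)
```

## The biological problem

Macrophages stimulated with bacterial lipopolysaccharide (LPS) mount a broad
transcriptional response. Under prolonged LPS exposure they become
*tolerant*: a second stimulation fails to re-induce many inflammatory genes
("tolerizable", here **pro-inflammatory**), while genes needed to keep the
infection in check remain inducible or rise further ("non-tolerizable",
here **antibacterial**). MotifTriad implements a complete in-silico pipeline
around this phenomenon:

1. classify genes into the two phenotypes from a three-condition expression
   matrix — untreated (N), 4 h LPS (N+L), and 24 h LPS followed by 4 h
   re-stimulation (T+L), two replicates each;
2. predict the transcription-factor binding motifs that discriminate the
   classified gene set with **three algorithmically independent engines**;
3. intersect the top 70% of each engine's predictions at the level of
   matrix-library accessions;
4. validate the surviving profile TFs against curated target-gene lists, a
   relaxed two-fold expression signature, and (optionally) a second,
   four-condition data set containing the tolerant (T) state.

A seeded synthetic-data generator emulates all four inputs with a
ground-truth manifest, so every stage is testable against planted truth.

## Phenotype classification

For a probe with condition averages $X = \bar N$, $Y = \overline{N{+}L}$,
$Z = \overline{T{+}L}$ and ratios $r_1 = Y/X$, $r_2 = Z/Y$:

* **pro-inflammatory**: $r_1 > 1$, $r_2 < 1$, and Welch $p < \alpha$;
* **antibacterial**: $r_1 > 1$, $r_2 > 1$ (strict), and $p < \alpha$;
* otherwise unclassified (probes with a zero denominator are unclassified
  with a recorded reason).

The significance test is Student's two-tailed t-test assuming
heteroscedasticity (Welch), by default contrasting the naive (N) against
the tolerant-restimulated (T+L) replicates; `contrast = "N_vs_NL"` selects
the naive-versus-first-stimulation contrast instead. Degenerate replicate
groups follow fixed conventions: both groups zero-variance and equal means
give $p = 1$; zero-variance with distinct means gives $p = 0$ (the
$t \to \infty$ limit). No multiple-testing correction is applied by default
(a Benjamini–Hochberg option exists); one-fold boundaries are strict
(`> 1`), matching the filter definition, while the relaxed two-fold
signature (`twofoldSignature()`) uses inclusive `>= 2` boundaries and no
p-value at all. "Gene" counts collapse probes by symbol
(case-insensitively), keeping the probe with the highest overall mean.

**Which contrast for synthetic data?** The generator's planted
pro-inflammatory genes are induced `foldInduction`-fold and repressed
`foldRepression`-fold (defaults 4 and 4), so their tolerized mean returns
*exactly* to baseline. Under that idealization the N-vs-T+L test has
nothing to detect, and the noiseless limit can only be recovered exactly
under the N-vs-N+L contrast; synthetic-bundle analyses in this package
therefore use `contrast = "N_vs_NL"`. Real tolerized genes retain partially
elevated expression, which is what makes the N-vs-T+L contrast informative
on microarray data.

**Detection limits with duplicate arrays.** With two replicates per
condition the Welch degrees of freedom fall toward 1 (the induced group's
variance is ~16-fold larger under 4-fold induction at fixed CV), so even a
4-fold effect at 5% replicate CV is missed in roughly 8% of genes, and the
null false-positive rate for each class pattern is about 1–2% — independent
of the CV, because the t statistic is scale-free. At the default planted
fractions (10% pro, 2% anti) this caps recovery sensitivity and precision
near 0.91 and 0.90 (pro) / 0.78 (anti). These are properties of the
duplicate design itself, not of the implementation; the package reports
them honestly rather than tuning them away.

## Engine 1: de novo discovery by EM under ZOOPS

`discoverMotifs()` fits a two-component finite mixture (motif vs 0-order
background) by expectation–maximization under the *zero-or-one occurrence
per sequence* (ZOOPS) model, scanning both strands. The E-step computes
per-offset and per-strand posterior site probabilities together with the
per-sequence occurrence posterior; the M-step re-estimates the probability
columns (pseudocount 0.1) and the occurrence prior $\gamma$. The objective
is asserted non-decreasing at every iteration; because the M-step is
Dirichlet-regularized, the monotone quantity (and the stored trace) is the
penalized log-likelihood. Masked (`N`) positions carry no likelihood and
can never be sites. Starting points are seed subsequences (up to
`nStarts`, seeded RNG), each burned in for three iterations; the three
best are run to convergence, and the two best convergence points are
*phase-refined* — re-run after ±1 column shifts, adopting a shift when it
improves the objective — since EM converges readily to column-shifted
optima. The whole fit is deterministic given the seed.

Motifs are extracted sequentially: after each fit, the best site per
sequence with posterior > 0.5 is hard-masked before the next round. Widths
are chosen per motif over a candidate grid (default {6, 8, 10, 12, 15},
bounded by a maximum width of 15) by the best E-value, ties broken by
higher log-likelihood ratio.

**E-value.** There is no closed form for this model's significance, so the
package uses a Monte-Carlo calibration: the fitted motif's log-likelihood
ratio is re-scored on `nShuffles` dinucleotide-preserving
(Altschul–Erickson) shuffles of the input and

$$E = \frac{1 + \#\{\mathrm{LLR}_{\mathrm{shuffled}} \ge \mathrm{LLR}\}}{n_{\mathrm{shuffles}} + 1}\times n_{\mathrm{widths}},$$

with an honest attainable floor of $n_{\mathrm{widths}}/(n_{\mathrm{shuffles}}+1)$.
E-values are comparable within an engine run, which is all the consensus
step requires. The shuffled replicates are generated once per discovery run
and shared across widths and rounds (deterministic given the seed).

## Engine 2: transcription contribution score (TCS)

`runTCS()` regresses a per-gene expression response (default
$\log_2(\overline{T{+}L}/\overline{N{+}L})$, the contrast the phenotype
turns on) on motif occurrence counts in the promoters, over many seeded
random subsets of a motif universe. Each sampled motif accumulates its
absolute standardized coefficient $|b|\,\mathrm{sd}(x)/\mathrm{sd}(y)$;
its TCS is the accumulation divided by the number of times it was sampled
(`tcs_normalization = "mean"`, removing sampling-frequency bias; `"sum"`
is available). The least-squares sign labels each motif stimulatory or
inhibitory. Occurrences are counted overlapping, once per strand; PWM
motifs count windows scoring at least 80% of the matrix's maximum log-odds.
The universe is either all fixed-size words (default $k = 8$) present in at
least 3 promoters, or a supplied PWM library — the pipeline default, which
keeps TCS scores directly accession-addressable. Singular designs fall back
to ridge ($\lambda = 10^{-6}\,\mathrm{tr}(X^TX)$, flagged); constant
predictor columns are confounded with the intercept and reported as 0.

## Engine 3: affinity–specificity association

`associateTF()` ranks genes by an occupancy-style promoter affinity,
$\sum_{\mathrm{windows,\ strands}} e^{\mathrm{log\text{-}odds}}$ (the
$\beta = 1$ thermodynamic limit, 0-order background), and independently by
a condition-specificity score (default $\log_2(\overline{N{+}L}/\bar N)$).
The two rankings are associated by the *iterated hypergeometric test*: for
every pair $(i, j)$ of rank cutoffs in a grid (default
{5, 10, 20, 50, 100, 200}), the overlap $k$ of the top-$i$ affinity genes
with the top-$j$ specificity genes is scored by $P(X \ge k)$ under the
hypergeometric law, and the minimum over the grid is reported, uncorrected
(an optional Bonferroni-by-grid-size correction is off by default, matching
the convention that a lower minimum p simply ranks a better association).
Ranking ties break lexicographically by gene identifier, making the engine
deterministic and invariant to monotone transforms of either score.

## Consensus across engines

Each engine's predictions are reduced to their best 70%
($\lceil 0.7 n \rceil$ with boundary ties included — the inclusive choice
favors recall ahead of the strict intersection). De novo motifs are mapped
to library accessions with an ungapped TOMTOM-like comparator: mean Pearson
correlation of aligned probability columns over all offsets with at least 4
aligned columns, both orientations; best hit at similarity ≥ 0.75 wins,
uniform columns contribute 0, and motifs mapping to the same accession
merge keeping the best E-value. Mapping precedes the top-70% cut. The
consensus is the set of accessions present in all three retained sets.
`contrastTestVsRandom()` pairs each consensus accession's per-engine scores
with those from a random-gene companion run (`runRandomBackground()`:
seeded sample of unclassified genes, uniform random responses within the
test genes' range), marking accessions the random run did not retain as
absent.

## Validation against curated targets

`validateTargets()` intersects the curated TF→target lists (shipped
fixture: the published table of biologically validated targets of the
pro-inflammatory profile TFs) with the two-fold signature,
case-insensitively; computes relative expression profiles normalized to the
single largest N-condition average of the *full* matrix; optionally runs
the four-condition cross-dataset check — tolerizable iff
$(N{+}L)/N > 1$ and $(T{+}L)/T < (N{+}L)/N$, both strict — and a
random-gene-set null (`randomGenePatternNull()`). On a signature built from
the same matrix at the same threshold, overlap membership already implies
the pattern, so `pattern_pass_count == overlap_count` there; the counts can
differ only across matrices or thresholds, which the cross-dataset check
exercises. Gene matching across data sets uses uppercase symbol equality
only — no ortholog or alias resolution — so synonym spellings in curated
tables (e.g. "Importin beta" vs Kpnb1) count as distinct strings, and the
deduplicated target-universe size is reported without asserting a
particular value.

## The synthetic study generator

`generateBundle()` emulates the study's inputs under one master seed:

* **Expression** — lognormal baselines (meanlog $\log 200$, sdlog 1);
  planted pro genes induced 4-fold then repressed 4-fold, planted
  antibacterial genes induced 4-fold then escalated 1.5-fold, null genes
  flat; two replicates per condition with multiplicative lognormal noise at
  5% CV. Lognormal multiplicative noise is the natural choice for
  intensity-scale array data and keeps effect sizes interpretable as fold
  changes.
* **Promoters** — 1301 nt (−1000..+300 around the TSS), i.i.d. uniform
  composition; the planted width-10 PWM (0.85 consensus probability per
  column) is inserted into 60% of pro-class promoters at a random
  non-overlapping offset and strand; repeat masking is emulated as `N` runs
  (10–50 nt) in 10% of promoters.
* **Library** — the planted matrix plus eight decoys built by permuting
  letters within columns and shuffling column order of the planted matrix:
  the decoys match its information content *exactly*, so planted-vs-decoy
  discrimination cannot come from motif strength alone.
* **Targets** — the planted TF paired with a random 70% of the genes that
  actually carry its plants, plus a decoy TF with targets drawn from null
  genes.

Everything is recorded in a manifest (classes, plant coordinates, target
lists), and bundle files are byte-identical across runs with the same seed.
What the generator does **not** emulate: probe-level artifacts,
normalization effects, correlated biological variation between conditions,
promoter GC structure, or co-occurring motif grammar. Passing tests on this
generator therefore demonstrate algorithmic correctness and end-to-end
recoverability of a planted signal, not performance on real arrays.

## Problem sizes and numerical choices

The package's reference synthetic experiment uses 1000 genes, 10% planted
pro class, insertion probability 0.6, 8 decoys, and ten seeds; on it the
pipeline runs with the desk-scale engine settings `nMotifs = 4`, width grid
{8, 10, 12}, 12 EM starts, TCS over the 9-matrix library (subset 5,
200 iterations), and the default affinity grid. These sizes are the
package's own choice of a reproducible reference experiment; all engine
parameters are exposed and default to the larger document values
(`nMotifs = 30`, widths up to 15) for real analyses.

Numerical conventions worth knowing: EM likelihoods are computed in plain
double precision (window log-odds are bounded by the 1e-3 background floor,
so no log-sum-exp shifting is needed); EM convergence is an absolute
log-likelihood improvement below `tol` (default 1e-3 in discovery); the
uniform-column Pearson correlation is defined as 0; rank ties break
lexicographically; random-set sampling is without replacement within a set;
and every stage takes an explicit named seed so engines can be re-run in
isolation.

## Known limitations

* Duplicate-array Welch testing caps classification sensitivity/precision
  (see above); with real data the study-scale counts depend on the
  deposited arrays' noise structure.
* The Monte-Carlo E-value has a floor of
  $n_{\mathrm{widths}}/(n_{\mathrm{shuffles}}+1)$; strong motifs tie at the
  floor and are then ordered by log-likelihood ratio.
* TCS values are comparable within a run, not across tools; only the
  test-versus-random ordering is meaningful.
* One planted PWM per bundle is supported; multi-TF grammars are out of
  scope for the generator.
* Low-complexity input defeats de novo discovery under a 0-order
  background: in, say, a poly-T context the T/A homopolymer is the true
  likelihood optimum and will out-score any planted word — which is
  precisely why promoter inputs are repeat-masked upstream.
* Sequential extraction can merge two planted words that share a 3–4 nt
  core into one hybrid motif whose erasure destroys both; this is inherent
  to erase-and-repeat strategies.

## A worked example

```{r example, eval = FALSE}
cfg <- syntheticConfig(seed = 1)
bundle <- generateBundle(cfg, dir = "bundle")
run <- runPipeline("bundle", config = list(
  contrast = "N_vs_NL",
  discovery = list(nMotifs = 4, widths = c(8, 10, 12))))
run$consensus          # accessions surviving all three engines
run$validation         # overlap with the curated target lists
bg <- runRandomBackground(run)
bg$contrast            # test-vs-random score table
```
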
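# MotifTriad

Macrophages exposed to lipopolysaccharide (LPS) for a prolonged period
become *LPS-tolerant*: on re-stimulation, many inflammatory genes are no
longer induced (tolerizable, "pro-inflammatory") while antibacterial
effectors stay inducible (non-tolerizable). MotifTriad is an R package for
researchers studying this switch: it classifies genes into the two
phenotypes from three-condition expression data and predicts the
transcription-factor binding motifs that discriminate them by intersecting
three algorithmically independent engines.

## The method in brief

Given condition averages $X=\bar N$ (untreated), $Y=\overline{N{+}L}$
(4 h LPS) and $Z=\overline{T{+}L}$ (24 h LPS + 4 h re-stimulation):

* **pro-inflammatory**: $Y/X>1$, $Z/Y<1$, Welch $p<0.05$;
* **antibacterial**: $Y/X>1$, $Z/Y>1$, Welch $p<0.05$.

Promoters (−1000..+300 of the TSS) of the classified set are then analyzed
by:

1. **de novo discovery** — EM on a two-component mixture under the ZOOPS
   (zero-or-one occurrence per sequence) model, both strands, sequential
   extraction, Monte-Carlo (dinucleotide-shuffle) E-values;
2. **TCS** — iterated least squares of an expression response on motif
   occurrence counts over random motif subsets, accumulating a
   transcription contribution score per motif with a
   stimulatory/inhibitory sign;
3. **affinity association** — occupancy-style promoter affinity ranking
   versus condition-specificity ranking, scored by the minimum
   hypergeometric tail over a grid of rank-cutoff pairs.

The top 70% of each engine's predictions (de novo motifs mapped to library
accessions by a column-correlation comparator) are intersected; consensus
TFs are validated against curated target lists, a relaxed two-fold
signature, random-gene nulls, and optionally a second four-condition data
set. A seeded synthetic-data generator with a ground-truth manifest stands
in for the microarray, promoter, TRANSFAC-style library and curated-target
inputs.

## Worked example

```r
library(MotifTriad)

cfg <- syntheticConfig(seed = 1)          # 1000 genes, 10% pro, 2% anti
bundle <- generateBundle(cfg, dir = "bundle")
run <- runPipeline("bundle", config = list(
  contrast = "N_vs_NL",
  discovery = list(nMotifs = 4, widths = c(8, 10, 12))))
print(run)
```

```
PipelineRun (pro gene set, 98 genes)
  consensus accessions: DC0006, PL0001
  validation overlap: 45 genes
```

`PL0001` is the planted matrix recovered by all three engines (`DC0006` is
a decoy that survived the per-engine 70% cuts by chance); the validation
overlap is the set of curated target genes that carry the two-fold
pro-inflammatory expression pattern. `run$consensus` holds the per-engine
scores (E-value, TCS, association p) for each consensus accession, and
`runRandomBackground(run)` produces the test-versus-random score contrast.

With real data, replace the bundle files with an expression TSV
(`probe_id`, `gene_symbol`, sample columns `N_1 ... TL_2`), a promoter
FASTA, a TRANSFAC-style matrix library and a TF→target TSV; the curated
target table for the pro-inflammatory profile TFs ships in
`inst/extdata/profile_tf_targets.tsv`.

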
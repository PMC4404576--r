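---
title: "Testing miRNA-family target over-representation in gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing miRNA-family target over-representation in gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirenrich)
```

## The model

A miRNA family is a group of miRNAs sharing a seed, hence a common set of
predicted target genes. Given a non-ranked gene set — typed in directly or
derived from ChIP-seq peaks of a transcription factor — the question is
whether the predicted targets of any family are over-represented in it.

The reference for "expected" is the **background**: all unique
(family, gene) pairs from a conserved-site prediction table, with
predictions pooled across all isoforms of a gene. Genes with no predicted
3'UTR site at all are outside the background and are removed from the input
set before testing; the retained size is called *N*. Only *N* between 20 and
4000 (both inclusive) is analysed: below that the randomization is
uninformative, above it the factor binds so broadly that enrichment loses
meaning (and the simulation cost grows).

For family *A* the observed statistic is the target count $m_A$ in the set,
with total $T = \sum_A m_A$. The null is simulated: each repetition draws
*N* genes uniformly without replacement from the background universe, giving
counts $z_A$ and total $T'$. The comparison is made on the **scaled** count
$z_A \cdot T / T'$. This one-number correction absorbs gene-set-level
confounders that inflate all families at once — the canonical one being
average 3'UTR length, since longer UTRs accumulate more predicted sites for
every family. A repetition is a "success" for *A* when the scaled count
reaches $m_A$, and

$$p_A = \frac{1 + \#\{\text{successes}\}}{R + 1},$$

followed by Benjamini–Hochberg adjustment across all families in the
background and two inclusive cutoffs: FDR at most the chosen threshold and
$m_A \ge \lceil (\text{min target pct}/100) \cdot N \rceil$.

Assumptions worth stating: the prediction table is treated as ground truth
(no site-level scoring is used); the uniform draw over the background
universe is the null, so any structure in the universe other than total
target density (e.g. GC content, conservation depth) is not matched; and
families are tested jointly against the *same* random sets per repetition,
which preserves their correlation structure in the null.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `n_reps` | 10000 | repetitions | resolution of $p$ is $1/(R+1)$; the menu 1000/10000/100000 trades resolution against time |
| `fdr_cutoff` | 0.05 | probability | inclusive call threshold; the interface constrains it to [0.005, 0.2] |
| `min_target_pct` | 0 | % of *N* | optional guard against families called on a handful of targets |
| `min_n`, `max_n` | 20, 4000 | genes | inclusive bounds on *N*; overridable in the library so tiny universes can be tested |
| `window_kb` | 10 | kb | nearest-TSS association window; menu 5/10/20 |
| `promoter_upstream/downstream` | 1000/500 | bp | strand-aware core-promoter window of the ranked method |
| `seed` | none | — | single seed; identical config + seed gives byte-identical outputs |

## Peak-to-gene association

Peaks are reduced to their interval midpoint, a choice that needs only BED3
input (no summit column) and is symmetric in the peak. The **nearest**
method assigns the midpoint to the gene with the closest strand-aware TSS on
the same chromosome if the unsigned distance is within the window; distance
ties go to the smaller gene id so results are deterministic. The **ranked**
method expresses the biology that factor binding concentrates in core
promoters and first introns: promoter membership outranks first-intron
membership, and within a rank the nearest TSS wins. The exact ranked scheme
is this package's own reconstruction of that idea — the promoter window
bounds and the promoter-over-intron priority are explicit, configurable
choices rather than recovered constants. When a gene-model table carries
several transcripts per gene, the longest span is the representative, so
each gene has exactly one TSS. With two or three peak files, a gene enters
the analysis set only when at least two distinct files put a peak near it;
several peaks from one file count once.

Around a master regulator two loop topologies are flagged: over-represented
families with a predicted site on the master itself (feedforward loop of
type 2), and miRNA genes with a master peak midpoint within the window of
their locus (candidate negative feedback). Feedback distance is measured to
the locus *interval* (zero inside, else gap to the nearest edge), unlike the
TSS-point convention for protein-coding genes, because a miRNA gene has no
meaningful single reference point at these scales. Regulatory sign is not
inferred, so coherent versus incoherent feedforward labelling is left to the
user.

## Numerical choices

* **Comparison rule.** A repetition counts against significance when
  $z_A \cdot T/T' \ge m_A$: equality is conservative. The scaled count is
  compared as a real number — rounding it would quantize small backgrounds.
* **Estimator.** The add-one form $(1+s)/(R+1)$ keeps $p > 0$, so
  downstream $\log$ transforms and BH behave; $p_A = 1$ exactly whenever
  $m_A = 0$.
* **Ratio per repetition.** $T'$ is that repetition's own total; a random
  set with no targets at all defines a ratio of 0, so it cannot count
  against a family with $m_A > 0$.
* **Degenerate inputs.** All-zero observed counts give all $p = 1$, not an
  error; an empty prediction table, an empty gene-model table and an empty
  miRNA-locus table are errors; unmappable identifiers and
  transcript-resolution failures are reported, never fatal.
* **Determinism.** One seed drives everything; the repetition loop draws
  sequentially so chunk size cannot change the stream.

## What the simulator emulates — and what it does not

`simulate_background()` plants each (family, gene) pair independently with
probability `base_density`, multiplied by `bias_factor` for a "long-3'UTR"
fraction of genes. Because the test only ever sees counts, a density
multiplier is the minimal faithful model of the UTR-length confounder; no
sequences, conservation scores or binding energies are simulated. Gene
models sit ≥ 100 kb apart on one synthetic chromosome so window tests are
unambiguous; peak fixtures place intended hits within the window and noise
at twice the window from every TSS. `simulate_gene_set()` mixes a planted
family's targets into an otherwise uniform draw with weight
`enrichment_prob` (0 = null, 1 = pure spike).

Passing tests on these fixtures therefore demonstrate the statistical
machinery — calibration, power on a planted signal, the confounder
correction, deterministic bookkeeping — but not robustness to properties of
real prediction data the generator does not model: correlated target sets
between families with overlapping seeds, heavy-tailed per-gene site counts,
annotation errors, or peak shapes. Real analyses also face identifier-era
mismatches the toy idmap cannot show.

The fixture sizes used by the test-suite and the acceptance script are the
package's reference conditions: an 8-gene/3-family universe with $N = 4$
(small enough to enumerate all $\binom{8}{4} = 70$ subsets exactly), a
200-gene/20-family background with 500 null sets of $N = 30$ at 1000
repetitions for calibration, the same background for a 30-gene pure spike at
10000 repetitions, and a `bias_factor = 2` background for the correction
contrast. At these sizes the whole suite runs in well under a minute of
simulation time.

## Design choices in open territory

Several details of the original web-tool behaviour are not documented
anywhere; this package fixes them explicitly:

* *N* bounds are **inclusive** (20 and 4000 both run).
* One-to-many symbol-to-Entrez mappings contribute **all** targets, with a
  message, rather than silently dropping an ambiguous token.
* Rows are kept when their conservation flag is in a configurable accepted
  set (default `conserved`, `broadly conserved`).
* The p-value estimator, the non-strict comparison, and the per-repetition
  ratio (rather than one ratio pooled across repetitions) are declared
  choices, mirrored exactly by the enumeration oracle in the tests so the
  check is rule-consistent.
* Whether the boundary of the association window is inclusive matters only
  on exact ties at base-pair resolution; `distance <= window` is used
  throughout.

## A worked run

```{r example}
sim <- simulate_background(n_genes = 200, n_families = 20,
                           base_density = 0.2, seed = 11)
bg  <- build_background(sim$predictions, sim$idmap)
set <- simulate_gene_set(bg, target_family = "miR-05", n_set = 30,
                         enrichment_prob = 1, seed = 12)
fit <- mir_enrich(set$genes, bg, n_reps = 10000, seed = 13)
tidy(fit)
glance(fit)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(fit)
```

## Limitations

The test is one-sided (over-representation only); under-representation,
ranked-list input, and enrichment against functional annotation databases
are out of scope. The scaling correction is a single global factor: it
neutralises set-wide density shifts but cannot fix family-specific biases
(e.g. a family whose sites are preferentially predicted in a GC-rich
subset of the genome). Finally, everything rests on the prediction table:
with a different TargetScan release the family set, the universe and hence
every number change, which is why the package treats that table as an
explicit input rather than shipping one.
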
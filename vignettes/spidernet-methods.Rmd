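---
title: "Methods: epigenetically seeded network inference by message passing"
author: "spidernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetically seeded network inference by message passing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidernet)
```

## The problem

A gene regulatory network summarizes which transcription factors (TFs)
regulate which genes. Sequence motifs predict where a TF *could* bind, but
most motif matches are not bound in a given cell type, and some genuine
binding happens with no recognizable motif at all (for example, when a TF
is recruited by a cofactor). Chromatin accessibility assays (DNase-seq,
ATAC-seq) say which genomic regions are open to binding, but not who binds
them. `spidernet` implements the SPIDER approach: combine the two sources
into a sparse, epigenetically informed *seed* network and then let a
message-passing refinement exploit the global structure of that seed to
score *every* TF–gene pair — including pairs with no motif evidence.

## Seed construction

For each TF we take its motif locations (BED intervals), keep only those
overlapping an open-chromatin peak by at least one base, and intersect the
survivors with gene *regulatory windows*. The default window is a 2 kb
interval centered on each transcriptional start site (TSS); a distal mode
instead places a pair of 5 kb windows at a configurable offset (the
default 20–25 kb up- and downstream probes enhancer-range signal). An edge
TF→gene is created when any surviving motif falls in any window of the
gene; its weight is the maximum motif score over those instances, which is
1 in the default pipeline (every surviving site is scored one), so the
seed is binary. Omitting the open-chromatin input gives the
epigenetically *naive* seed used as a baseline.

Coordinate conventions: BED 0-based half-open throughout; overlap means at
least one shared base; intervals that merely touch do not overlap but
*are* unified by `mergeOverlapping` (the composite-ChIP convention of
`bedtools merge`). Strand is ignored everywhere: both window modes are
symmetric about the TSS, so strand could not change placement, and
intersections are strand-blind. Genes with several annotated TSSs get one
window per TSS and the gene's regulatory region is their union. Windows
running past the chromosome start are clipped at zero with a warning.
Chromosome-name dialects ("chr1" vs "1") are never silently reconciled;
`checkChromosomeCompatibility` reports inputs whose name sets do not
intersect.

## Degree normalization

Let $A$ be the $N_{TF} \times N_G$ seed matrix,
$k_i^{TF} = \frac{1}{N_G}\sum_j A_{ij}$ and
$k_j^{Gene} = \frac{1}{N_{TF}}\sum_i A_{ij}$ the average degrees. The
normalized seed is

$$A^*_{ij} = A_{ij}\sqrt{(k_i^{TF})^2 + (k_j^{Gene})^2}.$$

High-degree TFs and genes sit in more open chromatin and are more likely
to be genuinely active, so their edges are up-weighted; zero entries stay
zero. The degrees are computed on whatever $A$ holds, so non-unit motif
scores propagate through the same formula.

## Message passing

The refinement harmonizes three matrices: the regulatory network $W$
(set to $A^*$), a TF–TF cooperativity prior $P$ and a gene–gene
co-regulation prior $C$ (both set to the identity here; arbitrary priors
are accepted). All three are first normalized entrywise by the two-way
Z-score

$$X^{(0)}_{ij} = \tfrac{1}{\sqrt2}\Big(\tfrac{X_{ij}-\mu_i}{\sigma_i} +
  \tfrac{X_{ij}-\mu_j}{\sigma_j}\Big),$$

with $\mu,\sigma$ over row $i$ and column $j$. A row or column with zero
variance contributes zero for its term — the dense seed necessarily
contains all-zero rows/columns and this guard keeps them finite. The
standard deviation uses the sample ($n-1$) convention by default
(`std_mode` switches to population); all frozen test values state their
mode.

Similarity between a row vector $\vec x$ and a column vector $\vec y$ is
the continuous Tanimoto form

$$\mathcal T(\vec x,\vec y) =
  \frac{\vec x\cdot\vec y}
  {\sqrt{\lVert\vec x\rVert^2 + \lVert\vec y\rVert^2 -
   |\vec x\cdot\vec y|}},$$

so $\mathcal T(\vec x,\vec x) = \lVert\vec x\rVert$; the denominator can
vanish only for a pair of all-zero vectors, where the similarity is
defined as 0. Each iteration moves $W$ a step of size $\alpha$ toward the
average of the cooperativity message $\mathcal T(P, W)$ and the
co-regulation message $\mathcal T(C, W^\top)^\top$, then re-estimates $P$
and $C$ from the updated $W$ as the similarity of its rows (shared
targets) and columns (shared regulators), blended with the same step size.
With identity priors the first $P$ update is exactly a normalized count of
shared targets between TF pairs, which is how an edge with no motif
evidence can inherit weight from its co-regulators on later iterations.

**Diagonal stabilization.** Applied literally, the $P$/$C$ updates
diverge: the Tanimoto self-similarity grows with vector norms, so each
round feeds larger values back into $W$ and the weights explode
geometrically (about $10^{20}$ within a hundred iterations at fixture
scale, with no convergence). The reference implementations of this
message-passing family therefore replace the diagonal of each updated
similarity matrix with
$n\,e^{2\alpha t}\,\mathrm{sd}(\text{off-diagonal column entries})$ at
step $t$. The exponentially growing self-similarity dominates the
Tanimoto denominators, progressively damping the updates and forcing
convergence, and it reproduces the intended Z-score-like scale of the
final weights. `spidernet` adopts this convention as the default; setting
`update_diagonal = FALSE` in `messagePassingConfig()` recovers the
literal updates for study (a test documents the divergence).

Convergence is declared when the mean absolute element-wise change of $W$
drops below `tol` (default $10^{-3}$), with a cap of 100 iterations; both
are configuration, since no printed stopping rule exists to match
bit-exactly. On the default fixture the iteration converges in roughly
25–30 steps. $\alpha$ defaults to 0.1; $\alpha = 0$ is accepted for
testing and is an exact fixed point after normalization.

## Evaluation

Gold standards are built from per-TF ChIP-seq peaks: replicates are merged
into one composite set, then intersected with the same regulatory windows
as the seed (edge = 1 iff any merged peak hits any window of the gene).
Benchmarking restricts prediction and gold standard to their common TFs
and evaluates *all* edges of that subnetwork — 19 common TFs against
27,090 genes gives exactly 514,710 evaluable edges.

* **AUC** uses the midrank Mann–Whitney convention, so binary or
  three-valued scores trace piecewise-linear ROC chords (the differential
  seed ROC is exactly three segments) and any strictly monotone transform
  of the scores leaves it unchanged.
* **AUPR** integrates the precision–recall curve trapezoidally over the
  ranked predictions. Binary scores make the curve degenerate, so a
  seeded Gaussian jitter ($\sigma = 0.05$ by default) is added once per
  evaluation before ranking; the jitter seed is part of the evaluation
  call, making the value reproducible. The uninformative baseline is the
  positive fraction.
* **Differential analysis** subtracts two binary networks of the same
  shape, giving classes $+1$ (specific to context A), $-1$ (specific to
  B) and $0$ (identical); evaluation scores $+1$ against $-1$ gold edges
  and excludes the identical ones, restricted to TFs assayed in both
  contexts. The procedure is antisymmetric: swapping the contexts negates
  scores and swaps labels, leaving the AUC unchanged.
* **Thresholding** for comparisons with unweighted external networks
  keeps either the top fraction of weights (ties broken by descending
  weight, then TF and gene axis order) or weights above a cutoff; the
  density default should be matched to the gold standard's density, which
  is this package's stand-in for protocols that are not published in
  detail.

## Hidden interactions

Refined edge weights behave like Z-scores, so edges absent from the seed
(weight exactly 0 there) are converted to upper-tail normal probabilities
and corrected by Benjamini–Hochberg over exactly that candidate set;
edges with $q$ below the FDR threshold (default 0.05) are reported with
the attained weight cutoff and a per-gene tally. The tail direction is a
deliberate choice: a lower-tail conversion would make *large* weights
non-significant, contradicting the fact that reported weight cutoffs for
significance sit far in the upper tail (a weight of 4.64 maps to an
upper-tail $p = 1.74\times10^{-6}$). Under a pure null (all-zero seed,
i.i.d. standard-normal weights, $10^5$ edges) the selection is empty or
nearly so, as expected for step-up control.

## The synthetic generator

`generateFixture()` emulates the statistical structure the method
exploits, not the genome. One synthetic chromosome carries `n_genes` TSSs
at a regular spacing (default 5 kb, validated to exceed the window span
so windows never overlap). TFs are assigned round-robin to `n_modules`
co-regulatory modules; each module draws a target-gene set (default a
quarter of the genes) and truth edge ⇔ module membership. Each true edge
emits one 10 bp motif in a TF-specific 50 bp slot of the gene's window —
slots keep peaks from leaking onto a neighbour's site — unless dropped
with probability `motif_dropout` (default 0.2), which creates the planted
*hidden* edges: true edges with no motif anywhere in the gene's windows.
Open-chromatin peaks cover each emitted true-edge motif with probability
$1 -$ `chromatin_closed_frac` (default 0.1). Decoy in-window motifs in
permanently closed chromatin (rate 0.02 per non-edge) give the naive seed
false positives that the epigenetic filter removes, and a handful of
intergenic motifs per TF exercise the window intersection. ChIP peaks
cover true-edge windows at rate $1 -$ `chip_fnr` and non-edges at
`chip_fpr` (both default 0, the noiseless gold standard). The bundle is a
deterministic function of `rng_seed`, and the noiseless setting closes the
loop exactly: seed = gold = truth.

Default scale is 20 TFs × 200 genes with 4 modules. That size runs the
full four-network benchmark in a few seconds and leaves roughly two
hundred planted hidden edges, enough for stable rank statistics; the
paired-fixture differential (half the modules shared) uses the same
scale. These sizes are the package's chosen study conditions and all
reported numbers in the README were computed at them.

What the generator does **not** emulate: realistic peak-width and
motif-score distributions, GC/sequence composition (there are no
sequences at all), overlapping or nested regulatory windows, chromosome
heterogeneity, and the extreme class imbalance of genome-scale gold
standards (fixture positives run ~25% versus ~16% at atlas scale).
Passing fixture tests therefore demonstrates correctness of the
machinery and the qualitative recovery behavior — refined networks
beating their seeds, hidden edges outranking non-edges — not
genome-scale accuracy figures.

## Numerical choices and degenerate inputs

* Zero-variance rows/columns contribute zero in the Z-score transform;
  all-zero vector pairs have similarity 0.
* The Tanimoto denominator is clamped at zero before the square root to
  absorb floating-point cancellation.
* Ties: AUC uses midranks; thresholding and top-k edge lists break ties
  by descending weight, then TF axis order, then gene axis order — fully
  deterministic.
* Windows clipped at coordinate 0 keep their overhang truncated rather
  than shifting; empty post-clip windows are dropped.
* Single-class gold rows are reported as not-evaluable per-TF rather than
  erroring the whole evaluation; the global AUC errors on single-class
  labels, naming the degenerate class.
* Networks are dense doubles over the declared universes; at the default
  scales every matrix involved is small (the largest object in message
  passing is the $N_G \times N_G$ co-regulation matrix).

## Known limitations

* The exact final weights depend on the convergence tolerance and the
  diagonal-stabilization schedule, so only structural properties (ranks,
  AUCs, recovery orderings) are comparable across implementations —
  bit-exact agreement with other software is not a goal.
* Identity priors are the only priors constructed here; arbitrary $P$/$C$
  matrices are accepted but deriving them (PPI, co-expression) is out of
  scope.
* No motif scanning, genome sequence handling, or liftover: inputs are
  pre-scanned interval files.
* The AUPR jitter makes binary-seed AUPR values reproducible only
  together with their seed; AUC is unaffected by design.
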
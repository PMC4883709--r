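---
title: "Expression-weighted motif discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted motif discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mama)
```

## The problem and the model

Short cis-regulatory elements (typically 8 bp or less) are hard to find in
higher eukaryotes: promoters are long, elements are fuzzy, and the usual
prerequisite — clustering genes by expression so that a motif finder can look
for what the cluster shares — fails when a regulatory cascade spreads one
signal across genes that do *not* share a single common element. This package
implements a clustering-free alternative: every 8-bp candidate sequence drawn
from the promoters of the most strongly up-regulated genes is scored directly
against *all* genes, weighting each gene's contribution by how similar its
promoter is to the candidate.

For a candidate $c$ and gene $n$ the similarity `h_score` is computed on every
ungapped window of length 8 on both strands of the promoter, and the best
window wins. A window comparison decomposes into maximal exact-match runs
$h_1, \dots, h_x$ separated by mismatch stretches $d_{1,2}, \dots, d_{x-1,x}$,
and scores

$$ h = \Big\{ \sum_x h_x! \;+\; \sum_{x<y} \frac{h_x h_y}
   {\prod_{k=x}^{y-1} (\hat a\, d_{k,k+1} + 1)} \Big\}^{\nu}. $$

The factorial makes uninterrupted identity dominate (a perfect 8-bp match
scores $8! = 40320$, two 4-bp halves considerably less), the cross terms
reward several shorter identities close together, and the gap penalty
$\hat a$ discounts cross terms by the mismatch distance between runs. The
exponent $\nu$ sharpens or flattens the similarity's influence.

The candidate's score is then the similarity-weighted average of transformed
expression ratios over all genes:

$$ \mathrm{score}(c) = \frac{\sum_n h(n)\, r(n)^{\tau}}{\sum_n h(n)}, $$

where $r(n)$ is the treatment/control ratio, transformed by a down-regulation
policy (ratios below 1 are set to 1 by default), capped at
`highest_r_score` (default 10), and raised to $\tau$. A candidate found
mostly near strongly induced genes inherits a high weighted mean; a candidate
spread indifferently across the genome collapses toward the global mean
ratio. If every gene has the same capped ratio $c$, every candidate scores
exactly $c^\tau$ — the score carries no information without expression
contrast, which is the intended degenerate behaviour.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nu` | 1 | power on the window similarity; higher values make near-exact matches dominate |
| `tau` | 1 | power on capped ratios; higher values emphasize strongly induced genes |
| `a_hat` | 1.0 | gap penalty per mismatch between runs; each gap contributes a factor $\hat a d + 1$ |
| `highest_r_score` | 10 | ratio cap; suppresses noise from extreme ratios at low signal |
| `down_policy` | set_to_one | down-regulated genes: clamp to 1, remove, or use the reciprocal |
| `top_k` | 50 | number of top up-regulated genes from which candidates are enumerated |
| `top_fraction` | 0.05 | fraction of ranked candidates eligible to seed motif groups |
| `max_mismatch` | 2 | Hamming radius for group membership (≥ 6/8 identity) |
| `up_threshold` | 2.0 | ratio above which a gene is a positive (up-regulated) example |
| `ru` | 1/16 | fraction of negative training examples kept by undersampling |

The source method never published the $\hat a$ it used; 1.0 is the minimal
choice that makes each gap factor equal $d + 1$, and it is exposed as
configuration. Because of that gap, externally reported score tables are not
exactly recomputable by any reimplementation, which is one reason the test
surface here is property-based rather than value-matching.

## Grouping, scanning, and co-localization

Ranked candidates are walked in score order. A candidate inside the top
`top_fraction` that no earlier group absorbed becomes a seed; every
lower-ranked, still ungrouped candidate within Hamming distance 2 (forward
orientation, fixed length) joins it. Groups are therefore disjoint and
deterministic given the ranking; ties in score break lexicographically.
Reverse complements are *not* merged at grouping time — scores are strand
symmetric, so both orientations surface on their own, and scanning later
searches both strands anyway.

A grouped motif "occurs" in a promoter when any member matches exactly on
either strand (the hit is anchored by its 5'-most base, half-open
accounting). This exact-match convention, rather than a PWM threshold,
follows from the way groups are built: members are themselves observed
candidates. Position-count matrices are descriptive output (logos, MEME
export), never a scanning model.

Pairwise co-localization is evaluated in the window (−500, +150) around the
TSS. For motifs A and B the eight contingency cells split presence of each
motif by the up-regulation label. The chi-square statistic compares the four
UP cells against expectations scaled from the corresponding non-UP cells,
$E_i = N(\mathrm{UP})\, O_i^{\neg\mathrm{UP}} / N(\neg\mathrm{UP})$, with 3
degrees of freedom (four cells, expectations derived externally — only the UP
cells enter the sum, since the non-UP cells *are* the reference). Two
conditional enrichments gate pair selection: EN1 contrasts presence of A with
and without B among up-regulated genes, EN2 contrasts A-with-B between up-
and non-up-regulated genes; both must exceed 1. A zero dividing rate yields an
infinite enrichment and is treated as enriched; a zero cell-count denominator
(e.g. no up-regulated gene contains B at all) makes the pair untestable.
Pairs whose member sets intersect are never evaluated. Signed separations
(every co-occurring hit pair, not only nearest neighbours) are histogrammed
in 50-bp bins centered on multiples of 50.

## The expression simulation

Motif and pair presences become binary features; genes with ratio above 2 are
positive examples. Genes are split 50/50 (stratified, so both classes appear
in both halves — the source says only "randomly divided", and stratification
prevents degenerate halves at small n), negatives in the training half are
undersampled to 1/16, and a radial-basis-kernel margin classifier is fitted
with (C, γ) chosen by stratified 5-fold cross-validated AUC-ROC over the
conventional grids $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$. Evaluation
uses the untouched, *not* undersampled test half: AUC-ROC from continuous
decision values, accuracy at the sign threshold.

No support-vector-machine library is available in the build environment, so
the classifier is a least-squares SVM (kernel regularized least squares with
a bias term) solved exactly:
$$\begin{pmatrix} 0 & \mathbf 1^\top \\ \mathbf 1 & K + I/C \end{pmatrix}
\begin{pmatrix} b \\ \alpha \end{pmatrix} =
\begin{pmatrix} 0 \\ y \end{pmatrix},\qquad
f(x) = K(x, X)\,\alpha + b.$$
This satisfies the module contract (binary margin classifier, RBF kernel,
continuous decision values); C keeps its meaning as the trade-off between
training error and margin smoothness. At the sample sizes this pipeline
produces after undersampling (tens of genes), the exact solve is faster than
an iterative SVM and has no convergence parameters.

By default the classifier receives the 30 strongest motif groups per
discovery pass (`max_motifs`). The top-5% seeding rule can produce hundreds
of groups, most of which are weakly correlated noise at desk scale; feeding
them all measurably dilutes the informative features (mean test AUC on the
planted single-motif benchmark drops from ≈0.85 to ≈0.78). Thirty matches
the depth at which this method's motif tables are conventionally reported;
the cap is configuration, not mechanism.

## Sequential parameter optimization

$\nu$, $\tau$, and the number of motif pairs $N_{mp}$ are optimized in that
order (the order of their measured effect on AUC-ROC). For each $\nu$, the
mean AUC over $\tau \in \{1..5\}$ with repeated runs (AoAR) is compared with
its predecessor; $\nu$ stops at the last value that improved. One deliberate
deviation: the literal published rule ("increase while not worse") never
terminates on an exactly flat response, so this implementation stops on
non-improvement — identical everywhere except exact ties, where the original
needs an arbitrary cap. For $\tau$, the slope of AUC against $\tau$ over a
5-wide window (SoAR) is tracked against its running maximum; the loop stops
when the slope falls below half the maximum (a negative first slope stops
immediately at $\tau = 1$). The step rule "add the integral 5/τ" is read as
$\max(1, \mathrm{round}(5/\tau))$ — effectively 1 — because a floor reading
would never advance beyond $\tau = 6$. $N_{mp}$ is the argmax of AoAR over
{1, 2, 3, 5, 10, 20, 30, 50, 100, 200}, ties to the smaller value. Safety
caps ($\nu \le 8$, $\tau \le 30$) guard pathological responses and warn when
hit. Every cell's seed is a deterministic function of the base seed and the
cell coordinates, so trajectories replay bit for bit and resumed runs
recompute nothing.

## What the synthetic generator does and does not emulate

`generate_synthetic()` builds i.i.d. uniform-base promoters (the same
convention the source used for its random background sequences), draws
up-regulated genes' ratios uniformly from (3, 10) and background ratios
log-normally around 1 (σ = 0.25 on the log scale, giving a realistic
long-tailed ratio distribution in which essentially no background gene
crosses the twofold threshold), and overwrites planted motifs — optionally
mutated per base, optionally with a partner at a fixed separation ± jitter —
at sampled positions. Insertions never use indels, so coordinates stay
exact and a truth record lists every insertion.

What this deliberately does not model: Markov-structured genomic background,
GC skew, nucleosome positioning, TATA-like compositional gradients around
the TSS, or expression noise correlated between genes. A green test on this
generator establishes that the *machinery* behaves as specified under a
known ground truth — recovery of planted motifs, correct positional and
co-localization statistics, sane classifier behaviour. It does not establish
that the method's biological findings on real genomes are reproduced; those
depend on external data and on an unpublished gap-penalty value.

The expression-noise model (log-normal) is an invention of this package —
the source provides no generative model — and its parameters are exposed so
tests control the effect size.

### The null-scenario check and selection leakage

Candidate discovery ranks k-mers by their correlation with the realized
expression ratios of *all* genes; the simulation then splits those same
genes into training and test halves. Features are therefore selected with
knowledge of every gene's label — a leakage inherited from the source
procedure, which also predicts motifs from the full microarray before
splitting. On a null world (no planted motifs, labels independent of
sequence) this leakage alone yields test AUC ≈ 0.63: the pipeline partly
memorizes chance correlations. The package's null sanity check therefore
evaluates the classifier with up-labels re-drawn independently of the labels
that drove discovery (same marginal distribution); under that construction
the measured AUC is ≈ 0.49, confirming the classifier itself invents no
signal. Users comparing motif sets on real data should prefer labels from an
independent experiment for the same reason.

## Numerical choices

* Factorials for run lengths 1..16 are precomputed; all scores are doubles.
* The compiled scanner encodes bases 2 bits wide and scores each window by a
  table lookup over all match masks, so a full candidate-by-genome scan is a
  few bit operations per window; `N` bases match nothing, including `N`.
* $\nu$ is applied after the per-gene maximum (legal because $x^\nu$ is
  monotone for $x \ge 0$), keeping the table $\nu$-independent.
* Candidates with zero total similarity score 0 and are flagged through
  `n_contributing = 0` (the weighted mean is 0/0 there).
* Grid-search ties resolve to the smallest C, then smallest γ; ranking ties
  in candidate scores resolve lexicographically; Nmp ties resolve to the
  smallest tested value. All ties are therefore deterministic.
* Chi-square expectations of zero mark a pair untestable rather than
  producing infinities inside the statistic.

## Known limitations

* Exact-match scanning of grouped motifs underestimates occurrences of
  degenerate elements relative to a PWM scan; this mirrors the source design.
* The binomial enrichment P-value treats 8-bp windows as independent trials,
  which overlapping windows are not; it is reported for description and never
  used for ranking (again by design).
* With only tens of positive genes, the train/test AUC has a seed-to-seed
  spread of several points; repeated-seed averages are used everywhere a
  decision depends on it.
* The sequential one-parameter-at-a-time optimization finds a local optimum
  along its path; it is not a global search, and is not meant to be.
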
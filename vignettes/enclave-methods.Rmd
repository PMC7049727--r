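---
title: "Detecting nested chromosome enclaves in Hi-C contact maps"
author: "HiCenclave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nested chromosome enclaves in Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCenclave)
```

## The problem and the model

A Hi-C experiment summarizes the 3D folding of a chromosome as a symmetric
contact matrix $W(i, j)$: the read count between equally sized,
non-overlapping genomic bins (loci) $i$ and $j$ at some resolution.
Classical domain callers segment the chromosome into *contiguous*
self-interacting blocks (TADs). Chromosomes, however, also form
*non-contiguous* preferentially self-interacting loci clusters — the plaid
patterns visible in contact heatmaps — and these clusters nest inside one
another across scales. HiCenclave detects such clusters, called
**enclaves**, by top-down recursive spectral bisection of the whole
chromosome, and represents their nesting as a rooted partition tree.

The interactions are treated as a weighted graph on the loci. One
bisection step is:

1. Form the random-walk normalized Laplacian $L = I - D^{-1} W$ on the
   current loci set, where $D$ is the diagonal degree matrix (degrees
   include the self-contact diagonal, so rows of $L$ sum to 0). The
   random-walk normalization keeps highly covered loci from dominating
   the spectrum.
2. Take the eigenvector of the second-smallest eigenvalue (the Fiedler
   vector), computed through the similarity-equivalent symmetric
   Laplacian for numerical stability.
3. Split the 1-D Fiedler coordinates with 2-means, taking the consensus
   over five seeded runs.

Each resulting part $C_1$ (against its partner $C_2$) is scored with the
**expansion metric**

$$\mathrm{expansion}_{C_1} =
  \frac{\sum_{x \in C_1} \sum_{y \in C_2} w(x, y)}
       {\sum_{x \in C_1} \sum_{y \in C_1} w(x, y)},$$

implemented with the literal ordered-pair reading of the double sums: the
numerator counts each cross edge once, the denominator counts each
internal edge twice and each diagonal entry once. A part is *insulated*
when its expansion is below 1. A bisection with two insulated parts is a
**split** (both parts are recursed); with exactly one, a **strip** (only
the insulated part is recursed, the partner is kept on the strip node as
auxiliary loci — it is a loose companion set, not a cluster of its own);
with none, the branch **stops**. Sets of two or fewer loci are never
bisected. The result is a partition tree in which, by construction, every
non-root node is insulated.

Expansions are computed on the full-chromosome (normalized and scaled)
weights restricted to the two parts, not on re-normalized submatrices, so
insulation always refers to the same weight scale.

## Preprocessing

Raw matrices are first balanced so that all row sums are equal
(Knight–Ruiz-style balancing), correcting locus-specific coverage bias.
The balancing is implemented as symmetric diagonal scaling
$\mathrm{diag}(s)\, W\, \mathrm{diag}(s)$ found by the Sinkhorn–Knopp
fixed-point iteration $s \leftarrow \sqrt{s / (W s)}$; on matrices with
positive row sums this converges to the same balanced matrix as
Newton-type Knight–Ruiz solvers. Default tolerance $10^{-8}$ on the row
sums, at most 1000 iterations; non-convergence is an error that reports
the residual.

Because Hi-C counts are heavily dispersed, the balanced weights are then
passed through a Box–Cox transform $(x^\lambda - 1)/\lambda$ (log at
$\lambda = 0$) with a chromosome-specific exponent chosen by maximizing
the profile log-likelihood for normality over the grid $[-2, 2]$ in steps
of 0.05 (the conventional profile range). Two choices are deliberate:

* zeros are structural ("no contact") — $\lambda$ is fitted on strictly
  positive entries only and zeros stay zero;
* the spectral step needs non-negative weights, so if the transform
  produces negative values all positive-support entries are shifted by
  $-\min + \varepsilon$ (machine-epsilon scale). The shift preserves the
  ordering of weights; it does compress *relative* contrasts, which is
  visible as larger expansion values deeper in the tree.

Bins whose total raw weight is zero are unmappable regions; they are
dropped before balancing and recorded so coordinates can be reconstructed.

## Landmarks and nestedness

Trees differ wildly in topology between chromosomes, so positions in the
tree are standardized through three landmark node classes:

* **top enclaves** — nodes whose own bisection is a strip but with only
  splits above ("first strips");
* **bottom enclaves** — children of splits with no split at or below them
  ("last splits");
* **leaves** — the remaining childless nodes.

The definitions collide on degenerate trees, and the package resolves the
collisions deterministically: a first strip that also has no split below
it is labelled *bottom* (it is a last split), and a childless split child
is likewise *bottom* rather than leaf. This precedence (bottom > top >
leaf) keeps the three sets disjoint and keeps whole clusters — rather
than their stripped-down remnants — as the bottom level, which is what
the bottom-enclave flat clustering and all downstream comparisons use.

**Nestedness** (NS) maps every node onto $[0, 1]$: 0 at top enclaves, 0.5
at bottom enclaves, 1 at leaves, linearly interpolated in root distance
$D$ (branches from the root) in between. Between top and bottom,

$$\mathrm{NS}_i = \frac{0.5\,(D_i - \min D)}{(\max D - \min D) + 1},$$

with $\min D$ the nearest top enclave above and $\max D$ the furthest
bottom enclave below; the $+1$ keeps these values strictly below 0.5.
Between bottom and leaf,

$$\mathrm{NS}_i = \frac{0.5\,(D_i - \min D)}{\max D - \min D} + 0.5.$$

Nodes above all top enclaves (the pure-split region near the root) carry
no NS of their own; loci whose deepest containing node lies there get a
per-locus NS of 0. A node under a top enclave with no bottom enclave
among its descendants has no defined anchor pair and is reported as
NS-undefined rather than silently interpolated. Per-locus NS is the NS of
the most nested node containing the locus; note that auxiliary loci of a
strip are "most nested" at the strip node itself.

## Validation statistics

Agreement with a reference clustering (TADs, compartments, or the planted
truth of a simulation) is measured by the **variation of information**

$$\mathrm{VI}(C, C') = H(C) + H(C') - 2 I(C, C'),$$

computed from empirical frequencies in natural logarithm. VI is a true
metric on partitions and is bounded by $\log N$. The flat clustering
compared is the bottom-enclave clustering; loci in no bottom enclave are
pooled into one catch-all cluster per chromosome (not singletons), which
keeps the cluster count comparable with references. Significance comes
from a tree-matched null: random trees with the template's exact topology
and node sizes but uniformly drawn memberships. With $r$ of the random
clusterings beating the observed VI and $n$ clusterings considered (500
draws, so $n = 501$), the empirical P-value is $(r + 1)/(n + 1)$; ties
count as not smaller.

Overlaps with genomic feature tracks use three per-cluster summaries —
covered fraction, mean signal intensity per bp, and overlapping-site
count — summed per site without merging, so self-overlapping tracks can
exceed a fraction of 1 (documented rather than "fixed"). Per-locus
**feature enrichment** divides each locus's overlap statistic by the mean
over the loci of its top enclave, making trends along nestedness
comparable across chromosomes. Deviations of stratum-level overlap counts
from the chromosome-wide rate are tested with the exact two-sided Poisson
rate test and Benjamini–Hochberg FDR (default 0.05); the exact (rather
than Wald) test was chosen because desk-scale strata have small counts. A
non-parametric cut-off for extreme FE values against a random-clustering
null is provided as the 75th percentile plus twice the IQR of the null.
DNA loops (BEDPE) count as integrated when both anchors fall in the same
bottom enclave; an anchor touching several enclaves is assigned to the
largest bp overlap, ties to the earlier-start enclave.

## What the synthetic generator emulates

`simulateContactMap()` draws Poisson (optionally negative-binomial)
counts around an expected matrix

$$E[i, j] = \mathrm{background} \cdot |i - j|^{-\alpha}
  + \sum_{\text{planted nodes} \supseteq \{i,j\}} w_{\text{node}},$$

i.e. a power-law distance-decay background (default $\alpha = 1$, the
fractal-globule-like decay regime) with nested planted blocks on top.
The diagonal is set to 0: self-contact counts are dominated by ligation
artifacts, and the decay form is undefined at distance zero (readers
still accept diagonals in real dumps).

The default hierarchy (`examplePlantedHierarchy()`, 144 bins) has three
superblocks, each a compact core of two leaf blocks (attachment weight 5,
core weight 45, block weight 50, background 10 — a 5:1 within-to-
background ratio at the block increments) plus a small loose **shell**:
loci attached to the whole superblock just above background with weak
internal cohesion. The shell emulates the shell of long-ranging DNA loops
around tightly packed cores; on such maps the recursion splits off
superblocks, strips the shells (creating top enclaves), splits the cores
into blocks (bottom enclaves) and strips inside blocks down to the
leaves, so every segment of the NS scale is populated. One superblock
interleaves its blocks in alternating runs (plaid pattern) and one
contains a block made of two distant genomic intervals — the
non-contiguous case that distinguishes enclaves from TADs.

What the generator does *not* emulate: realistic copy-number and
mappability bias (KR has little to do on these fixtures), resolution-
dependent noise structure, inter-chromosomal contacts, and the gradual,
ambiguous boundaries of real chromatin domains. Passing the recovery
tests therefore shows the algorithm is a correct implementation that
recovers the structure it is designed for; it does not certify biological
accuracy on real tissue data.

`simulateFeatureTrack()` plants Poisson-placed interval sites with a rate
multiplier on target loci, log-normal lengths and intensities;
`simulateLoops()` plants anchor pairs within or across clusters. Both are
used to verify that enrichment statistics recover planted signal and stay
quiet on uniform tracks.

## Numerical choices and degenerate inputs

* Eigensolver: dense symmetric `eigen()` on the symmetric normalized
  Laplacian, back-transformed by $D^{-1/2}$. At desk scale (a few
  thousand bins) this is simpler and more robust than sparse iterative
  solvers; matrices are held dense throughout.
* Eigenvector sign is canonicalized (first non-zero coordinate positive)
  so outputs are platform-stable. A (near-)tie at the second eigenvalue
  is reported as a warning — the Fiedler vector is then not unique and
  the first solver vector is used.
* Consensus 2-means: five runs seeded deterministically from one master
  seed (default 1234); labels aligned by center order along the Fiedler
  axis; majority vote, ties broken toward the nearer average center.
  With five (odd) runs ties cannot occur; the rule matters only for
  even seedings.
* All Fiedler coordinates identical is a degenerate split and an error;
  in tree construction any bisection error terminates only that branch
  and is recorded on the node as a termination reason.
* A locus with zero degree inside a restriction is a precondition
  violation naming the locus.
* Duplicate triple entries must agree (mirrored full dumps); conflicting
  duplicates are an error rather than being summed silently.
* Box–Cox on a constant positive sample is degenerate; the grid argmax
  falls back to the first grid point.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` work on simulated chromosomes
of 144 bins (50 planted-recovery replicates in the tests, 20 in the
script), 500-draw VI nulls, 100-loop integration sets and 100 null-track
replicates for the false-positive rate. These sizes were chosen to make
every property measurable with comfortable statistical margins while a
full run stays in the minutes range on a single core.

## Known limitations

* Dense matrices: memory is $O(N^2)$; chromosomes at very fine
  resolution (tens of thousands of bins) would need a sparse eigensolver
  that is out of scope here.
* Only intra-chromosomal (cis) maps; one chromosome per run.
* The strip convention follows the "core plus auxiliary shell" reading:
  the non-insulated partner of a strip is never recursed. If the partner
  in fact contains structure, it is only visible through the catch-all
  cluster.
* Per-locus NS of loci whose deepest node is NS-undefined (a branch with
  no bottom-enclave anchor below its top enclave) is reported as `NA`
  and excluded from enrichment trends.
* The balanced matrix normalizes row sums to exactly 1; tools that
  rescale to preserve total coverage will differ by a constant factor,
  which is irrelevant to the (scale-free) spectral step and expansion
  ratios.
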
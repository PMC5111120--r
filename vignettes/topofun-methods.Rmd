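---
title: "Term-conditional network topology features for protein function prediction"
author: "topofun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Term-conditional network topology features for protein function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofun)
```

## The model

`topofun` treats "does protein *i* carry GO term *t*?" as a binary
classification problem whose features are read off a node- and edge-weighted
PPI network. The guiding assumption is functional homophily: proteins close
to — and well connected with — the proteins already annotated with *t* are
more likely to carry *t* themselves. Two weight systems enter:

* **edge weights**: the interaction confidence $e_{u,v} \in (0,1]$ supplied
  with the edge list (taken as given, never re-scored);
* **node weights**: a 1767-dimensional primary-structure descriptor of each
  protein (amino-acid and dipeptide composition, three autocorrelation
  families over 8 standardised physicochemical scales at lags 1–50, and
  Dubchak composition/transition/distribution over 7 three-class attributes).

For a query $i$ and annotated set $F$, a breadth-first search enumerates the
shortest-path structure to depth $L = 1,\dots,10$. Writing $\sigma(v)$ for
the number of shortest $i\!\to\!v$ paths and $w(v)$ for the sum over those
paths of the product of edge confidences (both computed by the standard
predecessor recursion, so no path is ever materialised), the package derives
eight families per level — descriptor-weighted path averages (APVW),
confidence-mass proportions (PWPFP, APWPF), within-level interaction
proportions (PINPFP), degree summaries of the annotated level set (ADPF,
ADPWPF), the membership proportion (PP), and the proportion of
annotated-pair shortest paths that run through the query (PPL, defined from
$L = 2$ because a path joining two annotated proteins through $i$ has at
least two hops). The concatenated vector has
$1767\times10 + 6\times10 + 9 = 17{,}739$ entries.

Classification uses mRMR-ranked features and an RBF-kernel SVM with
$(C,\gamma)$ grid search under stratified 10-fold cross-validation;
performance is summarised by pooled out-of-fold Acc/Sen/Spe/Pre/Mcc and
trapezoidal ROC/PR areas.

## Interpretive choices in the feature algebra

A few combining rules are under-determined by the verbal definitions of the
features; the package fixes them as follows and tests against an exhaustive
path-enumeration oracle built on these same conventions:

* **"Path with distance L" means shortest path of hop length L.** The depth
  parameter is tied to BFS levels and capped at 10 (the hop diameter of the
  interactome the method targets), which is a property of shortest paths;
  it also keeps every family polynomial-time via the $\sigma/w$ dynamic
  programme instead of exponential simple-path enumeration.
* **A multi-hop path's weight is the product of its edge confidences**, the
  natural chaining of independent interaction reliabilities; it reduces to
  the single confidence at $L=1$.
* **APVW is normalised by the total path count NP** (all endpoints), while
  descriptor mass is summed only over annotated endpoints — so APVW scales
  with the local density of annotated proteins rather than being a pure
  conditional mean.
* **PPL is the ratio of through-query paths to all shortest paths between
  annotated pairs at distance L**, giving a proportion in $[0,1]$.
* **Every empty-denominator case yields 0** (empty levels, absent function
  proteins, zero path mass), so vectors are dense and length-invariant.
* **Degree is the unweighted degree in the full LCC**, not in the
  level-induced subgraph.
* **The query is removed from $F$ before featurisation.** Without this,
  membership of the positive set would be trivially encoded in PP/PWPFP at
  the query's own position and the classifier could learn the label from the
  label. The no-homophily control below is the regression test for this.

## Descriptor conventions

The autocorrelation block uses 8 property scales (Eisenberg hydrophobicity,
Hopp–Woods hydrophilicity, side-chain mass, pK1, pK2, isoelectric point,
Bhaskaran–Ponnuswamy flexibility, Charton polarizability), each standardised
to zero mean and unit SD over the 20 residues, at lags 1–50 — the standard
$8\times50$ split behind a 400-value family. Lags $d \ge N$ and zero-variance
(homopolymer) denominators return 0 so the vector length never varies. The
CTD block uses the 7 standard Dubchak attributes with their published
three-class partitions (exported as `AA_CTD_GROUPS` so the groupings are
auditable); transitions count both orders of a class change and divide by
$N-1$; distribution landmarks use the ceiling rule on occurrence indices and
are reported as fractions of $N$ in $[0,1]$. Non-canonical residues are
dropped with a warning (configurable replacement).

## Dataset construction

Positives come from the GO-style table, negatives from the NoGO-style table,
and everything else in the LCC is "unknown". Proteins annotated both
positive and negative resolve to positive (direct experimental evidence
outranks computed negatives) with a logged message. Benchmarks take all
positives and equally many negatives sampled uniformly without replacement,
falling back to the unknown pool when negatives run short; the 1:1 ratio
avoids the imbalance of realistic negative pools, and a 50-positive floor
guards statistical power. The degree-matched variant pairs each positive
with a non-positive of equal network degree (closest degree on exhaustion,
ties to the lower degree) to control for degree as a confounder. Datasets
are canonical functions of the selected sets (sorted within groups), so a
degenerate pool — exactly as many negatives as needed — reproduces byte-identical
datasets across resampling seeds and zero metric SD.

## Feature selection and evaluation

mRMR uses Peng's difference (MID) criterion with mutual information in bits
over a 3-bin discretization (z-score per column, cut at ±1 SD inclusive;
zero-SD columns to the middle bin) — Peng's published convention for
continuous features; ties break by ascending column index. The subset sweep
produces the nested prefixes of sizes 5, 10, …, 1000 (200 subsets),
truncating with a warning when fewer features are available.

The SVM grid is $C = 2^{-5}, 2^{-3}, \dots, 2^{15}$ crossed with
$\gamma = 2^{3}, 2^{1}, \dots, 2^{-15}$ (110 pairs), optimised by
cross-validated accuracy with ties resolved toward smaller $C$ then larger
$\gamma$ (a regularisation preference). Feature scaling (train min/max to
$[-1,1]$; constants to 0) and, by default, mRMR selection are fitted inside
each training fold only — nested selection costs a little optimism but keeps
the no-signal control honest; ranking once on the full benchmark is
available via `nested_selection = FALSE` for sweep-style analyses. ROC/PR
areas come from the pooled out-of-fold decision values as one curve rather
than per-fold averaging, trapezoidal in both cases, with score ties collapsed
to single operating points. Mcc is 0 whenever a marginal vanishes.

## What the synthetic generator does and does not emulate

`simulate_ppi_study()` produces the four input files the pipeline consumes.
Its defaults define the package's reference study: 300 proteins,
preferential-attachment graph with $m=3$ (heavy-tailed degrees, as in real
interactomes, and degree spread for the degree-matched sampler), confidences
uniform on $(0,1]$, sequence lengths uniform on 50–500, one planted term
annotating 30% of proteins, and a NoGO table covering half the non-members.
The homophily parameter $h$ rewires each member–non-member edge toward a
random co-member with probability $h$: at $h=0$ annotations are independent
of topology (the null), at $h=0.8$ the term forms a dense module. Sequences
are i.i.d. uniform over residues by default; an optional biased-composition
mode gives members a shifted amino-acid usage so that the node-weight (APVW)
channel also carries signal.

The generator does not mimic GO's term hierarchy, HIPPIE's confidence model,
evidence-code structure, or sequence redundancy. Passing tests on it
therefore demonstrate that the machinery detects planted topological
(and compositional) signal without leaking labels — not that any particular
accuracy will be attained on a real interactome, where false-negative
annotations, redundancy and hierarchy effects all intrude.

## Problem sizes and numerical checks

The test-suite checks run at deliberately small scale: oracle equivalence on
200 random connected graphs of ≤ 12 vertices against explicit geodesic
enumeration (exact to 1e-12), end-to-end planted-module recovery at
$n = 300$/$h = 0.8$ (expected CV accuracy ≥ 0.80; observed ≈ 0.98) with the
$h = 0$ control held to chance (0.4–0.6), and a 10-repeat resampling
experiment on a 60-protein fixture. The acceptance script repeats the
end-to-end runs and a full-scale 10-repeat resampling at $n = 300$. All
randomness flows from user-supplied seeds through local RNG scopes, so
identical seeds reproduce identical studies, folds and reports; the global
RNG state is never disturbed.

## Known limitations

* Featurisation is dense: all 17,739 features are computed even when only a
  ranked prefix is used downstream; for genome-scale networks the APVW block
  dominates memory and a sparse/streaming variant would be needed.
* mRMR's discretization loses information for strongly non-Gaussian
  features; the ±1 SD cut is a convention, not an optimum.
* The grid-search winner's pooled out-of-fold accuracy is mildly optimistic
  (the winner is chosen on the same folds); this is visible as null-control
  accuracies slightly above 0.5.
* Negative "unknown" samples may contain false negatives by construction;
  the resampling experiment quantifies, but cannot remove, the resulting
  variance.
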
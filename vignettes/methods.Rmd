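---
title: "Methods: signed propagation, network correlation and drug similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed propagation, network correlation and drug similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signetpharm)
```

This vignette is the package's own account of its models: what is
computed, under which assumptions, which knobs matter, and where a design
was genuinely open and a choice had to be made.

## Signed random walk with restart

A signaling network is a directed graph whose edges carry signs:
activation (+1) or inhibition (−1). A drug perturbs its targets; the
perturbation propagates. The signed random walk with restart models this
with a walker that at each step follows a uniformly random out-edge with
probability $1-c$ or teleports back to a seed with probability $c$. The
walker carries a sign: crossing a negative edge flips it; positive edges
preserve it; a restart resets it to the seed's original sign (an
inhibitory drug target seeds the negative channel). Writing $W_+$ and
$W_-$ for the transition operators routed through positive and negative
out-edges, and $q_+, q_-$ for the restart mass split by seed sign, the
stationary channels solve the coupled linear system

$$p = (1-c)\,(W_+^\top p + W_-^\top n) + c\,q_+,\qquad
  n = (1-c)\,(W_-^\top p + W_+^\top n) + c\,q_-.$$

The *activation score* $r = p - n \in [-1, 1]$ is negative where the
perturbation exerts net predicted inhibition. Summing the two equations
recovers exactly the unsigned RWR equation in $p + n$; this channel-sum
conservation is enforced in the test suite to $10^{-8}$, and on small
graphs the solution is checked against an independent enumeration of all
signed walks weighted $c(1-c)^L$.

Assumptions worth stating plainly:

* **Transition mass is normalised jointly** over all out-edges of a node;
  the sign only routes the channel. The alternative — normalising the
  positive and negative out-edges separately — does not conserve total
  mass under the flip dynamics, which is why joint normalisation was
  chosen.
* **Dangling nodes** (no out-edges) return their mass to the restart
  distribution *with original seed signs*, i.e. a forced restart. This
  keeps $\sum (p+n) = 1$ exactly. Note a consequence: with dangling nodes
  the fixed point is affine but not linear in the seed distribution, so
  seed-set influence equals the average of single-seed influences only on
  dangling-free graphs. Propagation is normally run on the giant strongly
  connected component, where the point is moot.
* **No balance attenuation.** Some signed-walk formulations damp the
  sign flip with extra parameters; here the plain flip walker is
  implemented (equivalent to setting such parameters to one).
* Seeds with *unknown* direction of action are treated as activating
  (+1) with a warning, the conservative reading for a score whose
  interesting tail is the inhibited one.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `restart` ($c$) | 0.75 | teleport probability; 0.75 everywhere, including the correlation stage, keeps influence local to the seeds |
| `tol` | 1e-10 | L1 change of the concatenated $(p,n)$ iterate; contraction factor is $1-c$, so the true error is within `tol`$/c$ |
| `max_iter` | 10000 | exceeded only on pathological inputs; exceeding it is an error, never a silent partial result |
| `fraction` | 0.1 | top share of nodes by $\lvert r\rvert$ kept by `select_top_signed()` |

The top-fraction selection ranks **all** nodes of the propagated graph by
$\lvert r\rvert$, keeps the top $\lceil f\,n\rceil$ rank positions with
boundary ties all retained, then filters by sign. The denominator is the
node count of the graph actually propagated on (the GSC when the pipeline
ran on the GSC). Published analyses of this kind do not always make that
denominator recoverable from their reported counts; it is a documented
convention here, not a reproduction of any specific count.

## Correlation Z-score

The association of a drug-target set $D$ and a disease-gene set $S$ is
the Pearson correlation of their unsigned RWR influence vectors over
*all* nodes of the background network — seeds included — standardised
against a permutation null:

$$z = \frac{\mathrm{Cor} - E(\mathrm{Cor})}{\delta(\mathrm{Cor})}.$$

The null redraws the **disease side** uniformly from the graph's nodes,
keeping the post-intersection cardinality, `n_null` = 1000 times by
default. Two open points were settled as follows: the resampled side is
the disease set (the natural reading of a "random contrast disease
genes" null), and null sets are drawn uniformly, **without degree
matching** — no degree-preserving null is described for this statistic in
the tradition the package follows, but uniform sampling does inflate z
for hub-heavy target sets, a known limitation to keep in mind when
comparing drugs with very different target degrees.

The formula path is exercised in the tests against published arithmetic
(a printed row with Cor 0.207, E(Cor) 0.005 and z 13.862 back-solves to
δ = 0.01457, which the implementation reproduces to three decimals), and
the null's sanity is checked by drawing the drug set itself from the
null, whose z must average to zero.

## Drug similarity

**Structure.** SMILES are parsed by OpenBabel; the circular fingerprint
is authored in the package: atom invariants (atomic number, heavy-atom
degree, total bond order, formal charge, attached hydrogens, ring
membership) are iteratively rehashed with sorted neighbour
(bond-order, identifier) pairs for `radius` rounds (default 2), and every
identifier sets bit `id mod n_bits` (default 2048). Tanimoto similarity
is $\lvert A\wedge B\rvert/\lvert A\vee B\rvert$. Two consequences are
deliberate: identical strings always score 1, and stereochemistry absent
from a canonical SMILES cannot distinguish stereoisomers — the bundled
components table contains such a pair (salvianolic acids B and Y), which
is reported, not "fixed". Two empty fingerprints are an error, not a 1.

**Target modules.** The separation score on an undirected interactome
uses the *closest-distance* convention of the network-medicine
literature: $\langle d_{AB}\rangle$ averages each member's hop distance
to the nearest member of the other module (0 if it belongs to both), and
$\langle d_{AA}\rangle$ each member's distance to its nearest other
member, singletons scoring 0. Unreachable terms are dropped from the
means; fully disconnected module pairs are an error. The bare formula
$s_{AB}=\langle d_{AB}\rangle-(\langle d_{AA}\rangle+\langle
d_{BB}\rangle)/2$ does not by itself fix the closest-vs-all-pairs choice;
closest was chosen and is locked in by a brute-force enumeration oracle
in the tests. $s_{AB}$ is symmetric, and $s_{AA}\le 0$ for modules of two
or more genes.

**Function.** PathSim counts instances of the metapath
compound→target→function→target→compound: $M_{ij} = \lvert\{(t, f, t'):
t \in T_i,\ t' \in T_j,\ f \in F_t \cap F_{t'}\}\rvert$ and
$\mathrm{sim}_{ij} = 2M_{ij}/(M_{ii}+M_{jj})$. Only the 4-step metapath
counts; directly shared targets contribute only through shared
annotation terms, not as a separate 2-step path — the stricter reading
of a function-fingerprint similarity. Drugs with no annotated target
have no self-paths and are excluded with a warning rather than given an
arbitrary score (mirroring the real situation of a component with an
empty target list).

**Clustering** runs `hclust` on $1-\mathrm{sim}$, complete linkage by
default (the method is configurable since the choice is not forced by
anything upstream), cut at `n_clusters` = 6 by default. Labels are
renumbered in order of first appearance, making the partition invariant
up to renaming under input permutation. Separation matrices ($s_{AB}$)
are *not* similarities in $[0,1]$ and are refused by the clustering
entry point rather than silently rescaled.

## Enrichment and bookkeeping

`hypergeom_upper(N, K, n, k)` is the inclusive upper tail
$P(X \ge k)$ — "at least this much overlap by chance" — computed via the
log-scale hypergeometric CDF; $k=0$ gives exactly 1. It is verified
against direct binomial-coefficient enumeration for every parameter
combination with $N \le 12$. The population defaults, in the pipeline, to
the node set of the propagated graph; this is configurable because no
universal convention exists. Raw p-values are reported; a
Benjamini–Hochberg column is optional for multi-set runs.

Percentages in `overlap_summary()` are rounded half up to 2 decimals and
the printed label trims trailing zeros — the convention that renders
38/1159, 38/79, 38/227 as 3.28, 48.1 and 16.74.

pIC50 is defined on the **molar** scale, $\mathrm{IC50}[\mu M] =
10^{-\mathrm{pIC50}}\times 10^6$ — the only convention under which the
bundled predicted/measured potency pairs are self-consistent. Printed
tables sometimes round one column from the other's unrounded value, so
the consistency checker accepts a pair when either direction matches
(0.002 µM or 0.001 pIC50).

## The synthetic study

Real inputs of this kind of analysis — a curated signaling network, an
interactome, disease genes, drug target lists — are database exports.
The generator replaces them with objects whose *statistical* structure is
planted and therefore testable:

* a preferential-attachment signed digraph (default 7000 nodes, out-degree
  4, 25% negative edges) whose edge directions are reversed with
  probability 0.15, calibrated once so the giant strongly connected
  component covers ≈60% of genes at the default scale, matching the
  coverage typical of curated human signaling networks;
* a disease module grown as a breadth-first ball (default 1000 genes) —
  the locality assumption implicit in using diffusion proximity at all;
* a drug whose targets (default 80, all inhibitory) fall in the module's
  closed 1-hop neighbourhood with probability `overlap_fraction`, the
  planted effect size;
* block-structured annotations: terms are partitioned among blocks and
  genes draw only from their block, so within-block PathSim exceeds
  cross-block PathSim by construction.

Scaled-down instances are used where many replicates are needed: the
parameter-recovery property runs 20 replicates of 200-node networks
(20-gene modules, 15-target drugs, 50 null sets) and requires the
60%-overlap drug to out-score the 0%-overlap control in ≥95% of
replicates; the propagated-inhibition property runs 20 replicates of
400-node networks and requires hypergeometric p < 0.05 in ≥90% of usable
replicates, with the selection stratum (top 20%) chosen wider than the
seed set, which by construction occupies the first ranks. The bundled
demonstration study uses 300 genes. These sizes are the package's chosen
experiment design: large enough for the planted signal to dominate
sampling noise, small enough to rerun freely.

What passing these tests does **not** show: that real signaling networks
are preferential-attachment graphs (they are not; they have modularity
and motif structure the generator lacks), that real disease genes form
clean BFS balls, or that GO term structure is block-diagonal. The
synthetic study validates the *machinery* — that each statistic recovers
the structure it claims to measure when that structure is present — not
any biological claim.

## Degenerate inputs and failure modes

* Duplicate edges, self-loops, unknown sign tokens and short lines are
  *errors with line numbers*, never silently merged or dropped.
* All-zero activation scores yield an empty selection with a warning.
* A degenerate correlation null (zero variance) is an error, not a z of
  ±Inf.
* Non-convergence reports the last residual and fails; there is no
  silent partial result anywhere.
* Gene-set members absent from a graph are dropped with a count
  message; an empty post-intersection set is an error.

## Known limitations

* Uniform (degree-ignorant) correlation nulls, as discussed above.
* The circular fingerprint is a faithful extended-connectivity scheme
  but not bit-compatible with any specific toolkit's implementation;
  comparisons should stay within one fingerprinting scheme.
* Hop distances (unweighted) in the separation score; confidence-weighted
  interactomes are collapsed to their topology.
* Exact power iteration only, sized for networks up to ~10^5 nodes; no
  approximate or streaming solvers.
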
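---
title: "Methods: detecting temperature-sensitive regions of RNA secondary structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting temperature-sensitive regions of RNA secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

RNA secondary structure is an equilibrium ensemble, and the ensemble shifts
with temperature. Some nucleotides barely change their probability of being
base-paired when the temperature moves a few degrees; others — RNA
thermometers being the textbook case — change a lot, and they tend to change
together, in contiguous stretches of sequence. `rnatherm` locates those
stretches, compares them between two homologous RNAs, and asks a sharper
question for the two-sequence case: *is the structural difference between
the homologs attributable to the specific substitutions that separate them,
or would any comparable number of random substitutions have done the same?*

## Pipeline

For a sequence of length $L$ and an integer temperature range
$t_1 \dots t_2$ (°C):

1. **Fold.** At every temperature $t$ the per-nucleotide paired-state
   probability $p_t(i) = \sum_j P_t(i,j)$ is computed from the equilibrium
   base-pair probability matrix $P_t$ of a thermodynamic folding engine.
2. **Difference data set.** For every elevated temperature the differences
   $d(t, i) = p_t(i) - p_{t_1}(i)$ are pooled into one combined data set of
   $(t_2 - t_1) \cdot L$ values (a 1000-nt sequence over 32–39 °C gives
   7000 values). Its mean $\mu$ and standard deviation $\sigma$ summarise
   the sequence's background temperature response.
3. **Outlier calling.** A cell $(t, i)$ is *significant* when
   $|d(t,i) - \mu| > k\sigma$, with $k = 3$ by default.
4. **Clustering.** The significant positions at the top difference
   ($t_2$ vs $t_1$) are clustered along the sequence with DBSCAN
   ($\varepsilon = 11$, MinPts $= 5$ by default).
5. **Comparison and statistics** (two sequences): positions and clusters
   are classified as shared or sequence-specific; each sequence-specific
   cluster is tested against an ensemble of in-silico mutants of the first
   sequence with a one-sided exact binomial test.

The interface limits mirror the intended use on mRNA-scale inputs:
sequences up to 9999 nt, temperatures within 0–99 °C, and a span
$t_2 - t_1 + 1 \le 20$ °C.

## Folding backends

Probabilities come from a pluggable provider. The `"vienna"` backend runs
`RNAfold -p` (with `--noGU` / `--noCloseGU` mapped from the GU options) and
reads the base-pair probability dot plot; this is the backend to use for
biological work, and the backend version is recorded in `summary.json`.
The `"reference"` backend is a self-contained McCaskill-style
partition-function engine included so that the entire pipeline is testable
and exactly verifiable. Any function `f(seq, t, opts)` returning a
probability vector can be registered with `register_fold_backend()`, which
is how the test suite injects deterministic synthetic profiles.

### The reference engine

The reference engine computes, over all pseudoknot-free structures with a
minimum hairpin loop of 3 unpaired bases, the Boltzmann-weighted pair
probabilities under a deliberately minimal energy model: each allowed pair
type (A-U, G-C, G-U) contributes
$\Delta G(\text{pair}, T) = \Delta H - T \Delta S$ (T in kelvin), with no
stacking or loop terms. The recursions follow the unambiguous grammar

$$Z(i,j) = Z(i{+}1,j) + \sum_{k \ge i+4} Z_b(i,k)\, Z(k{+}1,j), \qquad
  Z_b(i,j) = w(i,j)\, Z(i{+}1,j{-}1),$$

so an inside–outside pass yields exact pair and unpaired probabilities in
$O(L^3)$ time. Correctness is asserted against exhaustive structure
enumeration (`enumerate_structures()`), which agrees with the dynamic
program to better than $10^{-9}$ (observed: $\sim 10^{-15}$) on random
sequences up to 20 nt.

The energy constants (kcal/mol, kcal/mol/K) are

| pair | ΔH | ΔS | melting midpoint ΔH/ΔS |
|------|------|--------|------|
| A-U | −13.6 | −0.0440 | ≈ 309 K (36 °C) |
| G-C | −12.0 | −0.0260 | ≈ 461 K |
| G-U | −10.0 | −0.0360 | ≈ 278 K |

They were chosen once, on physical grounds: G-C far more stable than A-U,
wobble pairs weakest, and the A-U midpoint placed inside the physiological
range so that A,U-rich helices genuinely melt across the default 32–39 °C
scan. The A-U enthalpy is larger than a single-pair calorimetric value on
purpose — the model has no stacking cooperativity, so a steeper per-pair
transition stands in for the cooperative melting of a helix. The reference
engine is a pipeline-contract engine, not a thermodynamic substitute for
ViennaRNA's nearest-neighbour model, and no numeric agreement between the
two backends is claimed.

Numerics: the dynamic-programming tables are kept in extended precision
with a per-base scale factor derived from the maximum-weight structure
(a max-plus pass), which keeps partition functions for sequences of a few
thousand nucleotides in range without log-space arithmetic; a 1000-nt
eight-temperature scan completes in tens of seconds on one core. An
under/overflow raises an error rather than returning garbage.

Two GU options are honoured. `no_gu` removes G-U from the allowed pair set
everywhere. `no_close_gu` ("no G-U at helix ends") is approximated in the
recursion by admitting a G-U pair only when it stacks directly on the pair
immediately inside it ($Z_b(i,j) = w(i,j) Z_b(i{+}1,j{-}1)$ for G-U); the
enumeration oracle implements the exact either-side stacking rule. The two
therefore differ for G-U pairs stacked only outward; the discrepancy is
confined to the reference engine, and the `"vienna"` backend delegates to
RNAfold's own semantics.

## Difference data set and outlier model

The difference direction is $d = p_{\text{higher}} - p_{\text{lower}}$, so
a melting helix produces negative values, matching the "decrease their
probability to be paired with temperature elevation" reading of the output
tables. The base-vs-base row ($t_1$ vs $t_1$, identically zero) is *not*
part of the combined set — hence $7000 = 7 \times 1000$, not 8000, in the
worked example.

The standard deviation uses the population convention (divisor $n$): the
combined set is the complete population of computed differences, not a
sample from a larger one, and at $n \approx 7000$ the choice is numerically
immaterial — it is fixed so results are reproducible bit for bit. A
perfectly temperature-insensitive input has $\sigma = 0$ and yields zero
significant positions (rather than all, or an error). In two-sequence
mode each sequence gets its own $\mu, \sigma$ — each has its own histogram.

Note the threshold is *relative*: positions are outliers against the
sequence's own difference distribution. A sequence where everything melts
equally reports nothing, by design.

## Clustering

DBSCAN is run on the 1-D integer positions with distance $|a-b|$. A
position is a core point when at least MinPts input positions (itself
included — the common convention) lie within $\varepsilon$. Two departures
from a textbook randomized DBSCAN were made deliberately:

* Seed points are visited in ascending position order, never randomly.
  This removes DBSCAN's only order dependence — a border point reachable
  from two clusters goes to the cluster discovered first (leftmost) — and
  makes every run reproducible. One consequence worth knowing: when such a
  tie occurs, the losing cluster can end up with fewer than MinPts
  *members*, although it always retains a core point.
* Clustering by default uses only the significant positions of the top
  temperature difference; `cluster_all_temperatures = TRUE` clusters the
  union over all elevated temperatures instead.

Equivalence with a brute-force DBSCAN (explicit neighbourhood enumeration,
connected components, first-cluster border assignment) is asserted over
hundreds of random instances. The sliding-window density profile uses a
window of $2\varepsilon + 1$ positions moved in steps of one; a sequence
shorter than the window falls back to a single full-sequence window.

## Two-sequence comparison

Both sequences are analysed with identical parameters (enforced by
construction: one `run_config` drives both). Per elevated temperature,
positions significant in both are *shared*; the rest are
*sequence-specific* — the per-row classification mirrors the annotated
alignment output, where each temperature row is coloured by its own
$t$-vs-$t_1$ comparison. A cluster is sequence-specific when its
$[\text{start}, \text{end}]$ span shares **no** position with any cluster
span of the other sequence; overlap means span intersection of at least one
position. Spans rather than member sets are used so that "no overlap" is
well defined even when member sets interleave sparsely. The onset
temperature of a position is the lowest elevated temperature at which it is
flagged; a cluster's onset is the minimum over its members.

## In-silico mutagenesis

With $N$ substitutions separating the inputs, the mutant set consists of
derivatives of the *first* sequence carrying exactly $N$ substitutions
each (default 100 mutants; the data-set size is not dictated by the method,
only that per-cluster frequencies of order 1% be resolvable).

* **Coding regime** (default): synonymous single-base codon changes only,
  standard genetic code, frame 1 from position 1. Within one mutant the
  substitutions target *distinct codons*: two individually synonymous
  changes in the same codon are not always jointly synonymous, so distinct
  codons guarantee both exact Hamming distance $N$ and identical protein.
  Synonymous options are sampled uniformly.
* **Non-coding regime**: substitutions at distinct uniformly random
  positions, with each from→to type drawn from the substitution spectrum
  observed between the inputs (a type is rejection-resampled when no
  eligible position carries its from-base; a spectrum that can never be
  placed errors out after bounded retries).

Mutants are sampled independently; duplicate mutants are permitted.
Generation is a pure function of (parent, parameters, seed) and leaves the
caller's RNG stream untouched. A parent admitting no synonymous change
(e.g. built of AUG/UGG codons) makes the coding regime infeasible; in the
full pipeline this surfaces as a warning and the statistical stage is
skipped rather than failing the run.

## Statistics

Every mutant is run through the identical pipeline, giving one cluster
list per mutant. For a sequence-specific cluster, $k$ of $n$ mutants have
at least one cluster overlapping it (≥ 1 position). The hypotheses are
composite ("the probability to observe this cluster is < 95%" for a
cluster present in the first sequence only; "≥ 5%" for one present only in
the second), and the tests are computed at the boundary, the standard
treatment of composite one-sided nulls:

* *disappear* (present in 1, absent in 2):
  $p = \sum_{x=k}^{n} \binom{n}{x} 0.95^x\, 0.05^{\,n-x}$ — small $p$
  means the cluster is unlikely to disappear by chance;
* *appear* (present in 2, absent in 1):
  $p = \sum_{x=0}^{k} \binom{n}{x} 0.05^x\, 0.95^{\,n-x}$ — small $p$
  means the cluster is unlikely to appear by chance.

The two are mirror images: the appear test at $k$ equals the disappear
test at $n-k$. The 95% interval on $k/n$ is the two-sided Clopper–Pearson
interval (the exact interval of the standard binomial test; no interval
type is dictated by the method, so the exact one was chosen). No
multiple-testing correction is applied across clusters — p-values are
reported per cluster, and the table-building function emits a note when
more than one cluster is tested so users can correct as they see fit.

## Designed fixtures: what they do and do not show

`make_fixture()` builds sequences whose behaviour under the *reference*
engine is provable from the model:

* `stable-hairpin`: a G/C stem in adenine padding — G can only pair its
  designed C partners, so stem pairing stays above 0.9 across the range.
* `melting-hairpin`: an A-run/U-run element in cytosine padding. Cytosine
  pairs only G, of which there are none, so the element pairs exclusively
  within itself, and every A-U contact melts across 32–39 °C; its
  top-difference values exceed $3\sigma$ of the combined set.
* `pair-with-specific-cluster`: the element is sized so its significant
  positions (two A's + three U's) sit exactly at MinPts; removing one U in
  the second sequence drops it below clusterability, leaving the first
  sequence with a sequence-specific cluster and a statistical-table row.
* `pair-with-neutral-substitution`: a padding C→G far from the element
  pairs other padding positions stably and changes no significance call.

These fixtures emulate the *logic* of real temperature-sensitive elements
(an element melting coherently against a quiet background) but none of the
texture of real RNA: no stacking cooperativity, no loop entropies, no
competing long-range structure, and a background engineered to be inert.
Tests passing on them validate the pipeline's bookkeeping and statistics,
not the thermodynamic accuracy of predictions on biological sequences —
for that, use the `"vienna"` backend, and interpret results with the usual
caveats of equilibrium secondary-structure prediction (no pseudoknots, no
tertiary contacts, no kinetics).

## Degenerate inputs and numerical choices

* Sequences with no legal pair (homopolymers, 4-mers) give all-zero
  probability vectors, an empty significant set, and a "no clusters
  identified" marker — not an error.
* $\sigma = 0$ ⇒ no significant positions; identical inputs ⇒ mutant stage
  skipped with a notice; infeasible mutagenesis ⇒ warning, tests skipped.
* Backend outputs are validated (length, finiteness, $[0,1]$ within
  $10^{-9}$) and clamped at the boundary.
* All reported coordinates are 1-based and inclusive.
* Problem sizes used by the checks: oracle equivalence on 50 random
  sequences ≤ 20 nt at 3 temperatures; DBSCAN equivalence on 500 random
  instances (≤ 40 points on lines ≤ 300); binomial tests for all
  $k \le n \le 200$; 1000 synonymous mutants of a 300-nt parent at
  $N = 5$; end-to-end pair analyses at $L = 120$ with 20–100 mutants.
  These sizes make the whole suite run in a couple of minutes while
  leaving each property's space densely covered.

## Known limitations

* The reference engine's energy model is minimal by design; its `no_close_gu`
  is an inward-stacking approximation (exact in the enumeration oracle).
* Memory for the inside–outside tables grows as $O(L^2)$ extended-precision
  entries; sequences near the 9999-nt input cap are better served by the
  `"vienna"` backend.
* Mutants are generated for the first sequence only, and both test
  directions are evaluated against that one ensemble.
* DBSCAN parameters are taken as given; no automatic $\varepsilon$
  selection is attempted.
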
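---
title: "Causal analysis of multi-valued discrete networks with multiphi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal analysis of multi-valued discrete networks with multiphi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiphi)
```

## The problem

Discrete logical models of biological systems -- gene regulatory circuits,
simple neural networks, cellular automata -- are usually analysed with
Boolean tools, yet many systems need elements with more than two functional
states: a protein acting on different targets above different activity
thresholds, or a neuron that can stay silent, spike, or burst.  `multiphi`
implements the causal-analysis framework of integrated information theory
(IIT) for discrete Markovian dynamical systems whose elements have
arbitrary finite state counts.  It answers two questions about a system in
a state: *which subsets of elements irreducibly constrain the system's
past and future* (the cause--effect structure, CES), and *how irreducible
is the system as a whole to its parts* (integrated information,
$\Phi$).  Alongside, it implements the standard Boolean conversions of
multi-valued logical models (Van Ham, Faur&eacute;--Kaji, Tonello) and
coarse-graining in the opposite direction, so that the causal faithfulness
of binarization can be studied quantitatively.

## System representation

A network of $n$ nodes with $S_i$ states each is represented
state-by-state: an $S \times S$ row-stochastic transition probability
matrix (TPM) with $S = \prod_i S_i$, plus the vector of per-node state
counts, which is what disambiguates, say, four binary nodes from two
quaternary nodes over the same 16-state matrix.  States are indexed
mixed-radix little-endian (the first node varies fastest); the convention
is fixed package-wide and in the file formats, and `encodeState()` /
`decodeState()` expose it.

Causal analysis requires that nodes be conditionally independent given the
previous system state, i.e. that each TPM row factorize into per-node
conditionals (`nodeConditionals()`).  The factorization is exact for every
deterministic TPM; for probabilistic input it is checked by
`checkConditionalIndependence()` against an absolute tolerance (default
`1e-10`, configurable).  Rows are renormalized only when they are within
`1e-6` of 1 -- anything worse is rejected, because silently rescaling
corrupted probabilities hides data errors.  An adjacency matrix is never
required: `inferAdjacency()` recovers parent relations by probing pairs of
prior states that differ in a single node.

## Repertoires, mechanisms, and $\varphi$

A *mechanism* is a node subset in its current sub-state; a *purview* is a
node subset over whose states the mechanism's constraint is evaluated.
The *effect repertoire* is the product over purview nodes of their
next-state conditionals, conditioned on the mechanism's state with all
other inputs marginalized under the uniform (maximum-entropy perturbation)
distribution.  The *cause repertoire* inverts the dynamics by Bayes' rule
under a uniform prior; for multi-node mechanisms each mechanism node's
likelihood is marginalized onto the purview first and the marginals are
then multiplied ("virtual-element" decomposition).  This differs from a
joint inversion only for multi-node mechanisms; we evaluated both
conventions against the published survey statistics for random
deterministic classes and retained the virtual-element form, which
reproduces them more closely (see *Calibration* below).  A mechanism state
that no prior state can produce specifies no cause: the repertoire is
flagged *null* and its $\varphi$ is 0 rather than an error.

Irreducibility is measured with the absolute intrinsic difference (AID)
between the unpartitioned repertoire $p$ and a partitioned one $q$:

$$\mathrm{AID}(p, q) \;=\; \max_s \; p(s)\,\bigl|\log_2 p(s) / q(s)\bigr|,$$

whose maximizing state is reported as the *specified state* of the
mechanism.  Terms with $p(s) = 0$ contribute nothing; $q(s) = 0 < p(s)$
contributes $+\infty$ by default (a partition that destroys full
determination), with an optional finite cap (`phiConfig(phiCap = )`) for
numerical robustness in downstream statistics.  The measure sits behind
`aid()` so an alternative could be swapped in; no alternative ships,
because the earth-mover's distance used historically for binary systems
has no canonical multi-valued counterpart here.

Candidate partitions are *tripartitions*: assignments of each mechanism
node and each purview node to one of three part slots, deduplicated under
slot permutation and excluding the identity assignment
(`enumerateTripartitions()`, enumerated as restricted growth strings in
lexicographic order).  A part with an empty mechanism contributes the
unconstrained repertoire over its purview; a part with an empty purview
contributes the scalar 1; a part empty on both sides is simply an unused
slot, so partitions into two parts (including the full cut) are contained
in the family.  $\varphi$ of a mechanism over a purview is the minimum AID
over this family; ties keep the first partition in enumeration order.  The
maximally irreducible cause or effect (`mice()`) maximizes $\varphi$ over
all non-empty purviews, preferring the largest and then the
lexicographically first purview on ties -- the tie-breaks are arbitrary
but must be deterministic for reproducibility.  A mechanism whose cause
and effect are both irreducible forms a *distinction* with
$\varphi = \min(\varphi_c, \varphi_e)$.

The partition minimization is the computational hot spot (for an
$m$-node mechanism and $z$-node purview there are up to
$\{m+z \brace \le 3\}$ candidate partitions, each requiring a product of
part repertoires over the purview's joint states); it is implemented in
C++ with repertoires cached per (mechanism, purview) pair.

## System level: CES, cuts, $\Phi$

`computeCes()` evaluates every non-empty mechanism (ascending bitmask
order) and keeps the distinctions with $\varphi > 0$; a system of $N$
nodes therefore has at most $2^N - 1$ distinctions.  System cuts are
unidirectional bipartitions: `applyCut(net, from, to)` replaces the inputs
that `to`-nodes receive from `from`-nodes by independent uniform noise
(conditionals averaged over the severed sources), leaving all other
dependencies intact -- $2^n - 2$ ordered cuts in total.  Under a cut only
the intact CES's mechanisms are re-evaluated (purviews re-searched); cuts
are assumed not to create new distinctions.  The loss of a cut is the
absolute sum of per-distinction $\varphi$ differences, with destroyed
distinctions contributing their full intact $\varphi$, and

$$\Phi \;=\; \min_{\text{cuts}} \sum_{d \in \mathrm{CES}}
\bigl|\varphi_d - \varphi_d^{\text{cut}}\bigr|.$$

No normalization by part sizes is applied, keeping $\Phi$ in $\varphi$
units.  Single-node systems admit no cut and have $\Phi = 0$ by
definition.  `sia()` refuses unreachable states (all-zero TPM column) by
default, advising a state drawn from the TPM's successors; the survey
drivers opt into `unreachable = "zero"`, because an unreachable state
specifies no causes and hence an empty CES.  `majorComplex()` searches all
subsystems, freezing external nodes at their current state as background
conditions; ties prefer the larger subsystem.

## Binarization of multi-valued models

For a deterministic evolution function (`evolutionFunction()`), the Van
Ham scheme replaces an $m$-state component by $m-1$ ordered Boolean
constituents, value $k$ encoded as $k$ ones followed by zeros.  The
resulting binary table is only partial: binary states without a
multi-valued pre-image ("non-admissible") have no successor, so a proper
causal model requires one of $S^{\,k}$ completions for $k$ missing rows.
The Faur&eacute;--Kaji construction extends the map to every binary state
for *asymptotic* functions (each component either holds, jumps to its
maximum, or drops to zero): the coarse value of a constituent group is the
sum of its bits, the original function is applied to the coarse state, and
targets are written back as all-zeros, all-ones, or -- for a maintained
non-saturated value -- unchanged bits.  That last branch is the only
reading consistent with totality and with the exact coarse-graining
round-trip (`coarseGrain()` with the bit-sum state map reconstructs the
original function; this is tested property-style over random asymptotic
functions).  The Tonello construction instead steps each component's
coarse value one level toward its target and writes the stepped value in
canonical Van Ham form; it reproduces the published p53--Mdm2 table
bit-for-bit (golden-file test).  Beyond such models its fine structure is
under-determined by the sources available to us -- in particular how
non-canonical bit patterns should be preserved under a "maintain" step --
so the implementation is documented as best-effort and guarded by the
golden files.  A probabilistic variant (`probabilisticBinarization()`)
that splits intermediate values uniformly over equal-sum bit patterns is
provided as a clearly labelled conjectural tool for coarse-graining
studies; its output violates per-node conditional independence and is not
a valid causal model for the analysis pipeline.

## Synthetic data: what the generators emulate

`randomDeterministicNet()` draws, for each state, a successor uniformly
from all $S$ states -- the minimal reading of "randomly generated
deterministic TPM", with no bias toward sparse wiring or canalization.
`randomAsymptoticFunction()` draws each component's target uniformly from
the collapsed set $\{0, \text{current}, \text{max}\}$.  The three-neuron
toy circuits implement "fire if any other neuron fired and you are not
refractory", with a burst probability of 0.2 per firing event in the
ternary reading (the study condition; any value in $[0,1]$ is accepted)
and a deterministic binary reading that merges the two firing modes.
These generators emulate the *dynamics* classes of the surveys, not real
regulatory data: uniform random maps have no modular topology, no
canalizing functions, and dense effective connectivity, so conclusions
drawn from them say how the measures behave on generic discrete dynamics,
not how real gene networks score.

One calibration choice deserves emphasis: survey states are sampled
uniformly from the *reachable* states of each network (those with nonzero
TPM column mass).  Unreachable states specify no causes and would
contribute empty CESs; including them would make the published per-class
mean CES sizes unattainable (for uniform random maps over $S$ states,
roughly $(1-1/S)^S \approx 37\%$ of states are unreachable), and the
analysis of an unreachable state is an error in the reference tooling.
The binarization-correlation driver instead evaluates "the first state in
the TPM" (the all-zero state, whose Van Ham image is again all zeros) and
maps unreachable cases to $\Phi = 0$.

## Calibration and problem sizes

The test suite and the acceptance script rerun the surveys at reduced
sizes chosen as a compromise between sampling error and runtime on a
single CPU: 200 networks per 2--3-node class (the published surveys use
1000), 100 per four-node class before pooling, and 100 random asymptotic
functions for the binarization correlation.  At these sizes the
bootstrapped standard error of a mean CES size is 1--3%.  Against the
published per-class means our implementation reproduces class 333 exactly
(100% of the maximal 7 distinctions) and sits 2--4% high on the
binary-heavy classes; we attribute the residual to unpublished details of
the reference implementation's partition family and difference measure
(its defining description was unpublished at the time of the survey), and
the tests assert a 5% relative band.  The qualitative orderings -- more
elements raise $\Phi$ and lower mean $\varphi$, more states per element
raise both -- are asserted directly, as is the exact equality of effective
information within shared-TPM pairs.

## Numerical choices and degenerate inputs

* Row sums and factorization: absolute tolerance `1e-10`; input rows
  renormalized only within `1e-6` of 1.
* $\varphi$ ties: first partition in enumeration order; specified-state
  ties: first state in little-endian order; purview ties: largest, then
  lexicographic; system-cut ties: ascending bitmask of the severed source
  part; complex ties: larger subsystem, then lexicographic.
* Infinite AID terms are kept by default ($\Phi$ then propagates the
  determination loss); `phiCap` bounds them when finite statistics are
  needed.  The minimizing partition always exists finitely for valid
  repertoires because the full cut compares against an unconstrained
  repertoire whose support covers the constrained one.
* Single-node networks are allowed ($\Phi = 0$, at most one distinction);
  empty purviews yield the scalar repertoire 1; empty mechanisms yield
  unconstrained repertoires.

## Known limitations

* Cost is exponential in the node count (mechanisms, purviews, partitions
  and cuts all enumerate subsets); 5--6 nodes is comfortable, beyond that
  runtimes grow quickly.  The state count matters only polynomially.
* Relations among distinctions are not computed; $\Phi$ rests on the
  small-$\varphi$ difference alone.
* Only Markovian systems in state-by-state form are supported; the
  state-by-node import shim covers binary systems only.
* The Tonello construction is validated on p53-like models (components
  stepping one level at a time); its generalization to components with
  many levels is not canonical.
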
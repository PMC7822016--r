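# multiphi

Causal analysis of discrete dynamical systems with **multi-valued
elements** in the integrated information theory (IIT) framework.

Logical models of regulatory circuits and small neural networks often need
elements with more than two states — a protein acting on different targets
above different activity thresholds, a neuron that is silent, spiking, or
bursting. `multiphi` computes, for such systems, the **cause–effect
structure** (CES: the set of mechanisms that irreducibly constrain the
system's past and future, each with its integrated information φ) and the
system-level **integrated information Φ**, directly from a state-by-state
transition probability matrix (TPM) plus the number of states of each
element. It also implements the standard Boolean conversions of
multi-valued models — **Van Ham** (partial), **Fauré–Kaji** (total, for
asymptotic functions), **Tonello** (total, stepwise) — together with
**coarse-graining** back to the multi-valued model, and batch drivers for
random-network surveys, so that the causal faithfulness of binarization can
be studied quantitatively.

## The quantities

For a mechanism $M$ in its current state and a purview $Z$, cause and
effect repertoires are distributions over $Z$'s states obtained by
conditioning/inverting the TPM with all unconstrained inputs marginalized
uniformly. Irreducibility is the **absolute intrinsic difference** between
the intact repertoire $p$ and the best tripartitioned one $q$:

$$\varphi \;=\; \min_{\text{tripartitions}} \; \max_s \; p(s)\,\bigl|\log_2 p(s)/q(s)\bigr|$$

A mechanism with irreducible cause *and* effect forms a distinction with
$\varphi = \min(\varphi_c, \varphi_e)$; the CES collects all of them. The
system's integrated information is the φ lost under the least destructive
unidirectional bipartition cut:

$$\Phi \;=\; \min_{\text{cuts}} \sum_{d \in \mathrm{CES}} \bigl|\varphi_d - \varphi_d^{\mathrm{cut}}\bigr|$$

States are indexed mixed-radix **little-endian** (first node fastest)
everywhere, including the file formats.

## Worked example: the p53–Mdm2 network

The ternary-protein regulatory model (P = p53 with 3 activity levels,
Mc/Mn = cytoplasmic/nuclear Mdm2, binary) ships as a truth-table fixture:

```r
library(multiphi)
net <- p53Model()
net
#> NetworkModel: 3 nodes, 12 states (deterministic)
#>   nodes: P[3] Mc[2] Mn[2]

inferAdjacency(net)      # wiring recovered from the TPM alone
#>    P Mc Mn
#> P  0  1  1
#> Mc 0  0  1
#> Mn 1  0  0

sia(net, c(0, 0, 1))     # causal analysis at the attractor state
#> SIA: subsystem {1,2,3}, state (0,0,1)
#>   Phi = 0.292481 over 3 distinction(s) (sum phi 1.31617)
#>   minimum cut: {1,3} -/-> {2}
```

All three distinctions are first-order (single elements) — the model's
composition is flat. Its Boolean translations are not equivalent: the
Fauré–Kaji conversion keeps a first-order CES and can be coarse-grained
back to the original exactly, while the Tonello conversion introduces
higher-order mechanisms:

```r
f  <- p53Function()
vanHam(f)                          # defines only 12 of 16 binary states
tn <- networkFromFunction(tonello(f)@binaryFunction)
table(sapply(distinctions(computeCes(tn, c(0, 0, 0, 1))),
             function(d) length(d@mechanism)))
#> 1 2 3
#> 4 5 3

fk  <- faureKaji(f)
mac <- coarseGrain(networkFromFunction(fk@binaryFunction), fk@groups,
                   lapply(fk@groups, function(g) sumStateMap(length(g))))
identical(tpm(mac), tpm(net))
#> [1] TRUE
```

A command-line front end over the same functions is installed at
`system.file("scripts", "multiphi-cli.R", package = "multiphi")`
(`validate`, `sia`, `ces`, `binarize`, `survey`, `binarize-corr`).

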
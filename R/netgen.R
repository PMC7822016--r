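#' Parse a network class label
#'
#' Class labels name one node per digit, the digit giving that node's
#' number of states: `"33"` is two ternary nodes, `"2235"` four nodes with
#' 2, 2, 3 and 5 states.  A parenthesized suffix, as in `"44(2222)"`,
#' marks a class that shares its TPMs with the bracketed class (the
#' state-space sizes must agree).
#'
#' @param label character class label.
#' @return list with `radices`, `label`, and `sharedWith` (radices of the
#'   TPM-sharing class, or `NULL`).
#' @export
classLabel <- function(label) {
  m <- regmatches(label, regexec("^([2-9]+)(?:\\(([2-9]+)\\))?$", label))[[1]]
  if (length(m) == 0L || m[1] == "")
    stop("malformed class label: ", label)
  radices <- as.integer(strsplit(m[2], "")[[1]])
  shared <- if (nzchar(m[3])) as.integer(strsplit(m[3], "")[[1]]) else NULL
  if (!is.null(shared) && prod(shared) != prod(radices))
    stop("shared class ", m[3], " has a different state-space size")
  list(radices = radices, label = label, sharedWith = shared)
}

#' Random deterministic network
#'
#' Draws, for each of the `S` states, a successor uniformly from the `S`
#' states, giving an exact 0/1 row-stochastic TPM.  For a shared-TPM label
#' such as `"44(2222)"` the matrix is drawn for the bracketed class and
#' reinterpreted over the label's own radices, so equal seeds give the
#' paired classes identical matrices.
#'
#' @param label a class label string (see [classLabel()]) or an integer
#'   vector of radices.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return a deterministic [NetworkModel-class].
#' @export
randomDeterministicNet <- function(label, seed = NULL) {
  cl <- if (is.character(label)) classLabel(label)
        else list(radices = as.integer(label), sharedWith = NULL)
  .withSeed(seed, {
    r <- if (is.null(cl$sharedWith)) cl$radices else cl$sharedWith
    S <- prod(r)
    succ <- sample.int(S, S, replace = TRUE) - 1L
    net <- networkFromFunction(evolutionFunction(r, succ))
    if (is.null(cl$sharedWith)) net else reinterpretNet(net, cl$radices)
  })
}

#' Random asymptotic evolution function
#'
#' For every state and component, the target is drawn uniformly from the
#' set `{0, current value, maximum}` (duplicates collapse, so a component
#' currently at 0 picks uniformly between staying at 0 and jumping to its
#' maximum).  The result is always asymptotic.
#'
#' @param radices integer vector of per-component state counts.
#' @param seed optional integer seed.
#' @return an [EvolutionFunction-class].
#' @export
randomAsymptoticFunction <- function(radices, seed = NULL) {
  radices <- as.integer(radices)
  S <- prod(radices)
  .withSeed(seed, {
    succ <- vapply(0:(S - 1L), function(s) {
      cur <- decodeState(s, radices)
      nxt <- vapply(seq_along(radices), function(i) {
        opts <- unique(c(0L, cur[i], radices[i] - 1L))
        opts[sample.int(length(opts), 1L)]
      }, integer(1))
      encodeState(nxt, radices)
    }, integer(1))
    evolutionFunction(radices, succ)
  })
}

#' The p53-Mdm2 regulatory network model
#'
#' The asymptotic evolution function of the three-component p53-Mdm2
#' model: P (protein p53, ternary: inactive / active below / active above
#' the second threshold), Mc (cytoplasmic Mdm2) and Mn (nuclear Mdm2),
#' both binary.  Mn degrades P; P up-regulates Mc and inhibits the nuclear
#' import of Mdm2; Mc feeds Mn.  The function is shipped as a truth-table
#' fixture and defines a deterministic 12 x 12 TPM.
#'
#' @return [p53Model()] a [NetworkModel-class]; [p53Function()] the
#'   underlying [EvolutionFunction-class].
#' @examples
#' net <- p53Model()
#' inferAdjacency(net)
#' @export
p53Model <- function() networkFromFunction(p53Function())

#' @rdname p53Model
#' @export
p53Function <- function() {
  path <- system.file("extdata", "p53_evolution.tsv", package = "multiphi",
                      mustWork = TRUE)
  readEvolutionTable(path)
}

#' Three-neuron toy circuits with graded firing
#'
#' Each neuron fires iff at least one of the other two fired in the
#' previous step and it is not refractory (it did not itself fire, i.e.
#' its current state is 0).  In the ternary variant a firing neuron emits
#' a burst (state 2) with probability `pBurst` and a single spike (state
#' 1) otherwise; the binary variant only distinguishes firing (1) from
#' silence (0), merging the two firing modes, which makes it deterministic
#' (`pBurst` is accepted for symmetry and ignored).  Both TPMs are exact
#' products of per-neuron conditionals.
#'
#' @param pBurst burst probability in `[0, 1]` (default 0.2).
#' @return a [NetworkModel-class] with 3 nodes.
#' @export
ternaryNeuronModel <- function(pBurst = 0.2) {
  stopifnot(pBurst >= 0, pBurst <= 1)
  .neuronModel(3L, pBurst)
}

#' @rdname ternaryNeuronModel
#' @export
binaryNeuronModel <- function(pBurst = 0.2) {
  .neuronModel(2L, pBurst)
}

.neuronModel <- function(k, pBurst) {
  r <- rep(k, 3L)
  S <- prod(r)
  digits <- .stateDigits(r)
  conds <- lapply(1:3, function(i) {
    Ti <- matrix(0, S, k)
    for (h in seq_len(S)) {
      v <- digits[, h]
      fires <- v[i] == 0L && any(v[-i] >= 1L)
      if (!fires) Ti[h, 1] <- 1
      else if (k == 2L) Ti[h, 2] <- 1
      else { Ti[h, 2] <- 1 - pBurst; Ti[h, 3] <- pBurst }
    }
    Ti
  })
  NetworkModel(.tpmFromConditionals(conds, r), r,
               labels = paste0("N", 1:3))
}
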
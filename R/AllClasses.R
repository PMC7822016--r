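setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' NetworkModel: a discrete dynamical system in state-by-state form
#'
#' A network of `n` nodes, each with `numStates[i] >= 2` states, whose
#' dynamics are given by an `S x S` row-stochastic transition probability
#' matrix (TPM) with `S = prod(numStates)`.  Rows index the state at time
#' `t`, columns the state at `t + 1`, both in mixed-radix little-endian
#' order (first node varies fastest, see [encodeState()]).
#'
#' Validity enforces shape, row sums (within 1e-10 after an at-most-1e-6
#' renormalization performed by the constructor) and entries in `[0, 1]`.
#' Conditional independence across nodes (the Markov factorization of each
#' row into per-node conditionals) is a modelling assumption checked by
#' [validateNetwork()] / [checkConditionalIndependence()], not by the
#' validity method, so that deliberately non-factorizable matrices can be
#' constructed and inspected.
#'
#' @slot labels character vector of unique node labels.
#' @slot numStates integer vector of per-node state counts.
#' @slot tpm numeric `S x S` matrix.
#' @slot adjacency optional `n x n` binary matrix; `adjacency[j, i] = 1`
#'   means node `j` is a parent of (an input to) node `i`.
#' @seealso [NetworkModel()], [validateNetwork()], [sia()]
#' @export
setClass("NetworkModel",
  slots = c(labels = "character", numStates = "integer",
            tpm = "matrix", adjacency = "matrixOrNULL"))

setValidity("NetworkModel", function(object) {
  msgs <- character()
  n <- length(object@numStates)
  if (n < 1L) msgs <- c(msgs, "network must have at least one node")
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels and numStates lengths differ")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "node labels must be unique")
  if (any(object@numStates < 2L))
    msgs <- c(msgs, "every node must have at least 2 states")
  S <- prod(object@numStates)
  if (!all(dim(object@tpm) == c(S, S)))
    msgs <- c(msgs, sprintf("tpm must be %d x %d (prod of per-node states)",
                            S, S))
  else {
    if (any(object@tpm < -1e-12) || any(object@tpm > 1 + 1e-12))
      msgs <- c(msgs, "tpm entries must lie in [0, 1]")
    rs <- rowSums(object@tpm)
    if (any(abs(rs - 1) > 1e-10))
      msgs <- c(msgs, sprintf("tpm rows must sum to 1 (worst deviation %.3g)",
                              max(abs(rs - 1))))
  }
  if (!is.null(object@adjacency) &&
      !all(dim(object@adjacency) == c(n, n)))
    msgs <- c(msgs, "adjacency must be n x n")
  if (length(msgs)) msgs else TRUE
})

#' Repertoire: a probability distribution over the states of a purview
#'
#' Cause and effect repertoires are distributions over the joint states of a
#' node subset (the purview), indexed little-endian over the purview's
#' radices in ascending node order.  The empty purview has the scalar
#' repertoire 1.  A "null" cause repertoire (all-zero, arising when the
#' mechanism state is unreachable) is flagged by `isNull`.
#'
#' @slot purview integer vector of node indices (ascending; may be empty).
#' @slot radices integer vector of the purview nodes' state counts.
#' @slot probs numeric vector of length `prod(radices)` (length 1 for the
#'   empty purview).
#' @slot isNull logical flag for the null (unreachable-state) repertoire.
#' @export
setClass("Repertoire",
  slots = c(purview = "integer", radices = "integer",
            probs = "numeric", isNull = "logical"),
  prototype = list(isNull = FALSE))

setValidity("Repertoire", function(object) {
  L <- max(1L, prod(object@radices))
  if (length(object@probs) != L)
    return("probs length does not match purview radices")
  if (!object@isNull && abs(sum(object@probs) - 1) > 1e-10)
    return("repertoire must sum to 1 (unless null)")
  TRUE
})

#' Mice: a maximally irreducible cause or effect
#'
#' The result of maximizing mechanism-level integrated information (phi)
#' over candidate purviews in one temporal direction.
#'
#' @slot direction `"cause"` or `"effect"`.
#' @slot purview integer vector: the winning purview (node indices).
#' @slot repertoire the unpartitioned [Repertoire-class] over that purview.
#' @slot phi non-negative numeric: irreducibility under the minimum
#'   information tripartition.
#' @slot specifiedState integer vector: the purview state at which the
#'   intrinsic difference is maximal.
#' @slot partition list of three `(mechanism, purview)` parts: the
#'   minimizing tripartition.
#' @export
setClass("Mice",
  slots = c(direction = "character", purview = "integer",
            repertoire = "Repertoire", phi = "numeric",
            specifiedState = "integer", partition = "list"))

#' Distinction: a mechanism with its maximally irreducible cause and effect
#'
#' @slot mechanism integer vector of node indices (non-empty).
#' @slot mechState integer vector: the mechanism nodes' current values.
#' @slot cause,effect [Mice-class] objects.
#' @slot phi `min(cause phi, effect phi)`, strictly positive for a
#'   distinction that enters a CES.
#' @export
setClass("Distinction",
  slots = c(mechanism = "integer", mechState = "integer",
            cause = "Mice", effect = "Mice", phi = "numeric"))

#' CES: the cause-effect structure of a system in a state
#'
#' The set of causal distinctions specified by all mechanisms with phi > 0,
#' in canonical mechanism order (ascending bitmask).  A system of `N` nodes
#' has at most `2^N - 1` distinctions.
#'
#' @slot distinctions list of [Distinction-class] objects.
#' @slot sumPhi sum of distinction phi values.
#' @slot state the system state analysed (integer vector).
#' @slot labels node labels of the analysed system.
#' @export
setClass("CES",
  slots = c(distinctions = "list", sumPhi = "numeric",
            state = "integer", labels = "character"))

#' SIAResult: system irreducibility analysis output
#'
#' Holds the integrated information `Phi` of a (sub)system in a state, the
#' minimum information cut, the intact CES and the per-distinction phi
#' values under that cut.
#'
#' @slot subsystem integer vector of node indices analysed.
#' @slot state full-system state (integer vector).
#' @slot bigPhi non-negative numeric; 0 iff some cut loses no phi.
#' @slot cutFrom,cutTo the minimal unidirectional cut: connections from
#'   `cutFrom` to `cutTo` are severed (empty for single-node systems).
#' @slot ces the intact [CES-class].
#' @slot partitionedPhis numeric vector: each distinction's phi recomputed
#'   under the minimal cut.
#' @export
setClass("SIAResult",
  slots = c(subsystem = "integer", state = "integer", bigPhi = "numeric",
            cutFrom = "integer", cutTo = "integer", ces = "CES",
            partitionedPhis = "numeric"))

#' EvolutionFunction: a deterministic multi-valued update function
#'
#' A total map on the mixed-radix state space: `successor[s + 1]` is the
#' 0-based successor index of state `s` (little-endian indexing as
#' everywhere in the package).
#'
#' @slot labels character vector of component labels.
#' @slot radices integer vector of per-component state counts.
#' @slot successor integer vector of length `prod(radices)`; entries may be
#'   `NA` only in partial tables produced by the Van Ham binarization.
#' @export
setClass("EvolutionFunction",
  slots = c(labels = "character", radices = "integer",
            successor = "integer"))

setValidity("EvolutionFunction", function(object) {
  S <- prod(object@radices)
  if (length(object@successor) != S)
    return("successor must have one entry per state")
  ok <- is.na(object@successor) |
    (object@successor >= 0L & object@successor < S)
  if (!all(ok)) return("successor indices out of range")
  if (length(object@labels) != length(object@radices))
    return("labels and radices lengths differ")
  TRUE
})

#' BinarizationResult: a Boolean conversion of a multi-valued function
#'
#' @slot method `"van_ham"`, `"faure_kaji"` or `"tonello"`.
#' @slot binaryFunction [EvolutionFunction-class] over all-binary radices;
#'   partial (NA successors on non-admissible states) for Van Ham.
#' @slot admissible logical vector over binary states: has a multi-valued
#'   pre-image under the Van Ham state correspondence.
#' @slot stateToBinary integer vector: 0-based binary index of each
#'   multi-valued state (the Van Ham embedding; a bijection onto the
#'   admissible states).
#' @slot groups list mapping each original component to the indices of its
#'   binary constituents.
#' @slot original the input [EvolutionFunction-class].
#' @export
setClass("BinarizationResult",
  slots = c(method = "character", binaryFunction = "EvolutionFunction",
            admissible = "logical", stateToBinary = "integer",
            groups = "list", original = "EvolutionFunction"))
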
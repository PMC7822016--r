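#' Construct a NetworkModel
#'
#' Builds a [NetworkModel-class] from a state-by-state TPM and the per-node
#' state counts.  Rows are normalized only when their sums deviate from 1 by
#' at most 1e-6; larger deviations are rejected rather than silently
#' rescaled, since they usually indicate corrupted input.
#'
#' @param tpm numeric `S x S` matrix, `S = prod(numStates)`; rows index the
#'   current state, columns the next state, little-endian state order.
#' @param numStates integer vector of per-node state counts (each >= 2).
#' @param labels optional character vector of node labels (default
#'   `n1, n2, ...`).
#' @param adjacency optional `n x n` binary matrix (`[j, i] = 1` iff node j
#'   is an input of node i); checked against the TPM-inferred adjacency by
#'   [validateNetwork()].
#' @return a [NetworkModel-class] object.
#' @examples
#' # a node that copies itself and one that negates the first
#' f <- function(s) c(s[1], 1 - s[1])
#' tpm <- matrix(0, 4, 4)
#' for (s in 0:3) {
#'   v <- decodeState(s, c(2, 2))
#'   tpm[s + 1, encodeState(f(v), c(2, 2)) + 1] <- 1
#' }
#' net <- NetworkModel(tpm, c(2, 2), labels = c("A", "B"))
#' inferAdjacency(net)
#' @export
NetworkModel <- function(tpm, numStates, labels = NULL, adjacency = NULL) {
  numStates <- as.integer(numStates)
  S <- prod(numStates)
  tpm <- as.matrix(tpm)
  if (nrow(tpm) != ncol(tpm))
    stop("tpm must be square; got ", nrow(tpm), " x ", ncol(tpm))
  if (nrow(tpm) != S)
    stop("tpm side is ", nrow(tpm), " but prod(numStates) = ", S)
  rs <- rowSums(tpm)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad))
    stop("tpm rows do not sum to 1 (first offender: row ", bad[1],
         ", sum ", format(rs[bad[1]]), "); refusing to renormalize")
  tpm <- tpm / rs
  if (is.null(labels)) labels <- paste0("n", seq_along(numStates))
  dimnames(tpm) <- NULL
  if (!is.null(adjacency)) {
    adjacency <- matrix(as.integer(adjacency != 0), length(numStates))
  }
  new("NetworkModel", labels = as.character(labels), numStates = numStates,
      tpm = tpm, adjacency = adjacency)
}

#' @rdname multiphi-accessors
#' @export
setMethod("nodeLabels", "NetworkModel", function(x) x@labels)

#' @rdname multiphi-accessors
#' @export
setMethod("numStatesPerNode", "NetworkModel", function(x) x@numStates)

#' @rdname multiphi-accessors
#' @export
setMethod("nNodes", "NetworkModel", function(x) length(x@numStates))

#' @rdname multiphi-accessors
#' @export
setMethod("tpm", "NetworkModel", function(x) x@tpm)

#' @rdname multiphi-accessors
#' @export
setMethod("adjacency", "NetworkModel", function(x) x@adjacency)

#' Total number of system states
#' @param net a [NetworkModel-class].
#' @return integer `S = prod(numStatesPerNode(net))`.
#' @export
nStates <- function(net) prod(numStatesPerNode(net))

setMethod("show", "NetworkModel", function(object) {
  S <- nStates(object)
  det <- all(object@tpm %in% c(0, 1))
  cat(sprintf("NetworkModel: %d nodes, %d states (%s)\n",
              nNodes(object), S,
              if (det) "deterministic" else "probabilistic"))
  cat("  nodes: ",
      paste0(object@labels, "[", object@numStates, "]", collapse = " "),
      "\n", sep = "")
})

#' Per-node conditional distributions of a network
#'
#' Factorizes the state-by-state TPM into each node's next-state conditional
#' `Pr(s_i(t) = j | s(t-1) = h)`: for node `i` this is the `S x S_i`
#' column-marginal of each TPM row over node `i`'s states.  Under
#' conditional independence the row-wise product over nodes reconstructs
#' the TPM exactly.
#'
#' @param net a [NetworkModel-class].
#' @return list of `S x S_i` matrices, one per node, rows summing to 1.
#' @seealso [checkConditionalIndependence()]
#' @export
nodeConditionals <- function(net) {
  r <- numStatesPerNode(net)
  digits <- .stateDigits(r)
  P <- tpm(net)
  lapply(seq_along(r), function(i) {
    ind <- outer(digits[i, ], 0:(r[i] - 1L), "==") + 0  # S x S_i indicator
    P %*% ind
  })
}

## TPM implied by a list of per-node conditionals (length-S rows each):
## P[h, s] = prod_i T_i[h, digit_i(s)].
.tpmFromConditionals <- function(conds, radices) {
  digits <- .stateDigits(radices)
  S <- prod(radices)
  P <- matrix(1, S, S)
  for (i in seq_along(radices))
    P <- P * conds[[i]][, digits[i, ] + 1L, drop = FALSE]
  P
}

#' Check the Markov factorization of a TPM
#'
#' A network's elements are conditionally independent given the previous
#' system state iff each TPM row equals the product of the per-node
#' conditionals ([nodeConditionals()]).  Deterministic (0/1) TPMs always
#' factorize; probabilistic TPMs with correlated outputs do not.
#'
#' @param net a [NetworkModel-class].
#' @param tol absolute tolerance on the worst entry (default 1e-10).
#' @return list with `ok` (logical) and `maxDeviation`.
#' @export
checkConditionalIndependence <- function(net, tol = 1e-10) {
  P2 <- .tpmFromConditionals(nodeConditionals(net), numStatesPerNode(net))
  dev <- max(abs(tpm(net) - P2))
  list(ok = dev <= tol, maxDeviation = dev)
}

#' Validate a network model
#'
#' Produces a report of row-sum violations, out-of-range entries,
#' conditional-independence violations and (when an adjacency matrix was
#' supplied) inconsistencies with the TPM-inferred adjacency.  An empty
#' report means the model is valid.
#'
#' @param net a [NetworkModel-class].
#' @param tol tolerance for row sums and the factorization check.
#' @return list with logical `valid` and a character vector `problems`.
#' @export
validateNetwork <- function(net, tol = 1e-10) {
  problems <- character()
  P <- tpm(net)
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    problems <- c(problems,
                  sprintf("row %d sums to %.12g", bad, rs[bad]))
  neg <- which(P < -tol | P > 1 + tol)
  if (length(neg))
    problems <- c(problems,
                  sprintf("%d entries outside [0, 1]", length(neg)))
  ci <- checkConditionalIndependence(net, tol)
  if (!ci$ok)
    problems <- c(problems,
                  sprintf("conditional independence violated (max deviation %.3g)",
                          ci$maxDeviation))
  if (!is.null(adjacency(net))) {
    inferred <- inferAdjacency(net)
    extra <- which(inferred == 1L & adjacency(net) == 0L)
    if (length(extra))
      problems <- c(problems,
                    sprintf("adjacency omits %d dependencies present in the TPM",
                            length(extra)))
  }
  list(valid = length(problems) == 0L, problems = problems)
}

#' Infer the causal adjacency matrix from the TPM
#'
#' Node `j` is a parent of node `i` iff there exist two prior states that
#' differ only in `j`'s value and induce different conditional distributions
#' for `i`'s next state.
#'
#' @param net a [NetworkModel-class] (conditional independence assumed).
#' @param tol numerical tolerance for "different".
#' @return `n x n` integer matrix `A` with `A[j, i] = 1` iff `j -> i`.
#' @export
inferAdjacency <- function(net, tol = 1e-9) {
  r <- numStatesPerNode(net)
  n <- length(r)
  conds <- nodeConditionals(net)
  digits <- .stateDigits(r)
  A <- matrix(0L, n, n, dimnames = list(nodeLabels(net), nodeLabels(net)))
  for (j in seq_len(n)) {
    ## group prior states by the values of all nodes except j
    grp <- .projMap(r, setdiff(seq_len(n), j), digits)
    for (i in seq_len(n)) {
      Ti <- conds[[i]]
      depends <- any(vapply(split(seq_len(nrow(Ti)), grp), function(rows) {
        block <- Ti[rows, , drop = FALSE]
        any(abs(sweep(block, 2, block[1, ])) > tol)
      }, logical(1)))
      if (depends) A[j, i] <- 1L
    }
  }
  A
}

#' Sever connections across a unidirectional system cut
#'
#' Returns a new network in which every node of `to` has its inputs from
#' `from` replaced by independent uniform noise: its conditional rows are
#' averaged uniformly over the states of the `from` nodes.  Connections
#' within each part and from `to` back to `from` are untouched; the cut TPM
#' is the product of the modified per-node conditionals.
#'
#' @param net a [NetworkModel-class].
#' @param from,to integer vectors of node indices forming a bipartition
#'   (non-empty, disjoint, union = all nodes).
#' @return the cut [NetworkModel-class].
#' @export
applyCut <- function(net, from, to) {
  n <- nNodes(net)
  from <- sort(as.integer(from)); to <- sort(as.integer(to))
  if (length(from) == 0L || length(to) == 0L ||
      length(intersect(from, to)) ||
      !setequal(c(from, to), seq_len(n)))
    stop("cut must be a bipartition of all ", n, " nodes")
  r <- numStatesPerNode(net)
  digits <- .stateDigits(r)
  conds <- nodeConditionals(net)
  keep <- .projMap(r, setdiff(seq_len(n), from), digits)  # group rows over `from`
  nF <- prod(r[from])
  for (i in to) {
    Ti <- conds[[i]]
    avg <- rowsum(Ti, keep) / nF       # per kept-substate average
    conds[[i]] <- avg[keep + 1L, , drop = FALSE]
  }
  NetworkModel(.tpmFromConditionals(conds, r), r, nodeLabels(net))
}

#' Effective information of one system update
#'
#' Mutual information `I(X_t; X_{t+1})` in bits, with the state at `t`
#' distributed uniformly over all `S` states.  Bounded by `log2(S)`;
#' equals `log2(S)` for a permutation TPM and 0 for a constant one.
#'
#' @param net a [NetworkModel-class].
#' @return effective information in bits.
#' @export
effectiveInformation <- function(net) {
  P <- tpm(net)
  S <- nrow(P)
  pj <- colMeans(P)                       # marginal of X_{t+1}
  terms <- P * (log2(P) - rep(log2(pj), each = S))
  terms[P == 0] <- 0
  max(0, sum(terms) / S)
}

#' Reinterpret a TPM over a different node decomposition
#'
#' Returns a network with the same `S x S` matrix but a different list of
#' per-node state counts (products must agree).  Networks sharing a TPM have
#' identical effective information but generally different cause-effect
#' structures and integrated information.
#'
#' @param net a [NetworkModel-class].
#' @param numStates new per-node state counts, `prod(numStates) == nStates(net)`.
#' @param labels optional labels for the new nodes.
#' @return a [NetworkModel-class].
#' @export
reinterpretNet <- function(net, numStates, labels = NULL) {
  if (prod(numStates) != nStates(net))
    stop("state-space sizes differ: ", prod(numStates), " vs ", nStates(net))
  NetworkModel(tpm(net), numStates, labels)
}

#' Build a deterministic network from an evolution function
#'
#' @param f an [EvolutionFunction-class] (total: no NA successors).
#' @return a [NetworkModel-class] with an exact 0/1 TPM.
#' @export
networkFromFunction <- function(f) {
  succ <- f@successor
  if (anyNA(succ))
    stop("evolution function is partial (NA successors); a total map is required")
  S <- length(succ)
  P <- matrix(0, S, S)
  P[cbind(seq_len(S), succ + 1L)] <- 1
  NetworkModel(P, f@radices, f@labels)
}
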
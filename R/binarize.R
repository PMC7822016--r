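#' Construct an evolution function
#'
#' A deterministic, total update map over a mixed-radix state space, given
#' either as a vector of 0-based successor indices or as a function mapping
#' a value tuple to its successor tuple.
#'
#' @param radices integer vector of per-component state counts.
#' @param successor integer vector of 0-based successor indices (length
#'   `prod(radices)`), or a function `values -> values`.
#' @param labels optional component labels.
#' @return an [EvolutionFunction-class].
#' @export
evolutionFunction <- function(radices, successor, labels = NULL) {
  radices <- as.integer(radices)
  S <- prod(radices)
  if (is.function(successor)) {
    successor <- vapply(0:(S - 1L), function(s)
      encodeState(successor(decodeState(s, radices)), radices), integer(1))
  }
  if (is.null(labels)) labels <- paste0("n", seq_along(radices))
  new("EvolutionFunction", labels = as.character(labels),
      radices = radices, successor = as.integer(successor))
}

#' Is an evolution function asymptotic?
#'
#' Asymptotic: on every state, each component either keeps its current
#' value, jumps to its maximal value, or drops to zero.  All-binary
#' functions are trivially asymptotic.
#'
#' @param f an [EvolutionFunction-class].
#' @return logical.
#' @export
isAsymptotic <- function(f) {
  is.null(.asymptoticViolation(f))
}

## First violating (state, component) or NULL.
.asymptoticViolation <- function(f) {
  r <- f@radices
  for (s in seq_along(f@successor) - 1L) {
    if (is.na(f@successor[s + 1L])) next
    cur <- decodeState(s, r)
    nxt <- decodeState(f@successor[s + 1L], r)
    for (i in seq_along(r)) {
      if (!(nxt[i] %in% c(0L, cur[i], r[i] - 1L)))
        return(list(state = cur, component = i))
    }
  }
  NULL
}

## Binary layout of a multi-valued component set under the Van Ham scheme:
## component with m states -> m - 1 ordered Boolean constituents; value k
## is encoded as k ones followed by zeros.
.vhLayout <- function(f) {
  r <- f@radices
  sizes <- pmax(1L, r - 1L)
  groups <- split(seq_len(sum(sizes)), rep(seq_along(r), sizes))
  labels <- unlist(lapply(seq_along(r), function(i)
    if (sizes[i] == 1L) f@labels[i]
    else paste0(f@labels[i], seq_len(sizes[i]))))
  list(sizes = sizes, groups = groups, labels = labels,
       nBits = sum(sizes))
}

.vhEncodeValue <- function(value, size) {
  c(rep(1L, value), rep(0L, size - value))
}

## 0-based binary state index of each multi-valued state (little-endian
## over the concatenated bits).
.vhStateToBinary <- function(f, layout) {
  r <- f@radices
  S <- prod(r)
  vapply(0:(S - 1L), function(s) {
    v <- decodeState(s, r)
    bits <- unlist(lapply(seq_along(r), function(i)
      .vhEncodeValue(v[i], layout$sizes[i])))
    encodeState(bits, rep(2L, layout$nBits))
  }, integer(1))
}

## Per-group coarse value of a binary state: the number of ones among the
## group's constituents (canonical on admissible states, and the reading
## used to extend the Faure-Kaji and Tonello maps to all binary states).
.coarseValues <- function(bits, layout) {
  vapply(layout$groups, function(g) sum(bits[g]), integer(1))
}

.binarize <- function(f, method) {
  layout <- .vhLayout(f)
  B <- layout$nBits
  r2 <- rep(2L, B)
  S2 <- 2L^B
  s2b <- .vhStateToBinary(f, layout)
  admissible <- logical(S2)
  admissible[s2b + 1L] <- TRUE
  succ <- rep(NA_integer_, S2)
  r <- f@radices
  if (method == "van_ham") {
    succ[s2b + 1L] <- s2b[f@successor + 1L]
  } else {
    for (b in 0:(S2 - 1L)) {
      bits <- decodeState(b, r2)
      cur <- .coarseValues(bits, layout)
      tgt <- decodeState(f@successor[encodeState(cur, r) + 1L], r)
      newBits <- integer(0)
      for (i in seq_along(r)) {
        g <- layout$groups[[i]]
        sz <- layout$sizes[i]
        gb <- if (method == "faure_kaji") {
          if (tgt[i] == 0L) rep(0L, sz)
          else if (tgt[i] == r[i] - 1L) rep(1L, sz)
          else if (tgt[i] == cur[i]) bits[g]       # maintain: bits unchanged
          else stop("non-asymptotic target for component ", f@labels[i],
                    " at state (", paste(cur, collapse = ","), ")")
        } else {                                   # tonello: one step toward
          step <- cur[i] + sign(tgt[i] - cur[i])
          .vhEncodeValue(step, sz)
        }
        newBits <- c(newBits, gb)
      }
      succ[b + 1L] <- encodeState(newBits, r2)
    }
  }
  new("BinarizationResult", method = method,
      binaryFunction = new("EvolutionFunction", labels = layout$labels,
                           radices = r2, successor = succ),
      admissible = admissible, stateToBinary = s2b,
      groups = layout$groups, original = f)
}

#' Van Ham binarization (partial)
#'
#' One Boolean constituent per activity threshold: a component with `m`
#' states becomes `m - 1` ordered bits, value `k` mapping to `k` ones
#' followed by zeros.  The resulting binary function is defined only on the
#' admissible states (those with a multi-valued pre-image); other rows are
#' `NA`, so a full causal model requires choosing one of the
#' `S^(#missing)` deterministic completions.
#'
#' @param f an [EvolutionFunction-class].
#' @return a [BinarizationResult-class] with a partial binary function.
#' @export
vanHam <- function(f) .binarize(f, "van_ham")

#' Faure-Kaji binarization (total; requires an asymptotic function)
#'
#' Extends the Van Ham mapping to every binary state: a constituent group's
#' coarse value is the sum of its bits; the original function is applied to
#' the coarse state, and each component's target is written back as all
#' zeros (target 0), all ones (target max), or unchanged bits (target =
#' current value).  Coarse-graining the result by bit sums reconstructs the
#' original function exactly.
#'
#' @param f an asymptotic [EvolutionFunction-class].
#' @return a [BinarizationResult-class] with a total binary function.
#' @export
faureKaji <- function(f) {
  v <- .asymptoticViolation(f)
  if (!is.null(v))
    stop("function is not asymptotic: component ", f@labels[v$component],
         " at state (", paste(v$state, collapse = ","),
         ") targets neither 0, its current value, nor its maximum")
  .binarize(f, "faure_kaji")
}

#' Tonello binarization (total)
#'
#' Stepwise Boolean implementation: on every binary state the coarse value
#' of each component moves one step toward its target under the original
#' function, and the stepped value is written in canonical Van Ham form.
#' Reproduces the published construction on the p53-Mdm2 model; for
#' components with many levels the construction is best-effort (validated
#' by golden-file tests, see the package vignette).
#'
#' @param f an [EvolutionFunction-class].
#' @return a [BinarizationResult-class] with a total binary function.
#' @export
tonello <- function(f) .binarize(f, "tonello")

#' Number of deterministic completions of a partial Van Ham table
#'
#' A partial binary function with `k` undefined rows over `S` binary states
#' admits `S^k` deterministic completions.
#'
#' @param b a [BinarizationResult-class] from [vanHam()].
#' @return a numeric count.
#' @export
vanHamCompletionCount <- function(b) {
  S2 <- length(b@admissible)
  as.numeric(S2)^sum(!b@admissible)
}

#' Coarse-grain a network by grouping nodes into macro-elements
#'
#' Aggregates the TPM of `net` under a partition of its nodes into groups
#' and a per-group map from micro sub-states to macro values: macro rows
#' average (uniformly) over the micro states sharing a macro state, macro
#' columns sum.
#'
#' @param net a [NetworkModel-class].
#' @param grouping list of integer vectors partitioning the nodes; the list
#'   order defines the macro node order.
#' @param stateMap list parallel to `grouping`: integer vector per group
#'   mapping each micro sub-state index (1-based position, little-endian
#'   over the group's radices) to a 0-based macro value.  See
#'   [sumStateMap()] for the bit-sum map used with Van Ham constituents.
#' @param labels optional macro node labels.
#' @return the macro [NetworkModel-class].
#' @export
coarseGrain <- function(net, grouping, stateMap, labels = NULL) {
  n <- nNodes(net)
  if (!setequal(unlist(grouping), seq_len(n)) ||
      anyDuplicated(unlist(grouping)))
    stop("grouping must partition the node set")
  r <- numStatesPerNode(net)
  digits <- .stateDigits(r)
  macroR <- integer(length(grouping))
  for (g in seq_along(grouping)) {
    nm <- prod(r[sort(grouping[[g]])])
    if (length(stateMap[[g]]) != nm || anyNA(stateMap[[g]]))
      stop("stateMap for group ", g, " must assign all ", nm,
           " micro sub-states")
    vals <- sort(unique(stateMap[[g]]))
    if (!identical(vals, seq.int(0L, max(stateMap[[g]]))))
      stop("stateMap for group ", g,
           " must use contiguous macro values starting at 0")
    macroR[g] <- max(stateMap[[g]]) + 1L
  }
  if (any(macroR < 2L))
    stop("each macro element needs at least 2 states")
  S <- prod(r)
  ## micro state -> macro index
  macroVal <- vapply(seq_along(grouping), function(g) {
    sub <- .projMap(r, sort(grouping[[g]]), digits)
    as.integer(stateMap[[g]][sub + 1L])
  }, integer(S))
  macroVal <- matrix(macroVal, nrow = S)
  w <- cumprod(c(1L, macroR[-length(macroR)]))
  mm <- as.vector(macroVal %*% w)
  P <- tpm(net)
  cnt <- tabulate(mm + 1L, nbins = prod(macroR))
  Pm <- rowsum(P, mm) / cnt
  Pm <- t(rowsum(t(Pm), mm))
  if (is.null(labels)) labels <- paste0("g", seq_along(grouping))
  NetworkModel(Pm, macroR, labels)
}

#' Bit-sum state map for a Van Ham constituent group
#'
#' Maps each micro sub-state of `k` binary constituents to the macro value
#' equal to its number of ones, e.g. `{(0,0) -> 0, (1,0)/(0,1) -> 1,
#' (1,1) -> 2}`.
#'
#' @param k number of binary constituents in the group.
#' @return integer vector over the `2^k` micro sub-states.
#' @export
sumStateMap <- function(k) {
  vapply(0:(2L^k - 1L), function(s) sum(decodeState(s, rep(2L, k))),
         integer(1))
}

#' Probabilistic binarization (experimental, conjectural)
#'
#' Splits each multi-valued component into Van Ham constituents but maps a
#' transition into an intermediate value onto all bit patterns with that
#' sum with equal probability (e.g. a ternary 1 onto (1,0) and (0,1) at
#' probability 1/2 each).  Coarse-graining the result by bit sums
#' reconstructs the original function for arbitrary (not necessarily
#' asymptotic) evolution functions.  Note the rows of the resulting TPM
#' are valid distributions, but the joint bit transitions within a group
#' are anti-correlated, so the result generally violates the per-node
#' conditional independence required for causal analysis; it is provided
#' for studying coarse-graining reconstructions only.
#'
#' @param f an [EvolutionFunction-class].
#' @return a binary probabilistic [NetworkModel-class].
#' @export
probabilisticBinarization <- function(f) {
  layout <- .vhLayout(f)
  B <- layout$nBits
  r2 <- rep(2L, B)
  S2 <- 2L^B
  r <- f@radices
  P <- matrix(0, S2, S2)
  allBits <- .stateDigits(r2)
  for (b in 0:(S2 - 1L)) {
    bits <- allBits[, b + 1L]
    cur <- .coarseValues(bits, layout)
    tgt <- decodeState(f@successor[encodeState(cur, r) + 1L], r)
    ## distribution per group over its bit patterns with sum == target
    groupDists <- lapply(seq_along(r), function(i) {
      sz <- layout$sizes[i]
      pats <- 0:(2L^sz - 1L)
      ok <- vapply(pats, function(p)
        sum(decodeState(p, rep(2L, sz))) == tgt[i], logical(1))
      d <- numeric(length(pats)); d[ok] <- 1 / sum(ok)
      d
    })
    row <- Reduce(function(v, d) as.vector(outer(v, d)), groupDists, 1)
    P[b + 1L, ] <- row
  }
  NetworkModel(P, r2, layout$labels)
}
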
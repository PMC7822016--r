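## System-level analysis: cause-effect structure, cuts, Phi, complexes.

#' Cause-effect structure of a system in a state
#'
#' Evaluates every non-empty mechanism (subset of nodes, in ascending
#' bitmask order) in its current sub-state and collects the distinctions
#' with phi > 0.
#'
#' @param net a [NetworkModel-class].
#' @param state integer vector: the system's current state.
#' @param config a [phiConfig()].
#' @return a [CES-class].
#' @export
computeCes <- function(net, state, config = phiConfig()) {
  state <- .checkState(net, state)
  ctx <- .phiContext(net, state)
  n <- nNodes(net)
  ds <- list()
  for (mask in seq_len(2L^n - 1L)) {
    M <- .maskToSet(mask)
    d <- .distinctionCtx(ctx, M, config)
    if (!is.null(d)) ds[[length(ds) + 1L]] <- d
  }
  sumPhi <- if (length(ds)) sum(vapply(ds, function(d) d@phi, numeric(1))) else 0
  new("CES", distinctions = ds, sumPhi = sumPhi, state = state,
      labels = nodeLabels(net))
}

.checkState <- function(net, state) {
  state <- as.integer(state)
  r <- numStatesPerNode(net)
  if (length(state) != length(r) || any(state < 0L) || any(state >= r))
    stop("state must hold one in-range value per node")
  state
}

.stateReachable <- function(net, state) {
  idx <- encodeState(state, numStatesPerNode(net))
  any(tpm(net)[, idx + 1L] > 0)
}

#' Small-phi lost from a CES under a system cut
#'
#' Re-evaluates each distinction's mechanism on the cut network (purviews
#' re-searched; a mechanism whose distinction is destroyed contributes its
#' full intact phi) and sums the absolute phi differences.  No mechanisms
#' outside the intact CES are searched (cuts are assumed not to create new
#' distinctions).
#'
#' @param net the intact [NetworkModel-class].
#' @param state system state the CES was computed in.
#' @param ces the intact [CES-class] (from [computeCes()] on `net`).
#' @param from,to the unidirectional cut: `from -> to` connections severed.
#' @param config a [phiConfig()].
#' @return list with `loss` (sum of `|phi_intact - phi_cut|`) and
#'   `phis` (per-distinction phi under the cut).
#' @export
cesPhiUnderCut <- function(net, state, ces, from, to,
                           config = phiConfig()) {
  state <- .checkState(net, state)
  cutNet <- applyCut(net, from, to)
  ctx <- .phiContext(cutNet, state)
  phis <- vapply(ces@distinctions, function(d)
    .distinctionPhiCtx(ctx, d@mechanism, config), numeric(1))
  intact <- vapply(ces@distinctions, function(d) d@phi, numeric(1))
  list(loss = sum(abs(intact - phis)), phis = phis)
}

#' System irreducibility analysis
#'
#' Computes the CES of the full system in `state`, evaluates all `2^n - 2`
#' unidirectional bipartition cuts, and returns the integrated information
#' `Phi`: the minimal total phi lost from the CES under a cut.  Ties keep
#' the first cut in enumeration order (ascending bitmask of the severed
#' source part).  Single-node systems admit no cut and have `Phi = 0`.
#'
#' @param net a [NetworkModel-class].
#' @param state integer vector; must be reachable (its TPM column must have
#'   mass) unless `unreachable = "zero"`.
#' @param config a [phiConfig()].
#' @param unreachable `"error"` (default) stops with advice to pick a state
#'   occurring in the TPM; `"zero"` returns Phi = 0 with an empty CES (an
#'   unreachable state specifies no causes), used by the survey drivers.
#' @return an [SIAResult-class].
#' @export
sia <- function(net, state, config = phiConfig(),
                unreachable = c("error", "zero")) {
  unreachable <- match.arg(unreachable)
  state <- .checkState(net, state)
  n <- nNodes(net)
  if (!.stateReachable(net, state)) {
    if (unreachable == "error")
      stop("state (", paste(state, collapse = ","), ") is unreachable ",
           "(its TPM column is all zero); choose a state that occurs as a ",
           "successor in the TPM")
    return(new("SIAResult", subsystem = seq_len(n), state = state,
               bigPhi = 0, cutFrom = integer(), cutTo = integer(),
               ces = new("CES", distinctions = list(), sumPhi = 0,
                         state = state, labels = nodeLabels(net)),
               partitionedPhis = numeric()))
  }
  ces <- computeCes(net, state, config)
  if (n == 1L || length(ces@distinctions) == 0L) {
    return(new("SIAResult", subsystem = seq_len(n), state = state,
               bigPhi = 0, cutFrom = integer(), cutTo = integer(),
               ces = ces,
               partitionedPhis = numeric(length(ces@distinctions))))
  }
  best <- NULL
  for (mask in seq_len(2L^n - 2L)) {
    from <- .maskToSet(mask)
    to <- setdiff(seq_len(n), from)
    res <- cesPhiUnderCut(net, state, ces, from, to, config)
    if (is.null(best) || res$loss < best$loss) {
      best <- res; best$from <- from; best$to <- to
    }
    if (best$loss == 0) break
  }
  new("SIAResult", subsystem = seq_len(n), state = state,
      bigPhi = best$loss, cutFrom = as.integer(best$from),
      cutTo = as.integer(best$to), ces = ces, partitionedPhis = best$phis)
}

#' Major complex: the subsystem with maximal integrated information
#'
#' Runs [sia()] over every non-empty node subset, conditioning each
#' candidate subsystem on the remaining nodes frozen in their current state
#' (background conditions: external inputs fixed, external outputs
#' ignored).  Ties prefer the larger subsystem, then the lexicographically
#' first one.
#'
#' @inheritParams sia
#' @return the winning [SIAResult-class], whose `subsystem` slot names the
#'   complex in full-system node indices.
#' @export
majorComplex <- function(net, state, config = phiConfig()) {
  state <- .checkState(net, state)
  n <- nNodes(net)
  best <- NULL
  tol <- 1e-12
  for (mask in seq_len(2L^n - 1L)) {
    sub <- .maskToSet(mask)
    subNet <- .subsystemNetwork(net, sub, state)
    res <- sia(subNet, state[sub], config, unreachable = "zero")
    res@subsystem <- as.integer(sub)
    if (is.null(best) || res@bigPhi > best@bigPhi + tol ||
        (abs(res@bigPhi - best@bigPhi) <= tol &&
         (length(sub) > length(best@subsystem) ||
          (length(sub) == length(best@subsystem) &&
           .lexLess(sub, best@subsystem))))) {
      best <- res
    }
  }
  best
}

## Conditioned subsystem: external nodes frozen at their current values.
## Each retained node's conditional keeps only the TPM rows whose external
## coordinates equal the frozen state; outputs to external nodes are
## dropped by construction.
.subsystemNetwork <- function(net, sub, state) {
  sub <- sort(sub)
  n <- nNodes(net)
  r <- numStatesPerNode(net)
  if (setequal(sub, seq_len(n))) return(net)
  ext <- setdiff(seq_len(n), sub)
  digits <- .stateDigits(r)
  keep <- which(colSums(digits[ext, , drop = FALSE] !=
                          state[ext]) == 0L)
  ## rows ordered by the subsystem's little-endian sub-state index
  ord <- order(.projMap(r, sub, digits)[keep])
  rows <- keep[ord]
  conds <- nodeConditionals(net)
  NetworkModel(.tpmFromConditionals(
    lapply(sub, function(i) conds[[i]][rows, , drop = FALSE]), r[sub]),
    r[sub], nodeLabels(net)[sub])
}

#' @rdname multiphi-accessors
#' @export
setMethod("distinctions", "CES", function(x) x@distinctions)

#' @rdname multiphi-accessors
#' @export
setMethod("sumPhi", "CES", function(x) x@sumPhi)

#' @rdname multiphi-accessors
#' @export
setMethod("bigPhi", "SIAResult", function(x) x@bigPhi)

#' @rdname multiphi-accessors
#' @export
setMethod("mipCut", "SIAResult",
          function(x) list(from = x@cutFrom, to = x@cutTo))

#' Number of distinctions in a CES
#' @param ces a [CES-class].
#' @return integer count.
#' @export
nDistinctions <- function(ces) length(ces@distinctions)

#' Mean phi over a CES's distinctions
#' @param ces a [CES-class].
#' @return mean distinction phi, or `NA` for an empty CES.
#' @export
meanSmallPhi <- function(ces) {
  if (!length(ces@distinctions)) return(NA_real_)
  mean(vapply(ces@distinctions, function(d) d@phi, numeric(1)))
}

setMethod("show", "CES", function(object) {
  cat(sprintf("CES at state (%s): %d distinction(s), sum phi = %.6g\n",
              paste(object@state, collapse = ","),
              length(object@distinctions), object@sumPhi))
  for (d in object@distinctions)
    cat(sprintf("  {%s}=(%s)  phi = %.6g\n",
                paste(object@labels[d@mechanism], collapse = ","),
                paste(d@mechState, collapse = ","), d@phi))
})

setMethod("show", "SIAResult", function(object) {
  cat(sprintf("SIA: subsystem {%s}, state (%s)\n",
              paste(object@subsystem, collapse = ","),
              paste(object@state, collapse = ",")))
  cat(sprintf("  Phi = %.6g over %d distinction(s) (sum phi %.6g)\n",
              object@bigPhi, length(object@ces@distinctions),
              object@ces@sumPhi))
  if (length(object@cutFrom))
    cat(sprintf("  minimum cut: {%s} -/-> {%s}\n",
                paste(object@cutFrom, collapse = ","),
                paste(object@cutTo, collapse = ",")))
})

#' Serialize an SIA result to JSON
#'
#' Writes Phi, the minimal cut and, per distinction, the mechanism, its
#' state, cause/effect purviews, specified states and phi values.
#'
#' @param x an [SIAResult-class].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
siaToJson <- function(x, path = NULL) {
  miceJson <- function(m) list(purview = as.integer(m@purview),
                               phi = m@phi,
                               specifiedState = as.integer(m@specifiedState))
  obj <- list(
    schema = "multiphi/sia/1",
    subsystem = as.integer(x@subsystem),
    state = as.integer(x@state),
    bigPhi = x@bigPhi,
    cut = list(from = as.integer(x@cutFrom), to = as.integer(x@cutTo)),
    sumPhi = x@ces@sumPhi,
    distinctions = lapply(x@ces@distinctions, function(d) list(
      mechanism = as.integer(d@mechanism),
      mechState = as.integer(d@mechState),
      phi = d@phi,
      cause = miceJson(d@cause),
      effect = miceJson(d@effect))),
    partitionedPhis = as.numeric(x@partitionedPhis))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
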
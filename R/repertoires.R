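## Internal computation context for one (network, current state).
##
## Caches everything the mechanism- and system-level searches reuse:
## per-node conditionals, state digits, per-subset projection/gather maps,
## per-mechanism effect factors and cause likelihood marginals.  All caches
## live in an environment so lookups are O(1) by precomputed keys.

.phiContext <- function(net, state) {
  r <- numStatesPerNode(net)
  n <- length(r)
  S <- prod(r)
  digits <- .stateDigits(r)
  conds <- nodeConditionals(net)
  ctx <- new.env(parent = emptyenv())
  ctx$net <- net; ctx$r <- r; ctx$n <- n; ctx$S <- S
  ctx$digits <- digits; ctx$conds <- conds
  ctx$state <- as.integer(state)
  ## projection maps and gather index matrices for every node subset (by mask)
  nm <- 2L^n
  ctx$proj <- vector("list", nm); ctx$gather <- vector("list", nm)
  for (mask in 0:(nm - 1L)) {
    sub <- .maskToSet(mask)
    ctx$proj[[mask + 1L]] <- .projMap(r, sub, digits)
    ctx$gather[[mask + 1L]] <- matrix(order(ctx$proj[[mask + 1L]]),
                                      ncol = max(1L, prod(r[sub])))
  }
  ## rows of the TPM compatible with mechanism-mask A in the current state
  ctx$rowsFor <- vector("list", nm)
  ## effect factors indexed Amask * n + z
  ctx$effFactor <- vector("list", nm * n)
  ## cause likelihood of node i being in its current state, given each prior
  ctx$lambda <- lapply(seq_len(n), function(i)
    conds[[i]][, ctx$state[i] + 1L])
  ## marginals of lambda_i onto purview masks, indexed Bmask * n + i
  ctx$lambdaMarg <- vector("list", nm * n)
  ## repertoire caches indexed Amask * 2^n + Bmask + 1
  ctx$repC <- vector("list", nm * nm)
  ctx$repE <- vector("list", nm * nm)
  ctx
}

.ctxRowsFor <- function(ctx, Amask) {
  got <- ctx$rowsFor[[Amask + 1L]]
  if (!is.null(got)) return(got)
  A <- .maskToSet(Amask)
  if (length(A) == 0L) {
    rows <- seq_len(ctx$S)
  } else {
    aIdx <- .projMap(ctx$r, A, ctx$digits)[
      encodeState(ctx$state, ctx$r) + 1L]
    rows <- which(ctx$proj[[Amask + 1L]] == aIdx)
  }
  ctx$rowsFor[[Amask + 1L]] <- rows
  rows
}

## Effect factor of purview node z under mechanism mask A: the node's
## next-state distribution averaged uniformly over all prior states
## compatible with the mechanism's current state.
.ctxEffFactor <- function(ctx, Amask, z) {
  key <- Amask * ctx$n + z
  got <- ctx$effFactor[[key]]
  if (!is.null(got)) return(got)
  rows <- .ctxRowsFor(ctx, Amask)
  f <- colMeans(ctx$conds[[z]][rows, , drop = FALSE])
  ctx$effFactor[[key]] <- f
  f
}

## Marginal of node i's cause likelihood onto purview mask B (unnormalized,
## uniform prior weight implicit).
.ctxLambdaMarg <- function(ctx, i, Bmask) {
  key <- Bmask * ctx$n + i
  got <- ctx$lambdaMarg[[key]]
  if (!is.null(got)) return(got)
  g <- ctx$gather[[Bmask + 1L]]
  lam <- ctx$lambda[[i]]
  m <- colSums(matrix(lam[g], nrow = nrow(g)))
  ctx$lambdaMarg[[key]] <- m
  m
}

## Repertoire (bare probability vector over B's joint states, little-endian,
## ascending node order) of mechanism mask A over purview mask B.
## Cause repertoires use the virtual-element decomposition: each mechanism
## node's likelihood is marginalized onto the purview first, the marginals
## are multiplied across mechanism nodes, and the product normalized.
## A null cause (unreachable mechanism state) yields an all-zero vector.
.ctxRep <- function(ctx, dir, Amask, Bmask) {
  key <- Amask * 2L^ctx$n + Bmask + 1L
  cacheName <- if (dir == "effect") "repE" else "repC"
  got <- ctx[[cacheName]][[key]]
  if (!is.null(got)) return(got)
  B <- .maskToSet(Bmask)
  if (length(B) == 0L) {
    v <- 1
  } else if (dir == "effect") {
    v <- 1
    for (z in B)                        # ascending => little-endian order
      v <- as.vector(outer(v, .ctxEffFactor(ctx, Amask, z)))
  } else {
    A <- .maskToSet(Amask)
    LB <- prod(ctx$r[B])
    if (length(A) == 0L) {
      v <- rep(1 / LB, LB)
    } else {
      v <- rep(1, LB)
      for (i in A) v <- v * .ctxLambdaMarg(ctx, i, Bmask)
      tot <- sum(v)
      v <- if (tot > 0) v / tot else rep(0, LB)
    }
  }
  ctx[[cacheName]][[key]] <- v
  v
}

.asRepertoire <- function(ctx, purview, v) {
  new("Repertoire", purview = as.integer(sort(purview)),
      radices = ctx$r[sort(purview)], probs = as.numeric(v),
      isNull = length(v) > 0 && sum(v) == 0)
}

.checkSubset <- function(net, x, what) {
  x <- as.integer(x)
  if (anyDuplicated(x) || any(x < 1L) || any(x > nNodes(net)))
    stop(what, " must be a subset of node indices 1..", nNodes(net))
  sort(x)
}

#' Effect repertoire of a mechanism over a purview
#'
#' The distribution over the purview's next states induced by the mechanism
#' being in `mechState`, with all inputs outside the mechanism marginalized
#' under the uniform (maximum-entropy perturbation) distribution.  The
#' repertoire is the product over purview nodes of their constrained
#' next-state conditionals; the empty purview yields the scalar 1.
#'
#' @param net a [NetworkModel-class] (conditional independence assumed).
#' @param mechanism integer vector of node indices (may be empty: the
#'   unconstrained effect repertoire).
#' @param mechState integer vector of the mechanism nodes' current values,
#'   aligned with `sort(mechanism)`.
#' @param purview integer vector of node indices.
#' @return a [Repertoire-class].
#' @export
effectRepertoire <- function(net, mechanism, mechState, purview) {
  mechanism <- .checkSubset(net, mechanism, "mechanism")
  purview <- .checkSubset(net, purview, "purview")
  ctx <- .phiContext(net, .fullState(net, mechanism, mechState))
  .asRepertoire(ctx, purview,
                .ctxRep(ctx, "effect", .setToMask(mechanism),
                        .setToMask(purview)))
}

#' Cause repertoire of a mechanism over a purview
#'
#' Bayesian inversion of the node conditionals under a uniform prior over
#' prior system states.  Each mechanism node contributes the likelihood of
#' its current value given every prior state; likelihoods are marginalized
#' onto the purview per mechanism node (virtual-element decomposition),
#' multiplied, and normalized.  If the mechanism state has zero likelihood
#' everywhere, the mechanism specifies no cause and the returned repertoire
#' is flagged null (phi = 0 downstream).
#'
#' @inheritParams effectRepertoire
#' @return a [Repertoire-class]; the empty mechanism gives the uniform
#'   (unconstrained) repertoire over the purview.
#' @export
causeRepertoire <- function(net, mechanism, mechState, purview) {
  mechanism <- .checkSubset(net, mechanism, "mechanism")
  purview <- .checkSubset(net, purview, "purview")
  ctx <- .phiContext(net, .fullState(net, mechanism, mechState))
  .asRepertoire(ctx, purview,
                .ctxRep(ctx, "cause", .setToMask(mechanism),
                        .setToMask(purview)))
}

## Embed a mechanism state into a full system state (non-mechanism nodes 0;
## they are never read by the repertoire computations for that mechanism).
.fullState <- function(net, mechanism, mechState) {
  state <- integer(nNodes(net))
  if (length(mechanism) != length(mechState))
    stop("mechState must have one value per mechanism node")
  r <- numStatesPerNode(net)
  if (any(mechState < 0L) || any(mechState >= r[mechanism]))
    stop("mechState out of range")
  state[mechanism] <- as.integer(mechState)
  state
}

#' @rdname multiphi-accessors
#' @export
setMethod("probs", "Repertoire", function(x) x@probs)

setMethod("show", "Repertoire", function(object) {
  if (length(object@purview) == 0L) {
    cat("Repertoire over empty purview (scalar 1)\n")
    return(invisible(NULL))
  }
  cat("Repertoire over nodes {", paste(object@purview, collapse = ","),
      "}", if (object@isNull) " [null]", "\n", sep = "")
  states <- t(vapply(0:(length(object@probs) - 1L),
                     decodeState, integer(length(object@radices)),
                     radices = object@radices))
  df <- data.frame(state = apply(states, 1, paste, collapse = ""),
                   p = round(object@probs, 6))
  print(df, row.names = FALSE)
})
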
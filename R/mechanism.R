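## Mechanism-level irreducibility: tripartitions, the absolute intrinsic
## difference (AID) measure, phi, maximally irreducible causes/effects.

.rgsCache <- new.env(parent = emptyenv())

## Canonical assignments of k items to at most 3 unlabeled parts:
## restricted growth strings with values < 3 (first item in part 0, a new
## part id only after all smaller ids), excluding the identity (all items
## in one part).  Rows in lexicographic order; this is the package's
## deterministic tripartition enumeration order.
.rgsAssignments <- function(k) {
  key <- as.character(k)
  got <- .rgsCache[[key]]
  if (!is.null(got)) return(got)
  grids <- do.call(expand.grid, rev(replicate(k, 0:2, simplify = FALSE)))
  a <- as.matrix(grids[, rev(seq_len(k)), drop = FALSE])  # lexicographic rows
  colnames(a) <- NULL
  keep <- a[, 1] == 0L
  if (k > 1) {
    runmax <- a[, 1]
    for (j in 2:k) {
      keep <- keep & (a[, j] <= runmax + 1L)
      runmax <- pmax(runmax, a[, j])
    }
  }
  keep <- keep & rowSums(a != 0L) > 0L   # drop the identity partition
  a <- a[keep, , drop = FALSE]
  storage.mode(a) <- "integer"
  .rgsCache[[key]] <- a
  a
}

#' Enumerate mechanism-level tripartitions
#'
#' All ways of distributing the mechanism nodes and the purview nodes over
#' three part slots, deduplicated under permutation of the slots and
#' excluding the identity partition (everything in one common part).  A part
#' may have an empty mechanism (it contributes the unconstrained repertoire
#' over its purview) or an empty purview (it contributes the scalar 1).
#' Order is deterministic (lexicographic over canonical slot assignments).
#'
#' @param mechanism,purview integer vectors of node indices; the purview
#'   must be non-empty.
#' @return list of partitions; each partition is a list of 3 parts, each
#'   part a `list(mechanism =, purview =)` of (possibly empty) index
#'   vectors.
#' @export
enumerateTripartitions <- function(mechanism, purview) {
  mechanism <- sort(as.integer(mechanism))
  purview <- sort(as.integer(purview))
  if (length(purview) == 0L) stop("purview must be non-empty")
  m <- length(mechanism); z <- length(purview)
  a <- .rgsAssignments(m + z)
  lapply(seq_len(nrow(a)), function(i) {
    lapply(0:2, function(slot) {
      list(mechanism = mechanism[a[i, seq_len(m)] == slot],
           purview = purview[a[i, m + seq_len(z)] == slot])
    })
  })
}

#' Absolute intrinsic difference between two repertoires
#'
#' `max_s p(s) * |log2(p(s) / q(s))|` together with the maximizing state.
#' States with `p(s) = 0` contribute 0; `q(s) = 0 < p(s)` contributes
#' `cap` (default `Inf`: full determination destroyed by the partition).
#'
#' @param p,q [Repertoire-class] objects over the same purview, or bare
#'   numeric vectors of equal length.
#' @param cap value for infinite terms (default uncapped).
#' @return list with `phi` and `state` (the maximizing purview state; an
#'   integer vector when repertoires are given, else a 0-based index).
#' @examples
#' p <- c(1, 0, 0, 0); q <- rep(0.25, 4)
#' aid(p, q)  # phi = log2(4) = 2 at the support state
#' @export
aid <- function(p, q, cap = Inf) {
  decode <- NULL
  if (is(p, "Repertoire")) {
    if (!is(q, "Repertoire") || !identical(p@purview, q@purview))
      stop("p and q must be repertoires over the same purview")
    decode <- p@radices
    p <- p@probs; q <- q@probs
  }
  if (length(p) != length(q))
    stop("repertoires have different lengths")
  terms <- numeric(length(p))
  pos <- p > 0
  zq <- pos & q <= 0
  ok <- pos & !zq
  terms[ok] <- p[ok] * abs(log2(p[ok] / q[ok]))
  terms[zq] <- cap
  i <- which.max(terms)                 # first maximum
  phi <- terms[i]
  if (length(terms) == 0L) { phi <- 0; i <- 1L }
  state <- if (is.null(decode)) i - 1L else decodeState(i - 1L, decode)
  list(phi = phi, state = state)
}

## ---- internal fast path -------------------------------------------------

## Global submask -> global-mask tables for a node set, cached on the context.
.ctxSubMasks <- function(ctx, set) {
  mask <- .setToMask(set)
  if (is.null(ctx$subMasks)) ctx$subMasks <- vector("list", 2L^ctx$n)
  got <- ctx$subMasks[[mask + 1L]]
  if (!is.null(got)) return(got)
  k <- length(set)
  out <- integer(2L^k)
  for (sm in seq_len(2L^k) - 1L)
    out[sm + 1L] <- .setToMask(set[.maskToSet(sm)])
  ctx$subMasks[[mask + 1L]] <- out
  out
}

## Projections of purview-local state indices onto purview submasks.
.ctxProjZ <- function(ctx, Zset) {
  mask <- .setToMask(Zset)
  if (is.null(ctx$projZ)) ctx$projZ <- vector("list", 2L^ctx$n)
  got <- ctx$projZ[[mask + 1L]]
  if (!is.null(got)) return(got)
  rZ <- ctx$r[Zset]
  dg <- .stateDigits(rZ)
  z <- length(Zset)
  out <- lapply(seq_len(2L^z) - 1L, function(bm)
    .projMap(rZ, .maskToSet(bm), dg))
  ctx$projZ[[mask + 1L]] <- out
  out
}

## phi of mechanism M (in ctx$state) over purview Z, one direction.
## Returns list(phi, row, state, p); row indexes .rgsAssignments(m + z).
.phiMipCtx <- function(ctx, Mset, Zset, dir, cap = Inf) {
  Amask <- .setToMask(Mset); Bmask <- .setToMask(Zset)
  p <- .ctxRep(ctx, dir, Amask, Bmask)
  if (sum(p) == 0)                       # null cause: no constraint specified
    return(list(phi = 0, row = NA_integer_, state = 0L, p = p))
  m <- length(Mset); z <- length(Zset)
  subA <- .ctxSubMasks(ctx, Mset)
  subB <- .ctxSubMasks(ctx, Zset)
  reps <- vector("list", 2L^m * 2L^z)
  idx <- 1L
  for (a in seq_len(2L^m) - 1L) {
    ga <- subA[a + 1L]
    for (b in seq_len(2L^z) - 1L) {
      reps[[idx]] <- .ctxRep(ctx, dir, ga, subB[b + 1L])
      idx <- idx + 1L
    }
  }
  res <- cpp_phi_mip(p, .rgsAssignments(m + z), m, z, reps,
                     .ctxProjZ(ctx, Zset), cap)
  list(phi = res$phi, row = res$row, state = res$state, p = p)
}

.lexLess <- function(a, b) {
  ## TRUE if index vector a precedes b lexicographically
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

## MICE search over all non-empty purviews.  Tie-break: largest purview,
## then lexicographically first.
.miceCtx <- function(ctx, Mset, dir, cap = Inf) {
  best <- NULL
  tol <- 1e-12
  for (Bmask in seq_len(2L^ctx$n - 1L)) {
    Zset <- .maskToSet(Bmask)
    r <- .phiMipCtx(ctx, Mset, Zset, dir, cap)
    if (is.null(best) || r$phi > best$phi + tol ||
        (abs(r$phi - best$phi) <= tol &&
         (length(Zset) > length(best$Zset) ||
          (length(Zset) == length(best$Zset) &&
           .lexLess(Zset, best$Zset))))) {
      best <- r
      best$Zset <- Zset
    }
  }
  best
}

.miceObject <- function(ctx, Mset, dir, best) {
  rZ <- ctx$r[best$Zset]
  part <- if (is.na(best$row) || best$row == 0L) list() else {
    a <- .rgsAssignments(length(Mset) + length(best$Zset))[best$row, ]
    m <- length(Mset)
    lapply(0:2, function(slot)
      list(mechanism = Mset[a[seq_len(m)] == slot],
           purview = best$Zset[a[m + seq_along(best$Zset)] == slot]))
  }
  new("Mice", direction = dir, purview = as.integer(best$Zset),
      repertoire = .asRepertoire(ctx, best$Zset, best$p),
      phi = best$phi,
      specifiedState = decodeState(best$state, rZ),
      partition = part)
}

## ---- public wrappers ----------------------------------------------------

#' Partitioned repertoire under a mechanism tripartition
#'
#' Product over the partition's parts of the part-mechanism's repertoire
#' over the part-purview: an empty part mechanism contributes the
#' unconstrained repertoire over its purview, an empty part purview the
#' scalar 1.
#'
#' @param net a [NetworkModel-class].
#' @param partition one element of [enumerateTripartitions()].
#' @param direction `"cause"` or `"effect"`.
#' @param mechState values of the full mechanism (union of the part
#'   mechanisms), aligned with the sorted mechanism.
#' @return a [Repertoire-class] over the union of the part purviews.
#' @export
partitionedRepertoire <- function(net, partition, direction, mechState) {
  direction <- match.arg(direction, c("cause", "effect"))
  mechanism <- sort(unlist(lapply(partition, `[[`, "mechanism")))
  purview <- sort(unlist(lapply(partition, `[[`, "purview")))
  ctx <- .phiContext(net, .fullState(net, mechanism, mechState))
  rZ <- numStatesPerNode(net)[purview]
  L <- max(1L, prod(rZ))
  q <- rep(1, L)
  for (part in partition) {
    if (length(part$purview) == 0L) next
    v <- .ctxRep(ctx, direction, .setToMask(part$mechanism),
                 .setToMask(part$purview))
    pos <- match(sort(part$purview), purview)
    projLocal <- .projMap(rZ, pos, .stateDigits(rZ))
    q <- q * v[projLocal + 1L]
  }
  rep <- .asRepertoire(ctx, purview, q)
  rep@isNull <- sum(q) == 0
  rep
}

#' Mechanism-level integrated information over one purview
#'
#' Minimizes the absolute intrinsic difference between the unpartitioned
#' cause or effect repertoire of `mechanism` over `purview` and its
#' partitioned counterpart, over all candidate tripartitions
#' ([enumerateTripartitions()]).  Ties keep the first partition in
#' enumeration order.  A null cause repertoire has phi 0.
#'
#' @inheritParams effectRepertoire
#' @param direction `"cause"` or `"effect"`.
#' @param config a [phiConfig()] list (only `phiCap` is consulted here).
#' @return list with `phi`, the minimizing `partition`, and the
#'   `specifiedState` (purview state maximizing the measure).
#' @export
phiMip <- function(net, mechanism, mechState, purview, direction,
                   config = phiConfig()) {
  direction <- match.arg(direction, c("cause", "effect"))
  mechanism <- .checkSubset(net, mechanism, "mechanism")
  purview <- .checkSubset(net, purview, "purview")
  if (length(purview) == 0L) stop("purview must be non-empty")
  ctx <- .phiContext(net, .fullState(net, mechanism, mechState))
  r <- .phiMipCtx(ctx, mechanism, purview, direction, config$phiCap)
  mo <- .miceObject(ctx, mechanism, direction,
                    c(r, list(Zset = purview)))
  list(phi = mo@phi, partition = mo@partition,
       specifiedState = mo@specifiedState)
}

#' Maximally irreducible cause or effect of a mechanism
#'
#' Maximizes [phiMip()] over all non-empty purviews.  Ties prefer the
#' largest purview, then the lexicographically first one.
#'
#' @inheritParams phiMip
#' @return a [Mice-class] object.
#' @export
mice <- function(net, mechanism, mechState, direction,
                 config = phiConfig()) {
  direction <- match.arg(direction, c("cause", "effect"))
  mechanism <- .checkSubset(net, mechanism, "mechanism")
  if (length(mechanism) == 0L) stop("mechanism must be non-empty")
  ctx <- .phiContext(net, .fullState(net, mechanism, mechState))
  .miceObject(ctx, mechanism, direction,
              .miceCtx(ctx, mechanism, direction, config$phiCap))
}

#' Causal distinction of a mechanism
#'
#' A mechanism forms a distinction iff both its maximally irreducible cause
#' and effect have phi > 0; the distinction's phi is the smaller of the two.
#'
#' @inheritParams phiMip
#' @return a [Distinction-class], or `NULL` if the mechanism is reducible.
#' @export
computeDistinction <- function(net, mechanism, mechState,
                               config = phiConfig()) {
  mechanism <- .checkSubset(net, mechanism, "mechanism")
  if (length(mechanism) == 0L) stop("mechanism must be non-empty")
  ctx <- .phiContext(net, .fullState(net, mechanism, mechState))
  .distinctionCtx(ctx, mechanism, config)
}

.distinctionCtx <- function(ctx, Mset, config) {
  cB <- .miceCtx(ctx, Mset, "cause", config$phiCap)
  if (cB$phi <= 0) return(NULL)
  eB <- .miceCtx(ctx, Mset, "effect", config$phiCap)
  if (eB$phi <= 0) return(NULL)
  new("Distinction", mechanism = as.integer(Mset),
      mechState = ctx$state[Mset],
      cause = .miceObject(ctx, Mset, "cause", cB),
      effect = .miceObject(ctx, Mset, "effect", eB),
      phi = min(cB$phi, eB$phi))
}

## phi of a mechanism on a (possibly cut) context without building objects.
.distinctionPhiCtx <- function(ctx, Mset, config) {
  cB <- .miceCtx(ctx, Mset, "cause", config$phiCap)
  if (cB$phi <= 0) return(0)
  eB <- .miceCtx(ctx, Mset, "effect", config$phiCap)
  min(cB$phi, eB$phi)
}

#' @rdname multiphi-accessors
#' @export
setMethod("phi", "Mice", function(x) x@phi)

#' @rdname multiphi-accessors
#' @export
setMethod("phi", "Distinction", function(x) x@phi)

setMethod("show", "Distinction", function(object) {
  cat(sprintf("Distinction: mechanism {%s} = (%s), phi = %.6g\n",
              paste(object@mechanism, collapse = ","),
              paste(object@mechState, collapse = ","), object@phi))
  cat(sprintf("  cause : purview {%s}, phi %.6g, specifies (%s)\n",
              paste(object@cause@purview, collapse = ","),
              object@cause@phi,
              paste(object@cause@specifiedState, collapse = ",")))
  cat(sprintf("  effect: purview {%s}, phi %.6g, specifies (%s)\n",
              paste(object@effect@purview, collapse = ","),
              object@effect@phi,
              paste(object@effect@specifiedState, collapse = ",")))
})
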
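# Brute-force oracles, kept deliberately naive and independent of the
# package's index/caching machinery: everything is computed by explicit
# loops over decoded states.

oracleDigit <- function(stateIdx, radices, node) {
  decodeState(stateIdx, radices)[node]
}

# Pr(node i -> value j | prior h) by explicit summation over TPM columns.
oracleNodeConditional <- function(net, i) {
  r <- numStatesPerNode(net)
  S <- prod(r)
  P <- tpm(net)
  out <- matrix(0, S, r[i])
  for (h in seq_len(S))
    for (s in seq_len(S)) {
      j <- oracleDigit(s - 1L, r, i)
      out[h, j + 1L] <- out[h, j + 1L] + P[h, s]
    }
  out
}

# Priors compatible with the mechanism being in mechState.
oracleCompatiblePriors <- function(net, mechanism, mechState) {
  r <- numStatesPerNode(net)
  keep <- c()
  for (h in seq_len(nStates(net))) {
    v <- decodeState(h - 1L, r)
    if (all(v[mechanism] == mechState)) keep <- c(keep, h)
  }
  keep
}

# Effect repertoire: per purview node, average its conditional over all
# priors compatible with the mechanism state; combine by explicit
# enumeration of purview states.
oracleEffectRep <- function(net, mechanism, mechState, purview) {
  r <- numStatesPerNode(net)
  purview <- sort(purview)
  if (length(purview) == 0L) return(1)
  rows <- if (length(mechanism)) {
    oracleCompatiblePriors(net, sort(mechanism),
                           mechState[order(mechanism)])
  } else seq_len(nStates(net))
  factors <- lapply(purview, function(z) {
    Tz <- oracleNodeConditional(net, z)
    colMeans(Tz[rows, , drop = FALSE])
  })
  rZ <- r[purview]
  L <- prod(rZ)
  v <- numeric(L)
  for (b in seq_len(L)) {
    vals <- decodeState(b - 1L, rZ)
    v[b] <- prod(vapply(seq_along(purview),
                        function(k) factors[[k]][vals[k] + 1L], numeric(1)))
  }
  v
}

# Cause repertoire, virtual-element decomposition: per mechanism node,
# marginalize its likelihood onto the purview by explicit enumeration of
# prior states; multiply across mechanism nodes; normalize.
oracleCauseRep <- function(net, mechanism, mechState, purview) {
  r <- numStatesPerNode(net)
  purview <- sort(purview)
  if (length(purview) == 0L) return(1)
  rZ <- r[purview]
  L <- prod(rZ)
  if (length(mechanism) == 0L) return(rep(1 / L, L))
  ord <- order(mechanism)
  mechanism <- mechanism[ord]; mechState <- mechState[ord]
  v <- rep(1, L)
  for (k in seq_along(mechanism)) {
    i <- mechanism[k]
    Ti <- oracleNodeConditional(net, i)
    marg <- numeric(L)
    for (h in seq_len(nStates(net))) {
      b <- encodeState(decodeState(h - 1L, r)[purview], rZ)
      marg[b + 1L] <- marg[b + 1L] + Ti[h, mechState[k] + 1L]
    }
    v <- v * marg
  }
  tot <- sum(v)
  if (tot == 0) rep(0, L) else v / tot
}

oracleAid <- function(p, q, cap = Inf) {
  best <- 0; bestState <- 0L
  for (s in seq_along(p)) {
    term <- if (p[s] <= 0) 0
            else if (q[s] <= 0) cap
            else p[s] * abs(log2(p[s] / q[s]))
    if (term > best) { best <- term; bestState <- s - 1L }
  }
  list(phi = best, state = bestState)
}

# All partitions of items 1..k into at most 3 unlabeled parts, via
# generate-all-labelings-and-canonicalize; identity excluded.
oraclePartitions <- function(k) {
  seen <- character()
  out <- list()
  for (code in 0:(3^k - 1)) {
    a <- integer(k)
    c0 <- code
    for (j in seq_len(k)) { a[j] <- c0 %% 3; c0 <- c0 %/% 3 }
    if (all(a == a[1])) next              # identity
    relabel <- integer(0)
    canon <- integer(k)
    for (j in seq_len(k)) {
      pos <- match(a[j], relabel)
      if (is.na(pos)) { relabel <- c(relabel, a[j]); pos <- length(relabel) }
      canon[j] <- pos - 1L
    }
    key <- paste(canon, collapse = "")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- canon
    }
  }
  out
}

# Independent phi: oracle repertoires + oracle partition enumeration +
# oracle AID, minimized by explicit loops.
oraclePhiMip <- function(net, mechanism, mechState, purview, direction,
                         cap = Inf) {
  mechanism <- sort(mechanism)
  purview <- sort(purview)
  repOf <- function(A, B) {
    ms <- mechState[match(A, mechanism)]
    if (direction == "effect") oracleEffectRep(net, A, ms, B)
    else oracleCauseRep(net, A, ms, B)
  }
  p <- repOf(mechanism, purview)
  if (sum(p) == 0) return(0)
  r <- numStatesPerNode(net)
  rZ <- r[purview]
  m <- length(mechanism); z <- length(purview)
  best <- Inf
  for (a in oraclePartitions(m + z)) {
    q <- rep(1, length(p))
    for (slot in 0:2) {
      A <- mechanism[which(a[seq_len(m)] == slot)]
      B <- purview[which(a[m + seq_len(z)] == slot)]
      if (length(B) == 0L) next
      vB <- repOf(A, B)
      pos <- match(B, purview)
      for (s in seq_along(q)) {
        vals <- decodeState(s - 1L, rZ)
        q[s] <- q[s] * vB[encodeState(vals[pos], r[B]) + 1L]
      }
    }
    best <- min(best, oracleAid(p, q, cap)$phi)
  }
  best
}

oracleMicePhi <- function(net, mechanism, mechState, direction) {
  n <- nNodes(net)
  best <- 0
  for (mask in seq_len(2L^n - 1L)) {
    Z <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    best <- max(best, oraclePhiMip(net, mechanism, mechState, Z, direction))
  }
  best
}

# Random probabilistic network satisfying conditional independence, built
# from independent random per-node conditionals.
randomFactorizableNet <- function(radices, seed) {
  set.seed(seed)
  S <- prod(radices)
  conds <- lapply(radices, function(k) {
    M <- matrix(runif(S * k), S, k)
    M / rowSums(M)
  })
  P <- matrix(1, S, S)
  for (i in seq_along(radices)) {
    for (s in seq_len(S)) {
      j <- oracleDigit(s - 1L, radices, i)
      P[, s] <- P[, s] * conds[[i]][, j + 1L]
    }
  }
  NetworkModel(P, radices)
}

# Deterministic copy-style helpers used across tests.
copyChainNet <- function() {
  # A -> B (B copies A), A holds its own value
  f <- evolutionFunction(c(2, 2), function(v) c(v[1], v[1]),
                         labels = c("A", "B"))
  networkFromFunction(f)
}
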
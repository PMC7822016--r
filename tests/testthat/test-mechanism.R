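test_that("the intrinsic difference has its closed-form extremes", {
  p <- c(0.25, 0.25, 0.25, 0.25)
  r <- aid(p, p)
  expect_equal(r$phi, 0)
  expect_identical(r$state, 0L)          # first state on ties
  # point mass against uniform over k states: log2(k) at the support state
  for (k in c(2L, 3L, 5L)) {
    p <- numeric(k); p[k] <- 1
    r <- aid(p, rep(1 / k, k))
    expect_equal(r$phi, log2(k))
    expect_identical(r$state, k - 1L)
  }
  # q = 0 where p > 0 diverges unless capped
  expect_equal(aid(c(1, 0), c(0, 1))$phi, Inf)
  expect_equal(aid(c(1, 0), c(0, 1), cap = 10)$phi, 10)
})

test_that("aid matches elementwise brute force on random pairs", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    q <- runif(4); q <- q / sum(q)
    expect_equal(aid(p, q), oracleAid(p, q))
  }
  expect_error(aid(c(1, 0), c(0.5, 0.25, 0.25)), "length")
})

test_that("tripartition enumeration matches an independent canonicalizer", {
  for (sz in list(c(1, 1), c(1, 2), c(2, 2), c(2, 3))) {
    parts <- enumerateTripartitions(seq_len(sz[1]), sz[1] + seq_len(sz[2]))
    expect_length(parts, length(oraclePartitions(sum(sz))))
    # no identity: at least two parts touched
    for (p in parts) {
      used <- sum(vapply(p, function(part)
        length(part$mechanism) + length(part$purview) > 0, logical(1)))
      expect_gte(used, 2)
    }
  }
  # the full cut {(m, 0), (0, z)} is among the 1x1 partitions
  parts <- enumerateTripartitions(1, 2)
  hasFullCut <- any(vapply(parts, function(p) {
    any(vapply(p, function(q)
      identical(q$mechanism, 1L) && length(q$purview) == 0L, logical(1))) &&
    any(vapply(p, function(q)
      length(q$mechanism) == 0L && identical(q$purview, 2L), logical(1)))
  }, logical(1)))
  expect_true(hasFullCut)
})

test_that("the full-cut partitioned repertoire is unconstrained", {
  net <- p53Model()
  part <- list(list(mechanism = 3L, purview = integer(0)),
               list(mechanism = integer(0), purview = 1L),
               list(mechanism = integer(0), purview = integer(0)))
  q <- partitionedRepertoire(net, part, "effect", mechState = 1L)
  expect_equal(probs(q), oracleEffectRep(net, integer(0), integer(0), 1))
  qc <- partitionedRepertoire(net, part, "cause", mechState = 1L)
  expect_equal(probs(qc), rep(1 / 3, 3))
})

test_that("partitioned repertoires compose part repertoires", {
  net <- p53Model()
  parts <- enumerateTripartitions(c(1, 3), c(2, 3))
  st <- c(0, 0, 1)
  for (p in parts[c(1, 5, 9, length(parts))]) {
    got <- probs(partitionedRepertoire(net, p, "effect",
                                       mechState = st[c(1, 3)]))
    manual <- rep(1, 4)
    for (part in p) {
      if (!length(part$purview)) next
      v <- oracleEffectRep(net, part$mechanism, st[part$mechanism],
                           part$purview)
      pos <- match(part$purview, c(2, 3))
      for (s in 1:4) {
        vals <- decodeState(s - 1L, c(2L, 2L))
        manual[s] <- manual[s] *
          v[encodeState(vals[pos], rep(2L, length(pos))) + 1L]
      }
      manual <- manual
    }
    expect_equal(got, manual, tolerance = 1e-12)
  }
})

test_that("phi vanishes without mechanism-purview dependence", {
  # mechanism with no parents in the purview (cause direction)
  f <- evolutionFunction(c(2, 2), function(v) c(1 - v[1], v[1]))
  net <- networkFromFunction(f)   # node 2's only parent is node 1
  r <- phiMip(net, mechanism = 2, mechState = 1, purview = 2,
              direction = "cause")
  expect_equal(r$phi, 0)
  # a constant node without outputs: phi = 0 for every purview
  fc <- evolutionFunction(c(2, 2), function(v) c(1, v[2]))
  netc <- networkFromFunction(fc)
  m <- mice(netc, mechanism = 1, mechState = 1, direction = "effect")
  expect_equal(phi(m), 0)
  mc <- mice(netc, mechanism = 1, mechState = 1, direction = "cause")
  expect_equal(phi(mc), 0)
})

test_that("phi is bounded by the full-cut difference and non-negative", {
  net <- p53Model()
  st <- c(0, 0, 1)
  for (mech in list(1L, 3L, c(1L, 3L))) {
    for (dir in c("cause", "effect")) {
      m <- mice(net, mech, st[mech], dir)
      expect_gte(phi(m), 0)
      fullCut <- oracleAid(
        probs(m@repertoire),
        if (dir == "effect")
          oracleEffectRep(net, integer(0), integer(0), m@purview)
        else rep(1 / prod(numStatesPerNode(net)[m@purview]),
                 prod(numStatesPerNode(net)[m@purview])))$phi
      expect_lte(phi(m), fullCut + 1e-12)
    }
  }
})

test_that("p53 mechanism {Mn}=1 irreducibly drives P", {
  net <- p53Model()
  m <- mice(net, mechanism = 3, mechState = 1, direction = "effect")
  expect_gt(phi(m), 0)
  r <- phiMip(net, 3, 1, purview = 1, direction = "effect")
  expect_equal(r$phi, oraclePhiMip(net, 3, 1L, 1, "effect"))
})

test_that("the copy chain's effect MICE lands on the copied node", {
  net <- copyChainNet()   # both nodes copy node 1; node 1 drives node 2
  m <- mice(net, mechanism = 1, mechState = 1, direction = "effect")
  expect_true(2 %in% m@purview)
  expect_gt(phi(m), 0)
})

test_that("the cause MICE of {P}=0 specifies Mn = 1", {
  net <- p53Model()
  m <- mice(net, mechanism = 1, mechState = 0, direction = "cause")
  expect_gt(phi(m), 0)
  expect_identical(m@purview, 3L)
  expect_identical(m@specifiedState, 1L)
})

test_that("search phi equals exhaustive enumeration on 2-node systems", {
  nets <- list(randomDeterministicNet("33", seed = 21),
               randomDeterministicNet("23", seed = 22),
               randomFactorizableNet(c(3, 3), seed = 23))
  for (net in nets) {
    r <- numStatesPerNode(net)
    expect_lte(nStates(net), 9)
    set.seed(31)
    st <- vapply(r, function(k) sample.int(k, 1) - 1L, integer(1))
    for (mech in list(1L, 2L, c(1L, 2L))) {
      for (dir in c("cause", "effect")) {
        m <- mice(net, mech, st[mech], dir)
        expect_equal(phi(m), oracleMicePhi(net, mech, st[mech], dir),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("severing all edges drives every phi to zero", {
  # replace every node's conditional by its input-marginalized version:
  # no node retains any parent (self-loops included), so no mechanism can
  # specify anything
  net <- randomDeterministicNet("222", seed = 9)
  conds <- lapply(nodeConditionals(net), function(Ti)
    matrix(colMeans(Ti), nrow(Ti), ncol(Ti), byrow = TRUE))
  dead <- NetworkModel(multiphi:::.tpmFromConditionals(conds, c(2, 2, 2)),
                       c(2, 2, 2))
  expect_true(all(inferAdjacency(dead) == 0L))
  st <- multiphi:::.withSeed(9, multiphi:::.sampleReachableState(dead))
  ces <- computeCes(dead, st)
  expect_identical(nDistinctions(ces), 0L)
})

test_that("distinction phi is the minimum over directions", {
  net <- p53Model()
  d <- computeDistinction(net, mechanism = 1, mechState = 0)
  expect_s4_class(d, "Distinction")
  expect_equal(phi(d), min(d@cause@phi, d@effect@phi))
  expect_gt(phi(d), 0)
  # an isolated (input- and output-free) node forms no distinction
  f <- evolutionFunction(c(2, 2), function(v) c(v[1], 0))
  net2 <- networkFromFunction(f)
  expect_null(computeDistinction(net2, mechanism = 2, mechState = 0))
})
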
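test_that("the p53 CES at the attractor is purely first-order", {
  net <- p53Model()
  ces <- computeCes(net, c(0, 0, 1))
  expect_identical(nDistinctions(ces), 3L)
  orders <- vapply(distinctions(ces), function(d)
    length(d@mechanism), integer(1))
  expect_true(all(orders == 1L))
  expect_equal(sumPhi(ces),
               sum(vapply(distinctions(ces), phi, numeric(1))))
})

test_that("a CES never exceeds 2^N - 1 distinctions", {
  for (seed in 1:4) {
    net <- randomDeterministicNet("223", seed = seed)
    st <- multiphi:::.withSeed(seed, multiphi:::.sampleReachableState(net))
    expect_lte(nDistinctions(computeCes(net, st)), 2^3 - 1)
  }
})

test_that("a fully disconnected system has an empty CES and Phi = 0", {
  P <- matrix(1 / 4, 4, 4)   # both nodes uniformly random regardless of input
  net <- NetworkModel(P, c(2, 2))
  ces <- computeCes(net, c(0, 0))
  expect_identical(nDistinctions(ces), 0L)
  expect_equal(bigPhi(sia(net, c(0, 0))), 0)
})

test_that("phi loss under a cut matches independent recomputation", {
  net <- randomDeterministicNet("33", seed = 14)
  st <- multiphi:::.withSeed(14, multiphi:::.sampleReachableState(net))
  ces <- computeCes(net, st)
  res <- cesPhiUnderCut(net, st, ces, from = 1, to = 2)
  cutNet <- applyCut(net, 1, 2)
  manual <- vapply(distinctions(ces), function(d) {
    cphi <- oracleMicePhi(cutNet, d@mechanism, d@mechState, "cause")
    ephi <- oracleMicePhi(cutNet, d@mechanism, d@mechState, "effect")
    min(cphi, ephi)
  }, numeric(1))
  expect_equal(res$phis, manual, tolerance = 1e-9)
  intact <- vapply(distinctions(ces), phi, numeric(1))
  expect_equal(res$loss, sum(abs(intact - manual)), tolerance = 1e-9)
})

test_that("a cut that severs nothing loses nothing", {
  # two side-by-side loops: 1 <-> 2 and 3 <-> 4 (binary)
  f <- evolutionFunction(c(2, 2, 2, 2),
                         function(v) c(v[2], v[1], v[4], v[3]))
  net <- networkFromFunction(f)
  st <- c(0, 1, 1, 0)
  ces <- computeCes(net, st)
  expect_gt(nDistinctions(ces), 0)
  res <- cesPhiUnderCut(net, st, ces, from = c(1, 2), to = c(3, 4))
  expect_equal(res$loss, 0)
  # hence two independent subsystems side by side are reducible
  s <- sia(net, st)
  expect_equal(bigPhi(s), 0)
})

test_that("sia reports the minimal cut and non-negative Phi", {
  net <- p53Model()
  s <- sia(net, c(0, 0, 1))
  expect_gte(bigPhi(s), 0)
  # Phi equals the smallest loss over all 2^n - 2 unidirectional cuts
  losses <- vapply(seq_len(2^3 - 2), function(mask) {
    from <- which(bitwAnd(mask, c(1L, 2L, 4L)) != 0L)
    cesPhiUnderCut(net, c(0, 0, 1), s@ces, from,
                   setdiff(1:3, from))$loss
  }, numeric(1))
  expect_equal(bigPhi(s), min(losses))
  cut <- mipCut(s)
  expect_setequal(c(cut$from, cut$to), 1:3)
})

test_that("unreachable states are rejected unless asked to zero", {
  # node 1 constant 1, node 2 copies node 1: (0,*) columns are empty
  f <- evolutionFunction(c(2, 2), function(v) c(1, v[1]))
  net <- networkFromFunction(f)
  expect_error(sia(net, c(0, 0)), "unreachable")
  s <- sia(net, c(0, 0), unreachable = "zero")
  expect_equal(bigPhi(s), 0)
  expect_identical(nDistinctions(s@ces), 0L)
})

test_that("shared-TPM readings generally disagree on Phi but not EI", {
  net4 <- randomDeterministicNet("2222", seed = 18)
  net2 <- reinterpretNet(net4, c(4, 4))
  expect_equal(effectiveInformation(net4), effectiveInformation(net2))
  st <- multiphi:::.withSeed(18, multiphi:::.sampleReachableState(net4))
  sIdx <- encodeState(st, c(2, 2, 2, 2))
  p4 <- bigPhi(sia(net4, st, unreachable = "zero"))
  p2 <- bigPhi(sia(net2, decodeState(sIdx, c(4, 4)), unreachable = "zero"))
  # the decompositions see different composition: counts differ
  expect_false(isTRUE(all.equal(p4, p2)))
})

test_that("single-node systems have Phi = 0 and at most one distinction", {
  net <- NetworkModel(matrix(c(0.2, 0.8, 0.8, 0.2), 2, byrow = TRUE), 2L)
  s <- sia(net, 0L)
  expect_equal(bigPhi(s), 0)
  expect_lte(nDistinctions(s@ces), 1L)
  expect_length(s@cutFrom, 0)
})

test_that("the major complex ignores appended isolated nodes", {
  # strongly integrated pair plus a noisy isolated third node
  f <- evolutionFunction(c(2, 2), function(v) c(v[2], 1 - v[1]))
  pairNet <- networkFromFunction(f)
  conds <- nodeConditionals(pairNet)
  S <- 8
  cond3 <- matrix(0.5, S, 2)
  conds8 <- list(conds[[1]][rep(1:4, 2), ], conds[[2]][rep(1:4, 2), ], cond3)
  bigNet <- NetworkModel(multiphi:::.tpmFromConditionals(conds8, c(2, 2, 2)),
                         c(2, 2, 2))
  mc <- majorComplex(bigNet, c(0, 1, 0))
  expect_identical(mc@subsystem, c(1L, 2L))
  pairPhi <- bigPhi(sia(pairNet, c(0, 1)))
  expect_equal(bigPhi(mc), pairPhi, tolerance = 1e-9)
  # a strongly integrated pair is its own major complex (single nodes
  # admit no cut and score Phi = 0 by definition)
  expect_gt(pairPhi, 0)
  mc2 <- majorComplex(pairNet, c(0, 1))
  expect_identical(mc2@subsystem, c(1L, 2L))
  expect_equal(bigPhi(mc2), pairPhi)
})

test_that("SIA results serialize to parseable JSON", {
  s <- sia(p53Model(), c(0, 0, 1))
  js <- siaToJson(s)
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(obj$bigPhi, bigPhi(s))
  expect_length(obj$distinctions, nDistinctions(s@ces))
  expect_equal(obj$schema, "multiphi/sia/1")
})
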
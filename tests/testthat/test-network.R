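# Correlated-output TPM on 2 binary nodes: every row sends the pair to
# (0,0) or (1,1) with probability 1/2 each.  Rows are valid distributions
# but the joint does not factorize into per-node conditionals.
correlatedNet <- function() {
  P <- matrix(0, 4, 4)
  P[, 1] <- 0.5; P[, 4] <- 0.5
  NetworkModel(P, c(2, 2))
}

test_that("the p53 model validates cleanly", {
  rep <- validateNetwork(p53Model())
  expect_true(rep$valid)
  expect_length(rep$problems, 0)
})

test_that("shape and row-sum violations are caught", {
  expect_error(NetworkModel(matrix(0.25, 4, 4), c(3, 2)), "prod\\(numStates\\)")
  expect_error(NetworkModel(matrix(0.25, 4, 5), c(2, 2)), "square")
  P <- diag(4); P[2, ] <- P[2, ] * 0.5
  expect_error(NetworkModel(P, c(2, 2)), "row 2")
})

test_that("conditional independence violations are detected and reported", {
  net <- correlatedNet()
  ci <- checkConditionalIndependence(net)
  expect_false(ci$ok)
  expect_gt(ci$maxDeviation, 0.2)
  rep <- validateNetwork(net)
  expect_false(rep$valid)
  expect_true(any(grepl("conditional independence", rep$problems)))
})

test_that("deterministic TPMs always factorize exactly", {
  for (seed in 1:3) {
    net <- randomDeterministicNet("332", seed = seed)
    ci <- checkConditionalIndependence(net)
    expect_true(ci$ok)
    expect_identical(ci$maxDeviation, 0)
  }
  # product-built probabilistic net factorizes too
  expect_true(checkConditionalIndependence(ternaryNeuronModel(0.2))$ok)
})

test_that("node conditionals marginalize the TPM rows and multiply back", {
  net <- p53Model()
  conds <- nodeConditionals(net)
  # Table row (0,0,0) -> (2,0,1): point masses on the successor values
  h <- encodeState(c(0, 0, 0), c(3, 2, 2)) + 1L
  expect_equal(conds[[1]][h, ], c(0, 0, 1))   # P' = 2
  expect_equal(conds[[2]][h, ], c(1, 0))      # Mc' = 0
  expect_equal(conds[[3]][h, ], c(0, 1))      # Mn' = 1
  expect_true(all(vapply(conds, function(Ti)
    max(abs(rowSums(Ti) - 1)), numeric(1)) < 1e-10))
  # independent reconstruction against the naive oracle
  for (i in 1:3) expect_equal(conds[[i]], oracleNodeConditional(net, i))
  P2 <- multiphi:::.tpmFromConditionals(conds, numStatesPerNode(net))
  expect_equal(P2, tpm(net))
})

test_that("adjacency inference recovers the p53 wiring", {
  A <- inferAdjacency(p53Model())
  expected <- matrix(0L, 3, 3, dimnames = list(c("P", "Mc", "Mn"),
                                               c("P", "Mc", "Mn")))
  expected["Mn", "P"] <- 1L   # Mn degrades P
  expected["P", "Mc"] <- 1L   # P up-regulates Mc
  expected["P", "Mn"] <- 1L   # P inhibits nuclear import
  expected["Mc", "Mn"] <- 1L  # Mc feeds Mn
  expect_identical(A, expected)
})

test_that("adjacency of degenerate maps is as expected", {
  P <- matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4)
  expect_true(all(inferAdjacency(NetworkModel(P, c(2, 2))) == 0L))
  idNet <- networkFromFunction(evolutionFunction(c(2, 2), function(v) v))
  expect_identical(unname(inferAdjacency(idNet)),
                   matrix(c(1L, 0L, 0L, 1L), 2))
})

test_that("applyCut marginalizes severed inputs with uniform noise", {
  # copy chain: cutting A -/-> B makes B's conditional uniform
  net <- copyChainNet()
  cut <- applyCut(net, from = 1, to = 2)
  condsB <- nodeConditionals(cut)[[2]]
  expect_true(all(abs(condsB - 0.5) < 1e-12))
  # A's self-dependence is untouched
  expect_equal(nodeConditionals(cut)[[1]], nodeConditionals(net)[[1]])

  # p53 cut {P} -/-> {Mc, Mn}: Mc' conditional becomes the average of the
  # intact conditional over P in {0, 1, 2}
  p53 <- p53Model()
  cut53 <- applyCut(p53, from = 1, to = c(2, 3))
  conds <- nodeConditionals(p53)
  condsCut <- nodeConditionals(cut53)
  r <- c(3, 2, 2)
  for (h in seq_len(12)) {
    v <- decodeState(h - 1L, r)
    rows <- vapply(0:2, function(p)
      encodeState(c(p, v[2], v[3]), r) + 1L, integer(1))
    expect_equal(condsCut[[2]][h, ], colMeans(conds[[2]][rows, ]))
    expect_equal(condsCut[[3]][h, ], colMeans(conds[[3]][rows, ]))
  }
})

test_that("applyCut is idempotent and never adds parents", {
  for (seed in 1:3) {
    net <- randomDeterministicNet("223", seed = seed)
    cut <- applyCut(net, from = c(1, 3), to = 2)
    cut2 <- applyCut(cut, from = c(1, 3), to = 2)
    expect_equal(tpm(cut), tpm(cut2))
    expect_true(all(inferAdjacency(cut) <= inferAdjacency(net)))
  }
  # a cut with no crossing edges leaves the TPM unchanged
  two <- networkFromFunction(
    evolutionFunction(c(2, 2), function(v) c(1 - v[1], v[2])))
  expect_equal(tpm(applyCut(two, 1, 2)), tpm(two))
  expect_error(applyCut(two, 1:2, integer(0)), "bipartition")
})

test_that("effective information has the right extremes and invariances", {
  idNet <- networkFromFunction(evolutionFunction(c(2, 2, 2), function(v) v))
  expect_equal(effectiveInformation(idNet), 3)
  constNet <- NetworkModel(matrix(rep(c(1, rep(0, 7)), each = 8), 8, 8),
                           c(2, 2, 2))
  expect_equal(effectiveInformation(constNet), 0)
  net <- randomDeterministicNet("2222", seed = 2)
  expect_equal(effectiveInformation(net),
               effectiveInformation(reinterpretNet(net, c(4, 4))))
  expect_lte(effectiveInformation(net), 4)
})
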
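goldenPath <- function() {
  system.file("extdata", "p53_table3_binarizations.tsv",
              package = "multiphi", mustWork = TRUE)
}

test_that("asymptotic functions are recognized", {
  expect_true(isAsymptotic(p53Function()))
  # P: 0 -> 1 with max 2 is neither 0, current, nor max
  bad <- evolutionFunction(c(3, 2), function(v)
    c(if (v[1] == 0) 1 else v[1], v[2]))
  expect_false(isAsymptotic(bad))
  expect_error(faureKaji(bad), "not asymptotic")
  # all-binary functions are always asymptotic
  set.seed(5)
  f2 <- evolutionFunction(c(2, 2), sample(0:3, 4, replace = TRUE))
  expect_true(isAsymptotic(f2))
})

test_that("the Van Ham expansion of p53 covers 12 of 16 binary states", {
  vh <- vanHam(p53Function())
  expect_identical(sum(vh@admissible), 12L)
  expect_identical(length(vh@admissible), 16L)
  expect_equal(vanHamCompletionCount(vh), 16^4)
  # P = 1 maps to (P1, P2) = (1, 0); (0, 1) has no pre-image
  s2b <- vh@stateToBinary
  b <- s2b[encodeState(c(1, 0, 0), c(3, 2, 2)) + 1L]
  expect_identical(decodeState(b, rep(2L, 4)), c(1L, 0L, 0L, 0L))
  expect_false(vh@admissible[encodeState(c(0, 1, 0, 0), rep(2L, 4)) + 1L])
  # non-admissible rows are undefined
  expect_true(all(is.na(
    vh@binaryFunction@successor[!vh@admissible])))
  # the state map restricted to admissible states is a bijection
  expect_identical(sort(s2b), which(vh@admissible) - 1L)
})

test_that("binary-only input binarizes to itself, fully admissible", {
  set.seed(8)
  f <- evolutionFunction(c(2, 2, 2), sample(0:7, 8, replace = TRUE))
  for (conv in list(vanHam(f), faureKaji(f), tonello(f))) {
    expect_true(all(conv@admissible))
    expect_identical(conv@binaryFunction@successor, f@successor)
    expect_identical(conv@stateToBinary, 0:7)
  }
})

test_that("Faure-Kaji and Tonello reproduce the printed p53 table", {
  f <- p53Function()
  golden <- readBinarizationTables(goldenPath())
  expect_identical(faureKaji(f)@binaryFunction@successor,
                   golden$faureKaji@successor)
  expect_identical(tonello(f)@binaryFunction@successor,
                   golden$tonello@successor)
  expect_identical(vanHam(f)@binaryFunction@successor,
                   golden$vanHam@successor)
  expect_identical(vanHam(f)@admissible, golden$admissible)
  # writer emits the golden layout byte for byte
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  writeBinarizationTables(f, tmp)
  expect_identical(readLines(tmp), readLines(goldenPath()))
})

test_that("specific printed rows are reproduced", {
  f <- p53Function()
  r2 <- rep(2L, 4)
  fk <- faureKaji(f)@binaryFunction
  # non-admissible (P1,P2,Mc,Mn) = (0,1,0,0) maps to (1,1,0,0)
  expect_identical(
    decodeState(fk@successor[encodeState(c(0, 1, 0, 0), r2) + 1L], r2),
    c(1L, 1L, 0L, 0L))
  tn <- tonello(f)@binaryFunction
  expect_identical(
    decodeState(tn@successor[encodeState(c(0, 0, 0, 0), r2) + 1L], r2),
    c(1L, 0L, 0L, 1L))
  expect_identical(
    decodeState(tn@successor[encodeState(c(1, 1, 1, 1), r2) + 1L], r2),
    c(1L, 0L, 1L, 1L))
  expect_identical(
    decodeState(tn@successor[encodeState(c(1, 1, 0, 1), r2) + 1L], r2),
    c(1L, 0L, 1L, 0L))
})

test_that("Faure-Kaji restricted to admissible states equals Van Ham", {
  for (seed in 1:5) {
    f <- randomAsymptoticFunction(c(3, 2), seed = seed)
    vh <- vanHam(f); fk <- faureKaji(f)
    adm <- which(vh@admissible)
    expect_identical(fk@binaryFunction@successor[adm],
                     vh@binaryFunction@successor[adm])
  }
})

test_that("coarse-graining a Faure-Kaji model reconstructs the original", {
  cases <- list(c(3, 2), c(3, 3), c(4, 2), c(3, 2, 2))
  for (k in seq_along(cases)) {
    f <- randomAsymptoticFunction(cases[[k]], seed = 40 + k)
    fk <- faureKaji(f)
    net <- networkFromFunction(fk@binaryFunction)
    grouping <- fk@groups
    stateMap <- lapply(grouping, function(g) sumStateMap(length(g)))
    mac <- coarseGrain(net, grouping, stateMap)
    expect_equal(tpm(mac), tpm(networkFromFunction(f)))
    # deterministic in, deterministic out
    expect_true(all(tpm(mac) %in% c(0, 1)))
  }
})

test_that("coarse-graining with the identity grouping is a no-op", {
  net <- p53Model()
  mac <- coarseGrain(net, list(1, 2, 3), list(0:2, 0:1, 0:1),
                     labels = nodeLabels(net))
  expect_equal(tpm(mac), tpm(net))
  expect_error(coarseGrain(net, list(1, 2), list(0:2, 0:1)), "partition")
  expect_error(coarseGrain(net, list(1, 2, 3), list(0:2, 0:1, c(0L, 0L))),
               "at least 2")
})

test_that("the probabilistic binarization coarse-grains back exactly", {
  # deliberately non-asymptotic: P steps 0 -> 1 -> 2 -> 0
  f <- evolutionFunction(c(3, 2), function(v)
    c((v[1] + 1) %% 3, 1 - v[2]))
  expect_false(isAsymptotic(f))
  net <- probabilisticBinarization(f)
  expect_equal(rowSums(tpm(net)), rep(1, 8), tolerance = 1e-12)
  mac <- coarseGrain(net, list(c(1, 2), 3), list(sumStateMap(2), 0:1))
  expect_equal(tpm(mac), tpm(networkFromFunction(f)))
})
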
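## Batch drivers for the random-network surveys.  Every record is derived
## from its own sub-seed (seed + record index), so runs are reproducible
## record-by-record and interrupted CSV runs can resume where they left
## off.

## Sample one state uniformly from the reachable states of a network (the
## states with nonzero TPM column mass: states that occur as successors).
.sampleReachableState <- function(net) {
  reach <- which(colSums(tpm(net)) > 0)
  idx <- reach[sample.int(length(reach), 1L)]
  decodeState(idx - 1L, numStatesPerNode(net))
}

.bootMeanCi <- function(x, B = 1000L) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(c(lower = NA_real_, upper = NA_real_))
  means <- vapply(seq_len(B), function(b)
    mean(x[sample.int(length(x), length(x), replace = TRUE)]), numeric(1))
  c(lower = unname(quantile(means, 0.025)),
    upper = unname(quantile(means, 0.975)))
}

.summaryStats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA, q25 = NA, median = NA, q75 = NA))
  c(mean = mean(x), q25 = unname(quantile(x, 0.25)),
    median = unname(median(x)), q75 = unname(quantile(x, 0.75)))
}

#' Survey a random-network class
#'
#' Generates `nSamples` random deterministic networks of the class, picks
#' one reachable state per network uniformly at random, and records the
#' size of the CES, its mean small phi, the integrated information
#' (optional) and the effective information.
#'
#' @param label class label (see [classLabel()]).
#' @param nSamples number of networks.
#' @param seed integer; record `i` uses sub-seed `seed + i`.
#' @param computePhi run the full [sia()] per network (set `FALSE` to
#'   survey CES sizes only, which is considerably faster).
#' @param config a [phiConfig()].
#' @param out optional CSV path; records are appended as they complete and
#'   an existing file is resumed from its last row.
#' @return list with `records` (data.frame: one row per network) and
#'   `summary` (mean/quartiles and 95% bootstrap CIs of the means of Phi,
#'   mean small phi and the distinction count).
#' @export
runClassSurvey <- function(label, nSamples, seed = 1L, computePhi = TRUE,
                           config = phiConfig(), out = NULL) {
  stopifnot(nSamples >= 1L)
  records <- NULL
  start <- 1L
  if (!is.null(out) && file.exists(out)) {
    records <- utils::read.csv(out, stringsAsFactors = FALSE)
    start <- nrow(records) + 1L
  }
  newRows <- vector("list", max(0L, nSamples - start + 1L))
  for (i in seq.int(start, length.out = max(0L, nSamples - start + 1L))) {
    rec <- .withSeed(seed + i, {
      net <- randomDeterministicNet(label)
      state <- .sampleReachableState(net)
      ces <- computeCes(net, state, config)
      bp <- if (computePhi) {
        if (length(ces@distinctions) == 0L) 0
        else bigPhi(sia(net, state, config))
      } else NA_real_
      data.frame(class = label, index = i, seed = seed + i,
                 state = paste(state, collapse = ""),
                 bigPhi = bp, meanSmallPhi = meanSmallPhi(ces),
                 sumPhi = sumPhi(ces), nDistinctions = nDistinctions(ces),
                 effectiveInformation = effectiveInformation(net),
                 stringsAsFactors = FALSE)
    })
    newRows[[i - start + 1L]] <- rec
    if (!is.null(out))
      utils::write.table(rec, out, sep = ",", append = file.exists(out),
                         col.names = !file.exists(out), row.names = FALSE)
  }
  records <- rbind(records, do.call(rbind, newRows))
  summary <- list(
    bigPhi = c(.summaryStats(records$bigPhi),
               .bootMeanCi(records$bigPhi)),
    meanSmallPhi = c(.summaryStats(records$meanSmallPhi),
                     .bootMeanCi(records$meanSmallPhi)),
    nDistinctions = c(.summaryStats(records$nDistinctions),
                      .bootMeanCi(records$nDistinctions)))
  list(records = records, summary = summary)
}

#' Compare Phi across a pair of classes with or without shared TPMs
#'
#' For a shared pair (e.g. `c("2222", "44(2222)")`) each draw yields one
#' matrix read under both node decompositions and evaluated at the same
#' sampled state, so the per-network Phi values are paired; for an
#' independent pair both classes are drawn separately.  Reports the
#' Pearson correlation of Phi and two-sample Kolmogorov-Smirnov statistics
#' on the Phi and mean-small-phi distributions.
#'
#' @param pair character vector of two class labels; sharing is inferred
#'   from a parenthesized suffix on the second label, or forced with
#'   `shared`.
#' @param n number of network pairs.
#' @param seed integer seed (sub-seed per record, as in
#'   [runClassSurvey()]).
#' @param shared override the sharing inference (logical).
#' @param config a [phiConfig()].
#' @return list with `records`, `correlation` (`estimate`, `p.value`), and
#'   `ks` (statistics/p-values for Phi and mean small phi).
#' @export
runSharedTpmComparison <- function(pair, n, seed = 1L, shared = NULL,
                                   config = phiConfig()) {
  stopifnot(length(pair) == 2L)
  clB <- classLabel(pair[2])
  if (is.null(shared)) shared <- !is.null(clB$sharedWith) ||
    identical(pair[1], pair[2])
  evalNet <- function(net, state) {
    s <- sia(net, state, config, unreachable = "zero")
    c(bigPhi = s@bigPhi, meanSmallPhi = meanSmallPhi(s@ces))
  }
  rows <- lapply(seq_len(n), function(i) {
    a <- .withSeed(seed + i, {
      netA <- randomDeterministicNet(pair[1])
      stateA <- .sampleReachableState(netA)
      list(net = netA, state = stateA)
    })
    b <- if (shared) {
      netB <- reinterpretNet(a$net, clB$radices)
      sIdx <- encodeState(a$state, numStatesPerNode(a$net))
      list(net = netB, state = decodeState(sIdx, clB$radices))
    } else {
      .withSeed(seed + n + i, {
        netB <- randomDeterministicNet(pair[2])
        list(net = netB, state = .sampleReachableState(netB))
      })
    }
    va <- evalNet(a$net, a$state)
    vb <- evalNet(b$net, b$state)
    data.frame(index = i, bigPhiA = va[1], meanSmallPhiA = va[2],
               bigPhiB = vb[1], meanSmallPhiB = vb[2],
               eiA = effectiveInformation(a$net),
               eiB = effectiveInformation(b$net))
  })
  records <- do.call(rbind, rows)
  ct <- if (sd(records$bigPhiA) == 0 || sd(records$bigPhiB) == 0)
    list(estimate = NA_real_, p.value = NA_real_)
  else cor.test(records$bigPhiA, records$bigPhiB)
  ksSafe <- function(x, y) {
    k <- suppressWarnings(ks.test(x, y))
    list(statistic = unname(k$statistic), p.value = k$p.value)
  }
  list(records = records,
       shared = shared,
       correlation = list(estimate = unname(ct$estimate),
                          p.value = ct$p.value),
       ks = list(bigPhi = ksSafe(records$bigPhiA, records$bigPhiB),
                 meanSmallPhi = ksSafe(
                   records$meanSmallPhiA[!is.na(records$meanSmallPhiA)],
                   records$meanSmallPhiB[!is.na(records$meanSmallPhiB)])))
}

#' Correlation of Phi between multi-valued systems and their binarizations
#'
#' Draws random asymptotic evolution functions of the class, computes the
#' whole-system Phi of each at the first TPM state (the all-zero state,
#' whose Van Ham image is again the all-zero state), and the Phi of the
#' Faure-Kaji and Tonello binarizations at the mapped state.  States that
#' are unreachable in a draw contribute Phi = 0 (they specify no causes).
#'
#' @param label class label giving the radices (e.g. `"32"`).
#' @param n number of functions.
#' @param seed integer seed (sub-seed per record).
#' @param config a [phiConfig()].
#' @return list with `records` and per-method Pearson `r` and `p`.
#' @export
runBinarizationCorrelation <- function(label, n, seed = 1L,
                                       config = phiConfig()) {
  radices <- classLabel(label)$radices
  rows <- lapply(seq_len(n), function(i) {
    f <- randomAsymptoticFunction(radices, seed + i)
    net <- networkFromFunction(f)
    phiAt0 <- function(nw) {
      st <- integer(nNodes(nw))
      bigPhi(sia(nw, st, config, unreachable = "zero"))
    }
    data.frame(index = i,
               phiOriginal = phiAt0(net),
               phiFaureKaji = phiAt0(
                 networkFromFunction(faureKaji(f)@binaryFunction)),
               phiTonello = phiAt0(
                 networkFromFunction(tonello(f)@binaryFunction)))
  })
  records <- do.call(rbind, rows)
  corOf <- function(y) {
    if (sd(records$phiOriginal) == 0 || sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- cor.test(records$phiOriginal, y)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(records = records,
       faureKaji = corOf(records$phiFaureKaji),
       tonello = corOf(records$phiTonello))
}
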
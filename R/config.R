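#' Analysis configuration
#'
#' Bundles the settings of the causal analysis.  The partition scheme
#' (mechanism-level tripartitions), the repertoire comparison measure
#' (absolute intrinsic difference), the use of the small-phi difference for
#' the CES distance under system cuts, and the assumption that cuts cannot
#' create new distinctions are the package's canonical configuration; the
#' measure sits behind [aid()] so alternatives can be swapped in, but only
#' `"AID"` is provided.
#'
#' @param partitionType mechanism partition family; only `"TRI"`.
#' @param measure repertoire difference measure; only `"AID"`.
#' @param tolerance absolute tolerance for row sums and the conditional
#'   independence check.
#' @param phiCap cap for infinite intrinsic-difference terms arising when a
#'   partition assigns probability 0 to a state the unpartitioned
#'   repertoire supports; default `Inf` (uncapped).
#' @param smallPhiDifferenceForCes Phi is the absolute sum of phi lost from
#'   the CES under the minimum information partition (fixed `TRUE`).
#' @param cutsCannotCreateConcepts under a system cut only the intact CES's
#'   mechanisms are re-evaluated (fixed `TRUE`).
#' @param seed optional integer seed recorded for drivers.
#' @return a list of class `phiConfig`.
#' @export
phiConfig <- function(partitionType = "TRI", measure = "AID",
                      tolerance = 1e-10, phiCap = Inf,
                      smallPhiDifferenceForCes = TRUE,
                      cutsCannotCreateConcepts = TRUE, seed = NULL) {
  partitionType <- match.arg(partitionType)
  measure <- match.arg(measure)
  stopifnot(isTRUE(smallPhiDifferenceForCes),
            isTRUE(cutsCannotCreateConcepts),
            tolerance > 0, phiCap > 0)
  structure(list(partitionType = partitionType, measure = measure,
                 tolerance = tolerance, phiCap = phiCap,
                 smallPhiDifferenceForCes = smallPhiDifferenceForCes,
                 cutsCannotCreateConcepts = cutsCannotCreateConcepts,
                 seed = seed),
            class = "phiConfig")
}

## Run expr with a temporary RNG state seeded by `seed` (NULL = use the
## current stream).  Restores the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
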
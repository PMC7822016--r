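## Mixed-radix state arithmetic.
##
## Convention (fixed package-wide and in all file formats): states are tuples
## of per-node values, 0-based; the scalar index of a state is little-endian,
## i.e. node 1 varies fastest:  index = v1 + v2*S1 + v3*S1*S2 + ...
## Indices are 0-based internally where noted; the exported encode/decode
## functions use 0-based indices to match the on-disk row order (row r+1 of a
## TPM file holds state index r).

#' Encode a system state as a mixed-radix index
#'
#' Maps a tuple of per-node state values to the row/column index of the
#' state-by-state TPM, using the little-endian convention (first node varies
#' fastest): `index = v[1] + v[2]*r[1] + v[3]*r[1]*r[2] + ...`.
#'
#' @param state integer vector of per-node values, `0 <= state[i] < radices[i]`.
#' @param radices integer vector of per-node state counts (each >= 2... or 1
#'   is rejected; a node must have at least two states).
#' @return 0-based integer index in `0:(prod(radices) - 1)`.
#' @seealso [decodeState()]
#' @examples
#' encodeState(c(2, 1, 0), c(3, 2, 2))  # 2 + 1*3 + 0*6 = 5
#' @export
encodeState <- function(state, radices) {
  radices <- as.integer(radices)
  state <- as.integer(state)
  if (length(state) != length(radices))
    stop("state has length ", length(state), " but there are ",
         length(radices), " nodes")
  if (any(state < 0L) || any(state >= radices))
    stop("state value out of range for the given radices: (",
         paste(state, collapse = ","), ") with radices (",
         paste(radices, collapse = ","), ")")
  weights <- cumprod(c(1L, radices[-length(radices)]))
  as.integer(sum(state * weights))
}

#' Decode a mixed-radix index into a system state
#'
#' Exact inverse of [encodeState()].
#'
#' @param index 0-based state index.
#' @param radices integer vector of per-node state counts.
#' @return integer vector of per-node values.
#' @examples
#' decodeState(5, c(3, 2, 2))  # c(2, 1, 0)
#' @export
decodeState <- function(index, radices) {
  radices <- as.integer(radices)
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L ||
      index >= prod(radices))
    stop("index out of range [0, ", prod(radices) - 1L, "]")
  vals <- integer(length(radices))
  for (i in seq_along(radices)) {
    vals[i] <- index %% radices[i]
    index <- index %/% radices[i]
  }
  vals
}

## n x S matrix whose column s (1-based) holds the digits of state s-1.
.stateDigits <- function(radices) {
  S <- prod(radices)
  n <- length(radices)
  d <- matrix(0L, n, S)
  idx <- 0:(S - 1)
  for (i in seq_len(n)) {
    d[i, ] <- as.integer(idx %% radices[i])
    idx <- idx %/% radices[i]
  }
  d
}

## Projection of full state indices onto a node subset: returns an integer
## vector p of length S with p[s] = little-endian index (0-based) of the
## substate of s-1 on `subset` (ascending node indices).  subset may be
## empty (all zeros).
.projMap <- function(radices, subset, digits = .stateDigits(radices)) {
  S <- prod(radices)
  if (length(subset) == 0L) return(integer(S))
  sub <- sort(subset)
  w <- cumprod(c(1L, radices[sub][-length(sub)]))
  as.integer(colSums(digits[sub, , drop = FALSE] * w))
}

## 1-based state indices grouped by substate on `subset`: a matrix with
## prod(radices[subset]) columns; column b+1 lists the full states whose
## projection equals b.  Used for fast marginalization via colSums.
.gatherIdx <- function(radices, subset, digits = .stateDigits(radices)) {
  p <- .projMap(radices, subset, digits)
  matrix(order(p), ncol = max(1L, prod(radices[subset])))
}

## All non-empty subsets of 1:n as a list of ascending integer vectors,
## ordered by bitmask value (node 1 = lowest bit).  Deterministic canonical
## enumeration order used throughout the package.
.allSubsets <- function(n, nonEmpty = TRUE) {
  masks <- seq.int(if (nonEmpty) 1L else 0L, 2L^n - 1L)
  lapply(masks, .maskToSet)
}

.maskToSet <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L)

.setToMask <- function(set) {
  if (length(set) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(set) - 1L))
}
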
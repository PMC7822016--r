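## File formats.  All state orders on disk are little-endian mixed-radix
## (row r + 1 of a TPM block is state index r; the first node varies
## fastest), matching encodeState().

#' Read and write state-by-state TPM files
#'
#' TSV layout: first header line holds the node labels, second the number
#' of states per node, followed by `S` rows of `S` transition
#' probabilities.  The JSON variant carries
#' `{"nodes": [{"label":, "num_states":}], "tpm": [[...]]}`.  Rows are
#' accepted only when they sum to 1 within 1e-6 (see [NetworkModel()]);
#' deterministic TPMs are written as exact 0/1 integers.
#'
#' @param path file path; `readTpm` dispatches on a `.json` extension.
#' @param net a [NetworkModel-class] (for the writers).
#' @param format `"tsv"` or `"json"` (for [writeTpm()]; default from the
#'   extension).
#' @return `readTpm` a [NetworkModel-class]; the writers the path,
#'   invisibly.
#' @export
readTpm <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) return(.readTpmJson(path))
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop(path, ": expected two header lines plus TPM rows")
  labels <- strsplit(trimws(lines[1]), "\t")[[1]]
  numStates <- suppressWarnings(
    as.integer(strsplit(trimws(lines[2]), "\t")[[1]]))
  if (anyNA(numStates))
    stop(path, ":2: second header line must hold integer state counts")
  S <- prod(numStates)
  if (length(lines) != 2L + S)
    stop(path, ": expected ", S, " TPM rows (S = ", S, "), found ",
         length(lines) - 2L)
  rows <- lapply(seq_len(S), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[2L + i], "\t")[[1]]))
    if (length(v) != S || anyNA(v))
      stop(path, ":", 2L + i, ": expected ", S, " numeric entries")
    v
  })
  NetworkModel(do.call(rbind, rows), numStates, labels)
}

.readTpmJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$nodes) || is.null(obj$tpm))
    stop(path, ": JSON must have 'nodes' and 'tpm'")
  NetworkModel(obj$tpm, obj$nodes$num_states, obj$nodes$label)
}

#' @rdname readTpm
#' @export
writeTpm <- function(net, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  P <- tpm(net)
  if (format == "json") {
    obj <- list(nodes = data.frame(label = nodeLabels(net),
                                   num_states = numStatesPerNode(net)),
                tpm = P)
    writeLines(jsonlite::toJSON(obj, digits = NA), path)
    return(invisible(path))
  }
  fmtRow <- function(v) {
    if (all(v %in% c(0, 1))) paste(as.integer(v), collapse = "\t")
    else paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
               collapse = "\t")
  }
  lines <- c(paste(nodeLabels(net), collapse = "\t"),
             paste(numStatesPerNode(net), collapse = "\t"),
             vapply(seq_len(nrow(P)), function(i) fmtRow(P[i, ]),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write deterministic truth tables
#'
#' TSV layout: labels line, state-count line, then one row per state with
#' `n` current-value columns followed by `n` next-value columns.  Rows may
#' appear in any order but must cover every state exactly once.
#'
#' @param path file path.
#' @param f an [EvolutionFunction-class] (for the writer; must be total).
#' @return `readEvolutionTable` an [EvolutionFunction-class].
#' @export
readEvolutionTable <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(trimws(lines[1]), "\t")[[1]]
  radices <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  n <- length(radices)
  S <- prod(radices)
  if (length(lines) != 2L + S)
    stop(path, ": expected ", S, " rows, found ", length(lines) - 2L)
  succ <- rep(NA_integer_, S)
  for (i in seq_len(S)) {
    v <- as.integer(strsplit(lines[2L + i], "\t")[[1]])
    if (length(v) != 2L * n || anyNA(v))
      stop(path, ":", 2L + i, ": expected ", 2L * n, " integer entries")
    from <- encodeState(v[seq_len(n)], radices)
    if (!is.na(succ[from + 1L]))
      stop(path, ":", 2L + i, ": duplicate row for state (",
           paste(v[seq_len(n)], collapse = ","), ")")
    succ[from + 1L] <- encodeState(v[n + seq_len(n)], radices)
  }
  evolutionFunction(radices, succ, labels)
}

#' @rdname readEvolutionTable
#' @export
writeEvolutionTable <- function(f, path) {
  r <- f@radices
  n <- length(r)
  S <- prod(r)
  rows <- vapply(0:(S - 1L), function(s) {
    paste(c(decodeState(s, r),
            decodeState(f@successor[s + 1L], r)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(f@labels, collapse = "\t"),
               paste(r, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read and write a side-by-side binarization table
#'
#' The layout mirrors the printed presentation of multi-valued
#' binarizations: one row per binary state with the current bits, the Van
#' Ham image (`-` on non-admissible states), and the Faure-Kaji and
#' Tonello images, where `=` marks a cell equal to the Van Ham image.
#'
#' @param f an [EvolutionFunction-class]; its three binarizations are
#'   computed and written.
#' @param path file path.
#' @return `readBinarizationTables` a list with partial `vanHam` and total
#'   `faureKaji` / `tonello` [EvolutionFunction-class] objects plus the
#'   `admissible` indicator.
#' @export
writeBinarizationTables <- function(f, path) {
  vh <- vanHam(f); fk <- faureKaji(f); tn <- tonello(f)
  bf <- vh@binaryFunction
  r2 <- bf@radices
  B <- length(r2)
  S2 <- 2L^B
  fmt <- function(s) paste(decodeState(s, r2), collapse = "\t")
  rows <- vapply(0:(S2 - 1L), function(b) {
    vhs <- bf@successor[b + 1L]
    vhTxt <- if (is.na(vhs)) paste(rep("-", B), collapse = "\t") else fmt(vhs)
    eqOrBits <- function(s) {
      if (!is.na(vhs) && s == vhs) paste(rep("=", B), collapse = "\t")
      else fmt(s)
    }
    paste(fmt(b), vhTxt,
          eqOrBits(fk@binaryFunction@successor[b + 1L]),
          eqOrBits(tn@binaryFunction@successor[b + 1L]),
          sep = "\t")
  }, character(1))
  writeLines(c(paste(bf@labels, collapse = "\t"),
               paste(r2, collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname writeBinarizationTables
#' @export
readBinarizationTables <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(trimws(lines[1]), "\t")[[1]]
  r2 <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  B <- length(r2)
  S2 <- prod(r2)
  if (length(lines) != 2L + S2)
    stop(path, ": expected ", S2, " rows")
  vh <- fk <- tn <- rep(NA_integer_, S2)
  adm <- logical(S2)
  for (i in seq_len(S2)) {
    cells <- strsplit(lines[2L + i], "\t")[[1]]
    if (length(cells) != 4L * B)
      stop(path, ":", 2L + i, ": expected ", 4L * B, " columns")
    cur <- encodeState(as.integer(cells[seq_len(B)]), r2)
    vhCells <- cells[B + seq_len(B)]
    vhVal <- NA_integer_
    if (!any(vhCells == "-")) {
      vhVal <- encodeState(as.integer(vhCells), r2)
      adm[cur + 1L] <- TRUE
    }
    expand <- function(xs) {
      if (any(xs == "=")) {
        if (is.na(vhVal))
          stop(path, ":", 2L + i, ": '=' used on a row without a Van Ham image")
        bits <- decodeState(vhVal, r2)
        xs[xs == "="] <- bits[which(xs == "=")]
      }
      encodeState(as.integer(xs), r2)
    }
    vh[cur + 1L] <- vhVal
    fk[cur + 1L] <- expand(cells[2L * B + seq_len(B)])
    tn[cur + 1L] <- expand(cells[3L * B + seq_len(B)])
  }
  list(vanHam = evolutionFunction(r2, vh, labels),
       faureKaji = evolutionFunction(r2, fk, labels),
       tonello = evolutionFunction(r2, tn, labels),
       admissible = adm)
}

#' Import a binary state-by-node TPM
#'
#' Compatibility shim for the binary-only convention where a TPM is given
#' as an `S x n` matrix of `Pr(node i fires | current state)`.  Only
#' all-binary systems can be represented this way; the rows are expanded
#' into the state-by-state form.
#'
#' @param mat numeric `S x n` matrix with entries in `[0, 1]`, rows in
#'   little-endian state order.
#' @param labels optional node labels.
#' @return a [NetworkModel-class] with `n` binary nodes.
#' @export
stateByNodeToNetwork <- function(mat, labels = NULL) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (nrow(mat) != 2L^n)
    stop("state-by-node input must have 2^n rows; got ", nrow(mat),
         " rows for ", n, " nodes")
  conds <- lapply(seq_len(n), function(i) cbind(1 - mat[, i], mat[, i]))
  NetworkModel(.tpmFromConditionals(conds, rep(2L, n)), rep(2L, n), labels)
}
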
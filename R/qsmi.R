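# QSMI: quantization sparse matrix identification.
#
# Pipeline: paired ECG/SpO2 series -> 2-D counting matrix -> sliding-mask
# quantization into a few levels -> COO sparse encoding -> Pearson
# correlation of the dense flattenings as the match score.

#' Construct a quantization specification
#'
#' @param nLevels 3 (default) or 4 quantization levels.
#' @param maskSize window side m of the non-overlapping tiling (default 2).
#' @param a,c,d thresholds, `a <= c <= d`; a window sum (plus the bias
#'   total) maps to level 0 if `<= a`, 1 if `<= c`, 2 if `<= d`, 3
#'   otherwise; with 3 levels `d` is unused. The defaults `a = 0`,
#'   `c = 2` make level 0 exactly "empty window"; `d` defaults to `2 c`
#'   when 4 levels are requested.
#' @param bias optional m x m non-negative integer mask whose total is
#'   added to every window sum (all-zero by default).
#' @return a validated [QuantizationSpec-class].
#' @examples
#' quantizationSpec()
#' quantizationSpec(nLevels = 4, a = 0, c = 2, d = 5)
#' @export
quantizationSpec <- function(nLevels = 3L, maskSize = 2L, a = 0, c = 2,
                             d = NULL, bias = NULL) {
  nLevels <- as.integer(nLevels)
  maskSize <- as.integer(maskSize)
  if (is.null(d)) d <- if (nLevels == 4L) 2 * c else c
  if (is.null(bias)) bias <- matrix(0, maskSize, maskSize)
  new("QuantizationSpec", maskSize = maskSize, bias = bias,
      a = a, c = c, d = d, nLevels = nLevels)
}

# Affine min-max binning of a continuous series to integer indices 1..n.
# A zero-range (constant) series maps everything to bin 1 with a warning.
binIndices <- function(x, n, range = NULL) {
  if (is.null(range)) range <- c(min(x), max(x))
  span <- range[2] - range[1]
  if (span <= 0) {
    warning("constant series (zero amplitude range): all samples map to bin 1")
    return(rep(1L, length(x)))
  }
  idx <- floor(1 + (x - range[1]) / span * (n - 1) + 0.5)  # round half up
  pmin(n, pmax(1L, as.integer(idx)))
}

#' Map a paired record into an n x n counting matrix
#'
#' ECG amplitudes are binned to row indices 1..n by affine min-max
#' scaling (round half up, clamped), SpO2 values to column indices
#' likewise, and each sample pair increments exactly one cell, so the
#' matrix total equals the number of samples. Fixed ranges (for
#' cross-session comparability, e.g. ranges estimated from an
#' individual's enrollment session) can be supplied; by default each
#' record's own min/max is used.
#'
#' @param record a [BiosignalRecord-class].
#' @param n matrix side, >= 2.
#' @param ecgRange,spo2Range optional length-2 numeric fixed bin ranges.
#' @return a [CountMatrix-class].
#' @examples
#' r <- simulateIndividual(drawIndividualParams(1), 5, 100, seed = 2)
#' M <- mapToMatrix(r, n = 32)
#' sum(M@counts) == length(r)
#' @export
mapToMatrix <- function(record, n = 32L, ecgRange = NULL, spo2Range = NULL) {
  stopifnot(is(record, "BiosignalRecord"))
  n <- as.integer(n)
  if (n < 2L) stop("matrix size n must be >= 2")
  i <- binIndices(record@ecg, n, ecgRange)
  j <- binIndices(record@spo2, n, spo2Range)
  counts <- matrix(tabulate((j - 1L) * n + i, nbins = n * n), n, n)
  new("CountMatrix", counts = counts, nMapped = length(i))
}

#' Quantize-reduce a counting matrix with a sliding mask
#'
#' The n x n counting matrix is tiled into non-overlapping m x m windows
#' (ragged right/bottom edges zero-padded); each window's entry sum plus
#' the total of the bias mask is mapped to a quantization level by the
#' spec's thresholds. The result is a q x q matrix with
#' q = ceiling(n / m) and entries in 0 .. nLevels - 1.
#'
#' @param M a [CountMatrix-class].
#' @param spec a [QuantizationSpec-class].
#' @return a [ReducedMatrix-class].
#' @examples
#' r <- simulateIndividual(drawIndividualParams(1), 5, 100, seed = 2)
#' quantizeReduce(mapToMatrix(r, 32), quantizationSpec())
#' @export
quantizeReduce <- function(M, spec = quantizationSpec()) {
  stopifnot(is(M, "CountMatrix"), is(spec, "QuantizationSpec"))
  m <- spec@maskSize
  n <- nrow(M@counts)
  q <- ceiling(n / m)
  pad <- matrix(0, q * m, q * m)
  pad[seq_len(n), seq_len(n)] <- M@counts
  grp <- rep(seq_len(q), each = m)
  ws <- t(rowsum(t(rowsum(pad, grp)), grp))  # q x q window sums
  ws <- ws + sum(spec@bias)
  lev <- matrix(0L, q, q)
  lev[ws > spec@a] <- 1L
  lev[ws > spec@c] <- 2L
  if (spec@nLevels == 4L) lev[ws > spec@d] <- 3L
  new("ReducedMatrix", levels = lev, nLevels = spec@nLevels)
}

#' Encode a reduced matrix in COO sparse form
#'
#' Emits all and only the non-zero entries as 1-based (row, col, value)
#' triples in column-major order (column ascending, then row ascending).
#'
#' @param RM a [ReducedMatrix-class].
#' @return a [SparseCOO-class].
#' @seealso [cooDecode()]
#' @export
cooEncode <- function(RM) {
  stopifnot(is(RM, "ReducedMatrix"))
  nz <- which(RM@levels != 0)  # column-major linear indices
  q <- nrow(RM@levels)
  new("SparseCOO",
      row = as.integer((nz - 1L) %% q + 1L),
      col = as.integer((nz - 1L) %/% q + 1L),
      value = as.integer(RM@levels[nz]),
      nrow = q, ncol = as.integer(ncol(RM@levels)),
      nLevels = RM@nLevels)
}

#' Decode a COO sparse matrix back to its dense reduced form
#'
#' Inverse of [cooEncode()]: `cooDecode(cooEncode(RM))` reproduces `RM`.
#'
#' @param SM a [SparseCOO-class].
#' @return a [ReducedMatrix-class] of the declared shape.
#' @export
cooDecode <- function(SM) {
  stopifnot(is(SM, "SparseCOO"))
  validObject(SM)  # catches out-of-shape coordinates
  lev <- matrix(0L, SM@nrow, SM@ncol)
  lev[cbind(SM@row, SM@col)] <- SM@value
  nl <- max(SM@nLevels, if (length(SM@value)) max(SM@value) + 1L else 0L, 2L)
  new("ReducedMatrix", levels = lev, nLevels = as.integer(nl))
}

#' Write / read the COO plain-text format
#'
#' Text format: a header line `rows cols n_levels`, then one
#' `row col value` triple per line, 1-based, column-major order. The
#' round trip is exact.
#'
#' @param SM a [SparseCOO-class].
#' @param path file path.
#' @return `writeCOO` returns `path` invisibly; `readCOO` a
#'   [SparseCOO-class].
#' @export
writeCOO <- function(SM, path) {
  stopifnot(is(SM, "SparseCOO"))
  lines <- c(paste(SM@nrow, SM@ncol, SM@nLevels),
             sprintf("%d %d %d", SM@row, SM@col, SM@value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCOO
#' @export
readCOO <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 3 || anyNA(hdr))
    stop("malformed COO header in ", path)
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body)) {
    trip <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
    if (ncol(trip) != 3 || anyNA(trip))
      stop("malformed COO triple in ", path)
  } else trip <- matrix(integer(), 0, 3)
  new("SparseCOO", row = trip[, 1], col = trip[, 2], value = trip[, 3],
      nrow = hdr[1], ncol = hdr[2], nLevels = hdr[3])
}

#' Correlation similarity between two sparse-encoded reduced matrices
#'
#' The Pearson correlation coefficient of the two matrices flattened
#' over the full dense grid (zeros included). Returns 0 with a warning
#' if either flattening has zero variance.
#'
#' @param SM1,SM2 [SparseCOO-class] objects of equal declared shape.
#' @return a number in \[-1, 1\].
#' @export
qsmiSimilarity <- function(SM1, SM2) {
  stopifnot(is(SM1, "SparseCOO"), is(SM2, "SparseCOO"))
  if (SM1@nrow != SM2@nrow || SM1@ncol != SM2@ncol)
    stop("shape mismatch: ", SM1@nrow, "x", SM1@ncol, " vs ",
         SM2@nrow, "x", SM2@ncol)
  x <- as.vector(cooDecode(SM1)@levels)
  y <- as.vector(cooDecode(SM2)@levels)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance flattened matrix; similarity undefined, returning 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Enroll a cohort's training sessions as QSMI templates
#'
#' Each individual's template is the COO sparse encoding of its training
#' record, together with the amplitude ranges observed in that session
#' (used to bin later probes on the same grid). When an individual has
#' several training records, each becomes an alternate template. All
#' pairwise training similarities are retained for threshold sweeping.
#'
#' @param trainRecords list of [BiosignalRecord-class] training sessions
#'   (>= 1 per individual, >= 1 individual).
#' @param n counting-matrix side.
#' @param spec a [QuantizationSpec-class].
#' @return an object of class `QsmiTemplateSet`: a list with `templates`
#'   (per template: `individualId`, `coo`, `ecgRange`, `spo2Range`),
#'   `n`, `spec`, and `trainScores` (data.frame of pairwise training
#'   similarities with a `genuine` flag; empty with a single template).
#' @export
enrollQsmi <- function(trainRecords, n = 32L, spec = quantizationSpec()) {
  if (length(trainRecords) < 1L) stop("empty cohort: nothing to enroll")
  templates <- lapply(trainRecords, function(r) {
    er <- range(r@ecg); sr <- range(r@spo2)
    M <- mapToMatrix(r, n, ecgRange = er, spo2Range = sr)
    list(individualId = individualId(r),
         coo = cooEncode(quantizeReduce(M, spec)),
         ecgRange = er, spo2Range = sr)
  })
  ts <- data.frame(i = integer(), j = integer(), score = numeric(),
                   genuine = logical())
  if (length(templates) > 1) {
    pairs <- utils::combn(length(templates), 2)
    ts <- data.frame(
      i = pairs[1, ], j = pairs[2, ],
      score = apply(pairs, 2, function(p)
        qsmiSimilarity(templates[[p[1]]]$coo, templates[[p[2]]]$coo)),
      genuine = apply(pairs, 2, function(p)
        templates[[p[1]]]$individualId == templates[[p[2]]]$individualId))
  }
  structure(list(templates = templates, n = n, spec = spec,
                 trainScores = ts),
            class = "QsmiTemplateSet")
}

#' @export
print.QsmiTemplateSet <- function(x, ...) {
  cat(sprintf("QsmiTemplateSet: %d templates (%d individuals), n = %d\n",
              length(x$templates),
              length(unique(vapply(x$templates, `[[`, "", "individualId"))),
              x$n))
  print(x$spec)
  invisible(x)
}

#' Score a probe record against every enrolled QSMI template
#'
#' The probe is binned with each template's stored amplitude ranges (so
#' probe and template share a grid), quantized with the enrollment spec,
#' and compared by [qsmiSimilarity()].
#'
#' @param probe a [BiosignalRecord-class].
#' @param enrolled a `QsmiTemplateSet` from [enrollQsmi()].
#' @return data.frame with `templateIndividual`, `score` (correlation).
#' @export
scoreQsmi <- function(probe, enrolled) {
  stopifnot(inherits(enrolled, "QsmiTemplateSet"))
  res <- lapply(enrolled$templates, function(tp) {
    M <- mapToMatrix(probe, enrolled$n,
                     ecgRange = tp$ecgRange, spo2Range = tp$spo2Range)
    data.frame(templateIndividual = tp$individualId,
               score = qsmiSimilarity(
                 cooEncode(quantizeReduce(M, enrolled$spec)), tp$coo))
  })
  do.call(rbind, res)
}
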
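# MDI: multi-dimensional identification.
#
# Multi-lead sessions are mapped sample-by-sample into a discrete
# J-dimensional space of side u (reduce by R, shift by delta_theta, round,
# clamp), summarized as sparse element sequences (distinct coordinates with
# occupancy counts), optionally coarsened by a window factor m
# ("Num_u_Red_m"), and compared by multi-dimensional DTW.

#' Construct a reduction specification for the multi-dimensional mapping
#'
#' @param R positive reduction level dividing the raw amplitudes.
#' @param deltaTheta non-negative offset added after reduction so mapped
#'   values stay positive.
#' @param u side of the discrete space; coordinates are clamped to
#'   \[1, u\].
#' @param m window coarsening factor (1 = no coarsening). The defaults
#'   (`u = 32`, `m = 2`, `deltaTheta = 20`) are the configuration
#'   reported best for 5-lead signals ("Num_32_Red_2").
#' @return a validated list of class `ReductionSpec`.
#' @export
reductionSpec <- function(R = 0.1, deltaTheta = 20, u = 32L, m = 2L) {
  if (R <= 0) stop("R must be positive")
  if (deltaTheta < 0) stop("deltaTheta must be non-negative")
  u <- as.integer(u); m <- as.integer(m)
  if (u < 1L) stop("u must be >= 1")
  if (m < 1L) stop("m must be >= 1")
  structure(list(R = R, deltaTheta = deltaTheta, u = u, m = m),
            class = "ReductionSpec")
}

#' @export
print.ReductionSpec <- function(x, ...) {
  cat(sprintf("ReductionSpec: R = %g, deltaTheta = %g, u = %d, window m = %d\n",
              x$R, x$deltaTheta, x$u, x$m))
  invisible(x)
}

#' Map a multi-lead record into the discrete J-dimensional space
#'
#' For each time point k and lead j the coordinate is
#' `round(s_jk / R + deltaTheta)` (half up), clamped to 1 from below and
#' to u from above, yielding one J-dimensional integer point per sample.
#'
#' @param record a [MultiLeadRecord-class].
#' @param spec a [reductionSpec()].
#' @return a K x J integer matrix of points (class `PointSequence`), with
#'   attribute `u`.
#' @export
reduceMap <- function(record, spec = reductionSpec()) {
  stopifnot(is(record, "MultiLeadRecord"), inherits(spec, "ReductionSpec"))
  d <- floor(record@leads / spec$R + spec$deltaTheta + 0.5)
  d[d < 1] <- 1
  d[d > spec$u] <- spec$u
  pts <- matrix(as.integer(d), nrow(d), ncol(d))
  structure(pts, u = spec$u, class = c("PointSequence", class(pts)))
}

lexOrder <- function(coords) do.call(order, split(coords, col(coords)))

newSparseElements <- function(coords, values, u) {
  o <- lexOrder(coords)
  new("SparseElementSequence",
      coords = matrix(as.integer(coords[o, , drop = FALSE]),
                      nrow = length(o)),
      values = as.integer(values[o]), u = as.integer(u))
}

#' Accumulate a point sequence into a sparse element sequence
#'
#' Counts how many time points occupy each distinct coordinate; the total
#' occupancy equals the number of points. Elements are stored in
#' lexicographic coordinate order.
#'
#' @param points an integer K x J matrix from [reduceMap()] (attribute
#'   `u`, or supply `u`).
#' @param u space side; defaults to the matrix's `u` attribute.
#' @return a [SparseElementSequence-class].
#' @export
accumulateSparse <- function(points, u = attr(points, "u")) {
  if (is.null(u)) stop("space side u is required")
  pts <- unclass(points)
  key <- apply(pts, 1, paste, collapse = ",")
  first <- !duplicated(key)
  cnt <- table(factor(key, levels = key[first]))
  newSparseElements(pts[first, , drop = FALSE], as.vector(cnt), u)
}

#' Coarsen a sparse element sequence by a window factor
#'
#' Each coordinate axis is divided into tiles of side m (tile index =
#' `ceiling(coordinate / m)`); occupancies of coordinates merged into the
#' same tile are summed, so the total occupancy is conserved and the
#' element count never grows.
#'
#' @param seq a [SparseElementSequence-class].
#' @param m window factor >= 1 (`m = 1` is the identity).
#' @return a [SparseElementSequence-class] in a space of side
#'   `ceiling(u / m)`.
#' @export
windowReduce <- function(seq, m = 2L) {
  stopifnot(is(seq, "SparseElementSequence"))
  m <- as.integer(m)
  if (m < 1L) stop("window factor m must be >= 1")
  if (m == 1L) return(seq)
  cc <- ceiling(seq@coords / m)
  key <- apply(cc, 1, paste, collapse = ",")
  first <- !duplicated(key)
  v <- as.vector(rowsum(as.numeric(seq@values),
                        factor(key, levels = key[first])))
  newSparseElements(cc[first, , drop = FALSE], v, ceiling(seq@u / m))
}

seqFeatures <- function(x, useValue) {
  f <- if (useValue) cbind(x@coords, x@values) else x@coords
  matrix(as.numeric(f), nrow(f))
}

#' Multi-dimensional DTW distance between two sparse element sequences
#'
#' Local cost between two elements is the squared Euclidean distance over
#' their J coordinates; `useValue = TRUE` appends the occupancy count v as
#' an unweighted (J+1)-th component. Coordinates-only is the default:
#' occupancies grow with session length, so a single squared v difference
#' can dominate every coordinate term when the equal-length direct
#' alignment applies. Equal-length sequences are compared by the direct
#' position-wise sum; unequal lengths use the dynamic-programming DTW
#' recurrence. The distance is symmetric, non-negative and zero on
#' identical inputs.
#'
#' @param X1,X2 [SparseElementSequence-class] objects with the same J and
#'   the same u.
#' @param useValue include the occupancy count in the local cost
#'   (default FALSE).
#' @return a non-negative number.
#' @export
dtwDistance <- function(X1, X2, useValue = FALSE) {
  stopifnot(is(X1, "SparseElementSequence"), is(X2, "SparseElementSequence"))
  if (nrow(X1@coords) == 0 || nrow(X2@coords) == 0)
    stop("empty sparse element sequence")
  if (ncol(X1@coords) != ncol(X2@coords))
    stop("dimension mismatch: J = ", ncol(X1@coords), " vs ", ncol(X2@coords))
  if (X1@u != X2@u)
    stop("space-side mismatch: u = ", X1@u, " vs ", X2@u)
  .dtwCost(seqFeatures(X1, useValue), seqFeatures(X2, useValue))
}

#' Enroll multi-lead training sessions as MDI templates
#'
#' Each training record is reduced/mapped, accumulated and
#' window-coarsened with the given spec; the resulting sparse element
#' sequence is the individual's template.
#'
#' @param trainRecords list of [MultiLeadRecord-class] objects.
#' @param spec a [reductionSpec()].
#' @return list of class `MdiTemplateSet` with `templates` (per template:
#'   `individualId`, `elements`) and `spec`.
#' @export
enrollMdi <- function(trainRecords, spec = reductionSpec()) {
  if (length(trainRecords) < 1L) stop("empty cohort: nothing to enroll")
  templates <- lapply(trainRecords, function(r)
    list(individualId = individualId(r),
         elements = windowReduce(accumulateSparse(reduceMap(r, spec)),
                                 spec$m)))
  structure(list(templates = templates, spec = spec),
            class = "MdiTemplateSet")
}

#' Identify a probe against enrolled MDI templates
#'
#' The probe is processed with the enrollment spec and compared to every
#' template by [dtwDistance()]; the closest template wins (ties broken by
#' enrollment order, with a message). The probe is accepted when the
#' minimum distance does not exceed the threshold.
#'
#' @param probe a [MultiLeadRecord-class].
#' @param enrolled an `MdiTemplateSet` from [enrollMdi()].
#' @param threshold acceptance threshold on the DTW distance.
#' @param useValue passed to [dtwDistance()].
#' @return list with `bestIndividual`, `distance`, `accept`, and the full
#'   `distances` vector (named by template individual).
#' @export
mdiIdentify <- function(probe, enrolled, threshold, useValue = FALSE) {
  stopifnot(inherits(enrolled, "MdiTemplateSet"))
  spec <- enrolled$spec
  pe <- windowReduce(accumulateSparse(reduceMap(probe, spec)), spec$m)
  if (ncol(pe@coords) != ncol(enrolled$templates[[1]]$elements@coords))
    stop("probe lead count does not match the enrollment spec")
  d <- vapply(enrolled$templates, function(tp)
    dtwDistance(pe, tp$elements, useValue = useValue), numeric(1))
  names(d) <- vapply(enrolled$templates, `[[`, "", "individualId")
  best <- which(d == min(d))
  if (length(best) > 1)
    message("distance tie between templates ",
            paste(names(d)[best], collapse = ", "),
            "; keeping the first enrolled")
  best <- best[1]
  list(bestIndividual = names(d)[best], distance = unname(d[best]),
       accept = unname(d[best]) <= threshold, distances = d)
}

#' Write / read the sparse element plain-text format
#'
#' Text format: header `J u`, then one line `c1 ... cJ v` per element in
#' lexicographic coordinate order. The round trip is exact.
#'
#' @param x a [SparseElementSequence-class].
#' @param path file path.
#' @return `writeSparseElements` returns `path` invisibly;
#'   `readSparseElements` a [SparseElementSequence-class].
#' @export
writeSparseElements <- function(x, path) {
  stopifnot(is(x, "SparseElementSequence"))
  body <- apply(cbind(x@coords, x@values), 1, paste, collapse = " ")
  writeLines(c(paste(ncol(x@coords), x@u), body), path)
  invisible(path)
}

#' @rdname writeSparseElements
#' @export
readSparseElements <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop("malformed sparse-element header in ", path)
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
    if (ncol(m) != hdr[1] + 1 || anyNA(m))
      stop("malformed sparse-element line in ", path)
  } else m <- matrix(integer(), 0, hdr[1] + 1)
  new("SparseElementSequence",
      coords = m[, seq_len(hdr[1]), drop = FALSE],
      values = m[, hdr[1] + 1L], u = hdr[2])
}
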
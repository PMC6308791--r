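#' @import methods
NULL

#' One session of paired ECG and blood-oxygen samples for one individual
#'
#' A `BiosignalRecord` holds the raw material of the 2-D identification
#' pipeline: an ECG series and an SpO2 series sampled at the same time
#' points, so sample `k` of each channel forms one paired observation.
#'
#' @slot individualId character(1), opaque individual label.
#' @slot sessionId character(1), opaque session label.
#' @slot ecg numeric vector, ECG samples (arbitrary amplitude units).
#' @slot spo2 numeric vector, oxygen saturation in percent; same length as
#'   `ecg` (channels are paired per time index).
#' @slot samplingRate numeric(1), samples per second, > 0.
#'
#' @seealso [simulateIndividual()], [mapToMatrix()]
#' @export
setClass("BiosignalRecord",
  representation(
    individualId = "character",
    sessionId    = "character",
    ecg          = "numeric",
    spo2         = "numeric",
    samplingRate = "numeric"
  )
)

setValidity("BiosignalRecord", function(object) {
  msg <- character()
  if (length(object@individualId) != 1L || is.na(object@individualId))
    msg <- c(msg, "individualId must be a single non-NA label")
  if (length(object@sessionId) != 1L || is.na(object@sessionId))
    msg <- c(msg, "sessionId must be a single non-NA label")
  if (length(object@ecg) < 1L)
    msg <- c(msg, "ecg must contain at least one sample")
  if (length(object@ecg) != length(object@spo2))
    msg <- c(msg, "ecg and spo2 must have equal length (samples are paired)")
  if (anyNA(object@ecg) || anyNA(object@spo2))
    msg <- c(msg, "series must not contain missing values")
  if (length(object@samplingRate) != 1L || is.na(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' One multi-lead ECG session for one individual
#'
#' @slot individualId character(1) individual label.
#' @slot sessionId character(1) session label.
#' @slot leads numeric matrix, K samples (rows) by J leads (columns),
#'   J >= 2; all leads share the time base.
#' @slot samplingRate numeric(1), samples per second, > 0.
#'
#' @seealso [simulateMultilead()], [reduceMap()]
#' @export
setClass("MultiLeadRecord",
  representation(
    individualId = "character",
    sessionId    = "character",
    leads        = "matrix",
    samplingRate = "numeric"
  )
)

setValidity("MultiLeadRecord", function(object) {
  msg <- character()
  if (length(object@individualId) != 1L || is.na(object@individualId))
    msg <- c(msg, "individualId must be a single non-NA label")
  if (length(object@sessionId) != 1L || is.na(object@sessionId))
    msg <- c(msg, "sessionId must be a single non-NA label")
  if (!is.numeric(object@leads))
    msg <- c(msg, "leads must be a numeric matrix")
  if (ncol(object@leads) < 2L)
    msg <- c(msg, "a multi-lead record needs J >= 2 leads")
  if (nrow(object@leads) < 1L)
    msg <- c(msg, "leads must contain at least one sample")
  if (anyNA(object@leads))
    msg <- c(msg, "leads must not contain missing values")
  if (length(object@samplingRate) != 1L || is.na(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Per-individual generative parameters for the synthetic cohort
#'
#' Describes one synthetic individual: the P/Q/R/S/T wave morphology
#' (per-wave amplitude, Gaussian width in seconds, and center offset in
#' seconds relative to the R peak), the heart rate, the SpO2 baseline and
#' its slow-drift scale, and per-lead scale factors for multi-lead
#' synthesis. Parameters are drawn from continuous priors, so two
#' independent draws differ almost surely.
#'
#' @slot morphology data.frame with columns `wave` (P,Q,R,S,T), `amp`,
#'   `width` (s), `center` (s, offset from the R peak).
#' @slot heartRateHz numeric(1), beats per second, > 0.
#' @slot spo2Mean numeric(1), percent in \[85, 100\].
#' @slot spo2Sd numeric(1), non-negative random-walk step scale.
#' @slot leadScales numeric vector of positive per-lead gains.
#'
#' @seealso [drawIndividualParams()], [simulateIndividual()]
#' @export
setClass("IndividualParams",
  representation(
    morphology  = "data.frame",
    heartRateHz = "numeric",
    spo2Mean    = "numeric",
    spo2Sd      = "numeric",
    leadScales  = "numeric"
  )
)

setValidity("IndividualParams", function(object) {
  msg <- character()
  m <- object@morphology
  need <- c("wave", "amp", "width", "center")
  if (!all(need %in% names(m)) || nrow(m) != 5L ||
      !setequal(m$wave, c("P", "Q", "R", "S", "T")))
    msg <- c(msg, "morphology must have one row per wave P,Q,R,S,T with amp/width/center")
  else if (any(m$width <= 0))
    msg <- c(msg, "wave widths must be positive")
  if (length(object@heartRateHz) != 1L || object@heartRateHz <= 0)
    msg <- c(msg, "heartRateHz must be a single positive number")
  if (length(object@spo2Mean) != 1L ||
      object@spo2Mean < 85 || object@spo2Mean > 100)
    msg <- c(msg, "spo2Mean must lie in [85, 100]")
  if (length(object@spo2Sd) != 1L || object@spo2Sd < 0)
    msg <- c(msg, "spo2Sd must be non-negative")
  if (length(object@leadScales) < 1L || any(object@leadScales <= 0))
    msg <- c(msg, "leadScales must be positive")
  if (length(msg)) msg else TRUE
})

#' Counting matrix of paired ECG/SpO2 indices
#'
#' An n x n non-negative integer matrix in which cell (i, j) counts the
#' sample pairs whose binned ECG amplitude fell in row bin i and whose
#' binned SpO2 value fell in column bin j. The sum of all entries equals
#' the number of mapped sample pairs.
#'
#' @slot counts integer matrix, n x n, entries >= 0.
#' @slot nMapped integer(1), number of sample pairs mapped in.
#'
#' @seealso [mapToMatrix()], [quantizeReduce()]
#' @export
setClass("CountMatrix",
  representation(counts = "matrix", nMapped = "integer")
)

setValidity("CountMatrix", function(object) {
  msg <- character()
  cm <- object@counts
  if (nrow(cm) != ncol(cm) || nrow(cm) < 1L)
    msg <- c(msg, "counts must be a square matrix")
  if (any(cm < 0) || any(cm != round(cm)))
    msg <- c(msg, "counts must be non-negative integers")
  if (sum(cm) != object@nMapped)
    msg <- c(msg, "sum of counts must equal the number of mapped sample pairs")
  if (length(msg)) msg else TRUE
})

#' Quantization specification for the sliding-mask reduction
#'
#' Defines how a counting matrix is tiled into non-overlapping m x m
#' windows and how each window sum (plus the sum of the additive bias
#' mask) is mapped to a small integer level: level 0 if <= a, level 1 if
#' <= c, level 2 if <= d, level 3 otherwise for 4-level quantization;
#' with 3 levels, d is unused and level 2 is everything above c.
#'
#' @slot maskSize integer(1), window side m >= 1.
#' @slot bias numeric matrix m x m of non-negative integers added (by
#'   its total) to every window sum; all-zero by default.
#' @slot a,c,d numeric(1) thresholds with a <= c <= d.
#' @slot nLevels integer(1), 3 or 4.
#'
#' @seealso [quantizationSpec()], [quantizeReduce()]
#' @export
setClass("QuantizationSpec",
  representation(
    maskSize = "integer",
    bias     = "matrix",
    a        = "numeric",
    c        = "numeric",
    d        = "numeric",
    nLevels  = "integer"
  )
)

setValidity("QuantizationSpec", function(object) {
  msg <- character()
  m <- object@maskSize
  if (length(m) != 1L || m < 1L)
    msg <- c(msg, "maskSize must be a single count >= 1")
  if (!all(dim(object@bias) == c(m, m)))
    msg <- c(msg, "bias mask must be m x m")
  if (any(object@bias < 0) || any(object@bias != round(object@bias)))
    msg <- c(msg, "bias mask entries must be non-negative integers")
  if (!object@nLevels %in% c(3L, 4L))
    msg <- c(msg, "nLevels must be 3 or 4")
  if (object@a > object@c)
    msg <- c(msg, "thresholds must satisfy a <= c")
  if (object@nLevels == 4L && object@c > object@d)
    msg <- c(msg, "thresholds must satisfy c <= d for 4-level quantization")
  if (length(msg)) msg else TRUE
})

#' Quantized (reduced) matrix
#'
#' The q x q result of [quantizeReduce()]: q = ceiling(n / m), every
#' entry an integer level in 0 .. nLevels - 1.
#'
#' @slot levels integer matrix q x q.
#' @slot nLevels integer(1), number of quantization levels (3 or 4).
#'
#' @export
setClass("ReducedMatrix",
  representation(levels = "matrix", nLevels = "integer")
)

setValidity("ReducedMatrix", function(object) {
  msg <- character()
  rm_ <- object@levels
  if (nrow(rm_) != ncol(rm_) || nrow(rm_) < 1L)
    msg <- c(msg, "levels must be a square matrix")
  if (any(rm_ < 0) || any(rm_ != round(rm_)))
    msg <- c(msg, "levels must be non-negative integers")
  if (any(rm_ >= object@nLevels))
    msg <- c(msg, "every level must be < nLevels")
  if (length(msg)) msg else TRUE
})

#' Coordinate-list (COO) sparse encoding of a reduced matrix
#'
#' Stores the non-zero entries of a [ReducedMatrix-class] as 1-based
#' (row, col, value) triples in column-major order (column ascending,
#' then row ascending), matching the conventional printed listing.
#'
#' @slot row,col integer vectors, 1-based coordinates.
#' @slot value integer vector of strictly positive entries.
#' @slot nrow,ncol integer(1), declared dense shape.
#' @slot nLevels integer(1), level alphabet size carried for decoding.
#'
#' @seealso [cooEncode()], [cooDecode()], [writeCOO()]
#' @export
setClass("SparseCOO",
  representation(
    row = "integer", col = "integer", value = "integer",
    nrow = "integer", ncol = "integer", nLevels = "integer"
  )
)

setValidity("SparseCOO", function(object) {
  msg <- character()
  k <- length(object@value)
  if (length(object@row) != k || length(object@col) != k)
    msg <- c(msg, "row, col and value must have equal length")
  if (k > 0) {
    if (any(object@value <= 0L))
      msg <- c(msg, "stored values must be strictly positive")
    if (any(object@row < 1L) || any(object@row > object@nrow) ||
        any(object@col < 1L) || any(object@col > object@ncol))
      msg <- c(msg, "coordinates must lie within the declared shape")
    if (anyDuplicated(cbind(object@row, object@col)))
      msg <- c(msg, "duplicate (row, col) coordinates are not allowed")
  }
  if (object@nrow < 1L || object@ncol < 1L)
    msg <- c(msg, "declared shape must be at least 1 x 1")
  if (length(msg)) msg else TRUE
})

#' Sparse element sequence in the reduced J-dimensional space
#'
#' The multi-lead representation: distinct occupied J-dimensional integer
#' coordinates together with their occupancy counts v (how many time
#' points mapped to that coordinate). Elements are kept in lexicographic
#' coordinate order, making the sequence a canonical serialization that
#' two sessions can be compared over by dynamic time warping.
#'
#' @slot coords integer matrix, one element per row, J columns, entries
#'   in \[1, u\]; rows unique and lexicographically sorted.
#' @slot values integer vector of occupancies >= 1; their sum equals the
#'   number of mapped time points.
#' @slot u integer(1), side length of the discrete space.
#'
#' @seealso [accumulateSparse()], [windowReduce()], [dtwDistance()]
#' @export
setClass("SparseElementSequence",
  representation(coords = "matrix", values = "integer", u = "integer")
)

setValidity("SparseElementSequence", function(object) {
  msg <- character()
  cm <- object@coords
  if (nrow(cm) != length(object@values))
    msg <- c(msg, "one occupancy value per coordinate row is required")
  if (nrow(cm) > 0) {
    if (any(object@values < 1L))
      msg <- c(msg, "occupancy values must be >= 1")
    if (any(cm < 1L) || any(cm > object@u))
      msg <- c(msg, "coordinates must lie in [1, u]")
    if (any(cm != round(cm)))
      msg <- c(msg, "coordinates must be integers")
    if (anyDuplicated(cm))
      msg <- c(msg, "coordinates must be unique")
    if (nrow(cm) > 1) {
      o <- do.call(order, split(cm, col(cm)))
      if (!identical(o, seq_len(nrow(cm))))
        msg <- c(msg, "elements must be in lexicographic coordinate order")
    }
  }
  if (length(object@u) != 1L || object@u < 1L)
    msg <- c(msg, "u must be a single count >= 1")
  if (length(msg)) msg else TRUE
})

#' Evaluation result: FA/FR rates at a decision threshold
#'
#' @slot FA,FR numeric(1) false-acceptance and false-rejection rates in
#'   \[0, 1\].
#' @slot halfSum numeric(1), (FA + FR) / 2.
#' @slot acc numeric(1), accuracy 1 - (FA + FR) / 2.
#' @slot delta numeric(1), the decision threshold used.
#' @slot perIndividualFA named numeric, FA restricted to impostor trials
#'   against each enrolled individual.
#'
#' @seealso [sweepThreshold()], [computeRates()]
#' @export
setClass("EvalResult",
  representation(
    FA = "numeric", FR = "numeric", halfSum = "numeric", acc = "numeric",
    delta = "numeric", perIndividualFA = "numeric"
  )
)

setValidity("EvalResult", function(object) {
  msg <- character()
  r <- c(object@FA, object@FR)
  if (any(r < 0) || any(r > 1))
    msg <- c(msg, "FA and FR must lie in [0, 1]")
  if (abs(object@halfSum - (object@FA + object@FR) / 2) > 1e-12)
    msg <- c(msg, "halfSum must equal (FA + FR) / 2")
  if (abs(object@acc - (1 - object@halfSum)) > 1e-12)
    msg <- c(msg, "acc must equal 1 - halfSum exactly")
  if (length(msg)) msg else TRUE
})
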
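#' @rdname accessors
#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname accessors
#' @export
setGeneric("ecg", function(x) standardGeneric("ecg"))

#' @rdname accessors
#' @export
setGeneric("spo2", function(x) standardGeneric("spo2"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("leads", function(x) standardGeneric("leads"))

#' Accessors for biosignal containers
#'
#' Read-only access to the slots of [BiosignalRecord-class] and
#' [MultiLeadRecord-class] objects.
#'
#' @param x a record object.
#' @return the corresponding component: labels as character scalars,
#'   series as numeric vectors, `leads()` as a K x J numeric matrix.
#' @name accessors
#' @aliases individualId sessionId ecg spo2 samplingRate leads
NULL

#' @describeIn accessors individual label of a paired record
setMethod("individualId", "BiosignalRecord", function(x) x@individualId)
#' @describeIn accessors individual label of a multi-lead record
setMethod("individualId", "MultiLeadRecord", function(x) x@individualId)
#' @describeIn accessors session label of a paired record
setMethod("sessionId", "BiosignalRecord", function(x) x@sessionId)
#' @describeIn accessors session label of a multi-lead record
setMethod("sessionId", "MultiLeadRecord", function(x) x@sessionId)
#' @describeIn accessors ECG series of a paired record
setMethod("ecg", "BiosignalRecord", function(x) x@ecg)
#' @describeIn accessors SpO2 series of a paired record
setMethod("spo2", "BiosignalRecord", function(x) x@spo2)
#' @describeIn accessors sampling rate of a paired record
setMethod("samplingRate", "BiosignalRecord", function(x) x@samplingRate)
#' @describeIn accessors sampling rate of a multi-lead record
setMethod("samplingRate", "MultiLeadRecord", function(x) x@samplingRate)
#' @describeIn accessors lead matrix (K samples x J leads)
setMethod("leads", "MultiLeadRecord", function(x) x@leads)

#' @describeIn accessors number of paired samples / time points
#' @export
setMethod("length", "BiosignalRecord", function(x) length(x@ecg))

setMethod("show", "BiosignalRecord", function(object) {
  cat(sprintf(
    "BiosignalRecord: individual '%s', session '%s'\n  %d paired ECG/SpO2 samples at %g Hz (%.1f s)\n",
    object@individualId, object@sessionId, length(object@ecg),
    object@samplingRate, length(object@ecg) / object@samplingRate))
})

setMethod("show", "MultiLeadRecord", function(object) {
  cat(sprintf(
    "MultiLeadRecord: individual '%s', session '%s'\n  %d leads x %d samples at %g Hz\n",
    object@individualId, object@sessionId, ncol(object@leads),
    nrow(object@leads), object@samplingRate))
})

setMethod("show", "IndividualParams", function(object) {
  cat(sprintf(
    "IndividualParams: HR %.2f Hz, SpO2 %.1f%% (drift sd %.2g), %d lead scales\n",
    object@heartRateHz, object@spo2Mean, object@spo2Sd,
    length(object@leadScales)))
  print(object@morphology, row.names = FALSE)
})

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix: %d x %d, %d sample pairs mapped, %d non-zero cells\n",
              nrow(object@counts), ncol(object@counts), object@nMapped,
              sum(object@counts > 0)))
})

setMethod("show", "QuantizationSpec", function(object) {
  thr <- if (object@nLevels == 3L)
    sprintf("a=%g, c=%g", object@a, object@c)
  else
    sprintf("a=%g, c=%g, d=%g", object@a, object@c, object@d)
  cat(sprintf("QuantizationSpec: %d levels, %dx%d mask (bias sum %g), %s\n",
              object@nLevels, object@maskSize, object@maskSize,
              sum(object@bias), thr))
})

setMethod("show", "ReducedMatrix", function(object) {
  cat(sprintf("ReducedMatrix: %d x %d, %d levels, %.1f%% non-zero\n",
              nrow(object@levels), ncol(object@levels), object@nLevels,
              100 * mean(object@levels != 0)))
})

setMethod("show", "SparseCOO", function(object) {
  cat(sprintf("SparseCOO: shape %d x %d, %d stored triples (column-major)\n",
              object@nrow, object@ncol, length(object@value)))
  if (length(object@value)) {
    k <- min(8L, length(object@value))
    cat("  ", paste(sprintf("(%d,%d,%d)", object@row[seq_len(k)],
                            object@col[seq_len(k)], object@value[seq_len(k)]),
                    collapse = " "),
        if (length(object@value) > k) "..." else "", "\n")
  }
})

setMethod("show", "SparseElementSequence", function(object) {
  cat(sprintf(
    "SparseElementSequence: %d elements in a %d-D space of side %d, total occupancy %d\n",
    nrow(object@coords), ncol(object@coords), object@u, sum(object@values)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: FA %.4f, FR %.4f, (FA+FR)/2 %.4f, Acc %.2f%% at threshold %g\n",
    object@FA, object@FR, object@halfSum, 100 * object@acc, object@delta))
})
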